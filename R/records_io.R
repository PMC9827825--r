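# JSON-lines archive format for characterization records. First line is a
# versioned header object; every following line is one record. Field names
# match the records tibble schema exactly.

.RECORDS_FORMAT <- "ersnet-ts-records"
.RECORDS_VERSION <- 1L

#' Write characterization records as JSON lines
#'
#' @param records records tibble (see [characterize_candidates()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ts_records <- function(records, path) {
  header <- jsonlite::toJSON(list(format = .RECORDS_FORMAT,
                                  version = .RECORDS_VERSION),
                             auto_unbox = TRUE)
  cols <- c("reactant_key", "product_key", "conformer_index", "level",
            "converged", "delta_g_act", "gradient_calls",
            "irc_reactant_key", "irc_product_key")
  missing <- setdiff(cols, names(records))
  if (length(missing)) .stop2("records missing column(s): ", paste(missing, collapse = ", "))
  body <- vapply(seq_len(nrow(records)), function(r) {
    rec <- as.list(records[r, cols])
    rec <- rec[!vapply(rec, function(x) is.na(x) && !is.logical(x), logical(1))]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"))
  }, character(1))
  writeLines(c(as.character(header), body), path)
  invisible(path)
}

#' Read a JSON-lines characterization-record archive
#'
#' @param path JSONL file written by [write_ts_records()].
#' @return records tibble.
#' @export
read_ts_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .stop2("empty records file: ", path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, .RECORDS_FORMAT)) {
    .stop2("not an ersnet records file (header format '", header$format, "')")
  }
  if (header$version > .RECORDS_VERSION) {
    .stop2("records file version ", header$version, " is newer than supported")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(.empty_records())
  rows <- lapply(body, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble::tibble(
      reactant_key = rec$reactant_key,
      product_key = rec$product_key,
      conformer_index = as.integer(rec$conformer_index),
      level = rec$level,
      converged = isTRUE(rec$converged),
      delta_g_act = if (is.null(rec$delta_g_act)) NA_real_ else as.numeric(rec$delta_g_act),
      gradient_calls = as.integer(rec$gradient_calls),
      irc_reactant_key = if (is.null(rec$irc_reactant_key)) NA_character_ else rec$irc_reactant_key,
      irc_product_key = if (is.null(rec$irc_product_key)) NA_character_ else rec$irc_product_key
    )
  })
  dplyr::bind_rows(rows)
}
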