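# XYZ structure I/O and bond perception from Cartesian coordinates.
# Perception is the standard covalent-radius heuristic: a bond exists when
# the interatomic distance is below scale * (r_i + r_j); bond orders are then
# raised minimally (shortest bonds first) until every atom reaches an allowed
# valence. Needed to turn IRC endpoint geometries back into graphs.

# Covalent radii in Angstrom (Cordero et al. consensus values).
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)

#' Covalent radii used for bond perception
#' @return named numeric vector of radii in Angstrom.
#' @export
covalent_radii <- function() .COVALENT_RADII

#' Read an XYZ file
#'
#' Standard format: atom count, comment line, then `element x y z` rows.
#'
#' @param path file path.
#' @return list with `elements` (character), `coords` (numeric n x 3 matrix)
#'   and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) .stop2("malformed XYZ file: first line must be the atom count")
  if (length(lines) < n + 2) .stop2("malformed XYZ file: fewer rows than declared atoms")
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  elements <- vapply(rows, `[[`, character(1), 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(coords) || any(!is.finite(coords))) .stop2("non-finite coordinates in XYZ file")
  list(elements = elements, coords = coords, comment = lines[2])
}

#' Write an XYZ file
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 coordinate matrix (Angstrom).
#' @param path output path.
#' @param comment comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(elements, coords, path, comment = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(elements) == nrow(coords))
  lines <- c(length(elements), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f",
                     elements, coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Perceive a molecular graph from elements and coordinates
#'
#' Bonds are assigned between atom pairs closer than
#' `scale * (r_cov(i) + r_cov(j))`; all perceived bonds start at order one and
#' orders are then raised greedily, shortest eligible bond first, until every
#' atom sits at an allowed valence. Raising a bond is eligible while at least
#' one endpoint is below an allowed valence and neither endpoint exceeds its
#' maximum. Fails with an error listing the offending atoms when no
#' valence-valid assignment is reached.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 coordinate matrix in Angstrom.
#' @param scale covalent-radius scale factor (default 1.2).
#' @param radii named numeric vector of covalent radii (Angstrom).
#' @param label provenance label for the result.
#' @return a valence-valid `molgraph`.
#' @export
#' @examples
#' h2 <- perceive_graph(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' bond_list(h2)
perceive_graph <- function(elements, coords, scale = 1.2,
                           radii = covalent_radii(), label = "") {
  bad <- setdiff(unique(elements), names(radii))
  if (length(bad)) .stop2("unsupported element(s): ", paste(bad, collapse = ", "))
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  stopifnot(nrow(coords) == n)
  if (any(!is.finite(coords))) .stop2("non-finite coordinates")
  bonds <- matrix(0L, n, n)
  dist <- matrix(Inf, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        dist[i, j] <- dist[j, i] <- d
        if (d < scale * (radii[[elements[i]]] + radii[[elements[j]]])) {
          bonds[i, j] <- bonds[j, i] <- 1L
        }
      }
    }
  }
  satisfied <- function(v) {
    vapply(seq_len(n), function(a) v[a] %in% .ALLOWED_VALENCES[[elements[a]]],
           logical(1))
  }
  maxval <- vapply(elements, function(e) max(.ALLOWED_VALENCES[[e]]), integer(1))
  repeat {
    v <- as.integer(rowSums(bonds))
    ok <- satisfied(v)
    if (all(ok)) break
    # candidate raises: existing bond, an unsatisfied endpoint, both below max
    cand <- which(upper.tri(bonds) & bonds > 0, arr.ind = TRUE)
    if (nrow(cand)) {
      keep <- vapply(seq_len(nrow(cand)), function(r) {
        i <- cand[r, 1]; j <- cand[r, 2]
        (!ok[i] || !ok[j]) && v[i] < maxval[i] && v[j] < maxval[j]
      }, logical(1))
      cand <- cand[keep, , drop = FALSE]
    }
    if (!nrow(cand)) {
      .stop2("bond perception failed: no valence-valid order assignment for atom(s) ",
             paste(which(!ok), collapse = ", "),
             " (", paste(elements[!ok], collapse = ", "), ")")
    }
    d <- vapply(seq_len(nrow(cand)), function(r) dist[cand[r, 1], cand[r, 2]],
                numeric(1))
    r <- which.min(d)
    i <- cand[r, 1]; j <- cand[r, 2]
    bonds[i, j] <- bonds[i, j] + 1L
    bonds[j, i] <- bonds[i, j]
  }
  molgraph(elements, bonds, label = label)
}

#' Read an XYZ file and perceive its molecular graph
#'
#' Convenience wrapper around [read_xyz()] and [perceive_graph()].
#'
#' @param path XYZ file path.
#' @inheritParams perceive_graph
#' @return a valence-valid `molgraph` labelled with the file name.
#' @export
read_xyz_graph <- function(path, scale = 1.2, radii = covalent_radii()) {
  x <- read_xyz(path)
  perceive_graph(x$elements, x$coords, scale = scale, radii = radii,
                 label = basename(path))
}
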