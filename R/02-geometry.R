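#' Molecular geometry
#'
#' A validated set of atoms: element symbols, nuclear charges and Cartesian
#' positions in bohr. Atom indices are 1-based in all user-facing reports.
#'
#' @param element character vector of element symbols
#' @param xyz N x 3 numeric matrix of positions in bohr
#' @param z optional integer nuclear charges; derived from `element` if missing
#' @return an object of class `geometry`
#' @export
geometry <- function(element, xyz, z = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  if (length(element) != nrow(xyz)) {
    stop("element and xyz disagree on the number of atoms")
  }
  if (nrow(xyz) < 1) stop("geometry needs at least one atom")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(z)) z <- element_z(element)
  if (nrow(xyz) > 1) {
    dmin <- min(stats::dist(xyz))
    if (dmin <= 1e-6) {
      stop(sprintf("coincident atoms: minimum pairwise distance %.3g bohr", dmin))
    }
  }
  structure(
    list(element = as.character(element), z = as.integer(z),
         xyz = unname(xyz)),
    class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms (bohr)\n", length(x$element)))
  for (i in seq_along(x$element)) {
    cat(sprintf("  %3d %-2s %12.6f %12.6f %12.6f\n", i, x$element[i],
                x$xyz[i, 1], x$xyz[i, 2], x$xyz[i, 3]))
  }
  invisible(x)
}

n_atoms <- function(geom) length(geom$element)

# Default 1-based atom labels used on condensed matrices and reports.
atom_labels <- function(geom) {
  paste0(geom$element, "(", seq_along(geom$element), ")")
}

#' Read an XYZ file (geometry only)
#'
#' Standard XYZ: atom count, comment line, then `symbol x y z` in Angstrom.
#'
#' @param path file path
#' @return a [geometry] with coordinates converted to bohr
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  rows <- lines[seq(3, 2 + n)]
  tok <- strsplit(trimws(rows), "\\s+")
  sym <- vapply(tok, `[[`, "", 1)
  xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  geometry(sym, angstrom_to_bohr(xyz))
}
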