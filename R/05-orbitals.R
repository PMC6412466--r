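# Spin-resolved molecular orbital sets.

#' Construct a spin orbital set
#'
#' Holds, per spin channel, AO x MO coefficient matrices, orbital energies in
#' hartree, and integer occupations (exactly 0 or 1 per spin orbital).
#' Within each channel, orbitals are sorted canonically: occupied before
#' virtual, each class by increasing energy.
#'
#' @param coeff list with `alpha` and `beta` AO x MO coefficient matrices
#' @param energy list with `alpha` and `beta` energy vectors (hartree)
#' @param occ list with `alpha` and `beta` occupation vectors (0/1)
#' @param restricted logical; `TRUE` when the two channels are duplicates of
#'   a spin-restricted solution
#' @return an object of class `spin_orbitals`
#' @export
spin_orbitals <- function(coeff, energy, occ, restricted = FALSE) {
  out <- list(coeff = list(), energy = list(), occ = list(),
              restricted = isTRUE(restricted))
  for (s in c("alpha", "beta")) {
    cs <- as.matrix(coeff[[s]])
    es <- as.numeric(energy[[s]])
    os <- as.numeric(occ[[s]])
    if (ncol(cs) != length(es) || ncol(cs) != length(os)) {
      stop("coefficients/energies/occupations disagree for channel ", s)
    }
    if (ncol(cs) > nrow(cs)) stop("more MOs than AOs in channel ", s)
    if (any(abs(os) > 1e-12 & abs(os - 1) > 1e-12)) {
      stop("fractional occupation in channel ", s,
           ": occupations must be exactly 0 or 1 per spin orbital")
    }
    os <- round(os)
    ord <- order(-os, es)
    out$coeff[[s]] <- cs[, ord, drop = FALSE]
    out$energy[[s]] <- es[ord]
    out$occ[[s]] <- as.integer(os[ord])
  }
  class(out) <- "spin_orbitals"
  out
}

#' @export
print.spin_orbitals <- function(x, ...) {
  cat(sprintf("spin_orbitals: %d AOs; N_occ(alpha) = %d, N_occ(beta) = %d%s\n",
              nrow(x$coeff$alpha), sum(x$occ$alpha), sum(x$occ$beta),
              if (x$restricted) " (restricted)" else ""))
  invisible(x)
}

n_occ <- function(mos, spin) sum(mos$occ[[spin]])

occupied_coeff <- function(mos, spin) {
  mos$coeff[[spin]][, mos$occ[[spin]] == 1, drop = FALSE]
}

virtual_coeff <- function(mos, spin) {
  mos$coeff[[spin]][, mos$occ[[spin]] == 0, drop = FALSE]
}

#' Validate MO orthonormality against an AO overlap matrix
#'
#' @param mos a [spin_orbitals]
#' @param overlap symmetric positive-definite AO overlap matrix
#' @param tolerance flag a channel whose residual `max |C' S C - I|` exceeds
#'   this (default `1e-6`)
#' @return list with per-channel residuals, flags, and the tolerance; class
#'   `orbital_validation`
#' @export
validate_orbitals <- function(mos, overlap, tolerance = 1e-6) {
  overlap <- as.matrix(overlap)
  if (nrow(overlap) != nrow(mos$coeff$alpha)) {
    stop("overlap dimension does not match the AO dimension")
  }
  if (max(abs(overlap - t(overlap))) > 1e-8) stop("overlap matrix is not symmetric")
  res <- lapply(c(alpha = "alpha", beta = "beta"), function(s) {
    cs <- mos$coeff[[s]]
    g <- crossprod(cs, overlap %*% cs)
    max(abs(g - diag(ncol(cs))))
  })
  structure(
    list(residual = unlist(res), flagged = unlist(res) > tolerance,
         tolerance = tolerance),
    class = "orbital_validation")
}

#' @export
print.orbital_validation <- function(x, ...) {
  for (s in names(x$residual)) {
    cat(sprintf("  %-5s max |C'SC - I| = %.3e %s\n", s, x$residual[s],
                if (x$flagged[s]) "FLAGGED" else "ok"))
  }
  invisible(x)
}

#' Write an orbital validation report as JSON
#' @param validation an `orbital_validation`
#' @param path output path
#' @export
write_validation_json <- function(validation, path) {
  jsonlite::write_json(
    list(residual = as.list(validation$residual),
         flagged = as.list(validation$flagged),
         tolerance = validation$tolerance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
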