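# Molden format reader and writer.
#
# Supported sections: [Atoms] (AU / Angs), [GTO] (s, p, d, f, g and combined
# sp shells), [MO] with Sym= / Ene= / Spin= / Occup= headers, and the
# spherical-component markers [5D], [5D7F], [5D10F], [7F], [9G], plus the
# Cartesian markers [6D], [10F]. Restricted files (a single spin channel,
# occupations 0/2) are duplicated into identical alpha/beta channels.

#' Read a Molden orbital file
#'
#' @param path file path
#' @param normalization_tolerance maximum allowed deviation of a contracted
#'   shell's self-overlap from 1 before renormalization; beyond it the file
#'   is rejected naming the shell (default `0.2`)
#' @return list with `geometry` ([geometry]), `shells` (list of
#'   [gaussian_shell]) and `mos` ([spin_orbitals])
#' @export
read_molden <- function(path, normalization_tolerance = 0.2) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  secline <- grepl("^\\s*\\[", lines)
  secname <- toupper(gsub("^\\s*\\[([^]]+)\\].*$", "\\1", lines))
  secname[!secline] <- ""

  find_section <- function(name) which(secline & secname == toupper(name))
  section_body <- function(start) {
    if (length(start) == 0) return(character(0))
    start <- start[1]
    nxt <- which(secline & seq_along(lines) > start)
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    if (end < start + 1) character(0) else lines[(start + 1):end]
  }

  for (need in c("ATOMS", "GTO", "MO")) {
    if (length(find_section(need)) == 0) {
      stop("Molden parse error: missing [", need, "] section in ", path)
    }
  }

  pure_d <- any(secname %in% c("5D", "5D7F", "5D10F"))
  pure_f <- any(secname %in% c("7F", "5D7F")) ||
    (any(secname == "5D") && !any(secname == "10F"))
  pure_g <- any(secname == "9G")
  if (any(secname == "6D")) pure_d <- FALSE
  if (any(secname == "10F")) pure_f <- FALSE

  # ---- [Atoms] ----
  hdr <- lines[find_section("ATOMS")[1]]
  ang <- grepl("angs", tolower(hdr))
  rows <- Filter(nzchar, trimws(section_body(find_section("ATOMS"))))
  tok <- strsplit(rows, "\\s+")
  sym <- vapply(tok, `[[`, "", 1)
  zval <- vapply(tok, function(t) as.numeric(t[3]), numeric(1))
  xyz <- t(vapply(tok, function(t) as.numeric(t[4:6]), numeric(3)))
  if (ang) xyz <- angstrom_to_bohr(xyz)
  geom <- geometry(sym, xyz, z = zval)

  # ---- [GTO] ----
  gto <- section_body(find_section("GTO"))
  gto <- sub("D(?=[+-]\\d)", "E", gto, perl = TRUE)  # Fortran exponents
  shells <- list()
  i <- 1
  while (i <= length(gto)) {
    ln <- trimws(gto[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    t <- strsplit(ln, "\\s+")[[1]]
    atom <- suppressWarnings(as.integer(t[1]))
    if (is.na(atom)) stop("Molden parse error in [GTO] near: ", ln)
    i <- i + 1
    repeat {
      if (i > length(gto) || !nzchar(trimws(gto[i]))) { i <- i + 1; break }
      t <- strsplit(trimws(gto[i]), "\\s+")[[1]]
      stype <- tolower(t[1])
      nprim <- as.integer(t[2])
      prim <- t(vapply((i + 1):(i + nprim), function(j) {
        as.numeric(strsplit(trimws(gto[j]), "\\s+")[[1]])
      }, numeric(if (stype == "sp") 3 else 2)))
      prim <- matrix(prim, nrow = nprim)
      i <- i + nprim + 1
      lmap <- c(s = 0L, p = 1L, d = 2L, f = 3L, g = 4L)
      if (stype == "sp") {
        shells <- c(shells,
                    list(.checked_shell(atom, 0L, prim[, 1], prim[, 2], TRUE,
                                        normalization_tolerance, length(shells) + 1),
                         .checked_shell(atom, 1L, prim[, 1], prim[, 3], TRUE,
                                        normalization_tolerance, length(shells) + 2)))
      } else {
        l <- lmap[stype]
        if (is.na(l)) stop("unsupported shell type '", stype, "' in [GTO]")
        pure <- switch(stype, d = pure_d, f = pure_f, g = pure_g, TRUE)
        shells <- c(shells,
                    list(.checked_shell(atom, l, prim[, 1], prim[, 2], pure,
                                        normalization_tolerance, length(shells) + 1)))
      }
    }
  }
  nao <- n_ao(shells)

  # ---- [MO] ----
  mo <- section_body(find_section("MO"))
  orbs <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur$coef_idx)) {
      v <- numeric(nao)
      v[cur$coef_idx] <- cur$coef_val
      orbs[[length(orbs) + 1]] <<- list(energy = cur$energy, spin = cur$spin,
                                        occ = cur$occ, coef = v)
    }
  }
  for (ln in mo) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (grepl("^(Sym|Ene|Spin|Occup)\\s*=", t, ignore.case = TRUE)) {
      key <- tolower(sub("\\s*=.*$", "", t))
      val <- trimws(sub("^[^=]*=", "", t))
      if (key == "sym") {
        flush()
        cur <- list(energy = NA_real_, spin = "alpha", occ = NA_real_,
                    coef_idx = integer(0), coef_val = numeric(0))
      }
      if (is.null(cur)) {
        cur <- list(energy = NA_real_, spin = "alpha", occ = NA_real_,
                    coef_idx = integer(0), coef_val = numeric(0))
      }
      if (key == "ene") cur$energy <- as.numeric(val)
      if (key == "spin") cur$spin <- tolower(val)
      if (key == "occup") cur$occ <- as.numeric(val)
    } else {
      p <- strsplit(t, "\\s+")[[1]]
      if (length(p) >= 2) {
        cur$coef_idx <- c(cur$coef_idx, as.integer(p[1]))
        cur$coef_val <- c(cur$coef_val, as.numeric(p[2]))
      }
    }
  }
  flush()
  if (length(orbs) == 0) stop("Molden parse error: empty [MO] section")

  spins <- vapply(orbs, `[[`, "", "spin")
  occs <- vapply(orbs, `[[`, 0, "occ")
  restricted <- !any(spins == "beta")
  pack <- function(sel) {
    list(coef = vapply(orbs[sel], `[[`, numeric(nao), "coef"),
         energy = vapply(orbs[sel], `[[`, 0, "energy"),
         occ = occs[sel])
  }
  if (restricted) {
    if (any(abs(occs) > 1e-12 & abs(occs - 2) > 1e-12)) {
      stop("unsupported input: restricted Molden file with occupation not in {0, 2} ",
           "(fractional or ROHF occupations are rejected)")
    }
    a <- pack(seq_along(orbs))
    a$coef <- matrix(a$coef, nrow = nao)
    mos <- spin_orbitals(coeff = list(alpha = a$coef, beta = a$coef),
                         energy = list(alpha = a$energy, beta = a$energy),
                         occ = list(alpha = a$occ / 2, beta = a$occ / 2),
                         restricted = TRUE)
  } else {
    if (any(abs(occs) > 1e-12 & abs(occs - 1) > 1e-12)) {
      stop("unsupported input: unrestricted Molden file with fractional occupation")
    }
    a <- pack(which(spins != "beta"))
    b <- pack(which(spins == "beta"))
    mos <- spin_orbitals(
      coeff = list(alpha = matrix(a$coef, nrow = nao),
                   beta = matrix(b$coef, nrow = nao)),
      energy = list(alpha = a$energy, beta = b$energy),
      occ = list(alpha = a$occ, beta = b$occ))
  }
  list(geometry = geom, shells = shells, mos = mos)
}

# Build a shell, rejecting grossly unnormalized contractions.
.checked_shell <- function(atom, l, expo, coef, pure, tol, shell_index) {
  ap <- outer(expo, expo, function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
  nrm2 <- as.numeric(t(coef) %*% ap %*% coef)
  if (abs(nrm2 - 1) > tol) {
    stop(sprintf(
      "validation error: shell %d (l = %d on atom %d) has self-overlap %.4f; AO is unnormalized beyond tolerance %.2g",
      shell_index, l, atom, nrm2, tol))
  }
  gaussian_shell(atom, l, expo, coef, pure = pure, normalize = TRUE)
}

#' Write a Molden orbital file
#'
#' @param geom a [geometry]
#' @param shells list of [gaussian_shell]
#' @param mos a [spin_orbitals]
#' @param path output path
#' @export
write_molden <- function(geom, shells, mos, path) {
  out <- c("[Molden Format]", "[Atoms] AU")
  for (i in seq_along(geom$element)) {
    out <- c(out, sprintf("%-3s %4d %4d %20.12e %20.12e %20.12e",
                          geom$element[i], i, geom$z[i],
                          geom$xyz[i, 1], geom$xyz[i, 2], geom$xyz[i, 3]))
  }
  out <- c(out, "[GTO]")
  lsym <- c("s", "p", "d", "f", "g")
  for (a in seq_along(geom$element)) {
    out <- c(out, sprintf("%4d 0", a))
    for (sh in shells) {
      if (sh$center_atom != a) next
      out <- c(out, sprintf(" %s %4d 1.00", lsym[sh$l + 1], length(sh$exponents)))
      out <- c(out, sprintf("  %20.12e %20.12e", sh$exponents, sh$coefficients))
    }
    out <- c(out, "")
  }
  if (any(vapply(shells, function(s) s$pure && s$l >= 2, logical(1)))) {
    out <- c(out, "[5D7F]", "[9G]")
  }
  out <- c(out, "[MO]")
  emit <- function(spin) {
    cs <- mos$coeff[[spin]]
    for (k in seq_len(ncol(cs))) {
      out <<- c(out,
                sprintf(" Sym= a%d", k),
                sprintf(" Ene= %20.12e", mos$energy[[spin]][k]),
                sprintf(" Spin= %s", if (spin == "alpha") "Alpha" else "Beta"),
                sprintf(" Occup= %.1f",
                        if (mos$restricted) 2 * mos$occ[[spin]][k]
                        else as.numeric(mos$occ[[spin]][k])),
                sprintf(" %4d %20.12e", seq_len(nrow(cs)), cs[, k]))
    }
  }
  emit("alpha")
  if (!mos$restricted) emit("beta")
  writeLines(out, path)
  invisible(path)
}
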