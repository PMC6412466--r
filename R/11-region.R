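# Threshold section analysis of condensed response matrices, QM-region
# suggestion from reaction-center atoms, and model-error reports.

#' Threshold sections of a condensed response matrix
#'
#' Marks atom pairs whose entries exceed a signed threshold: `K > tau` for
#' sign `"+"`, `K < -tau` for sign `"-"`. Sections at looser thresholds are
#' nested inside tighter ones (0.1 within 0.01 within 0.001).
#'
#' @param lrf a `condensed_lrf`
#' @param tau threshold magnitude (> 0); canonical values 0.1, 0.01, 0.001
#' @param sign `"+"` or `"-"`
#' @return an object of class `section_set` with the boolean `members`
#'   matrix and per-atom membership counts
#' @export
threshold_sections <- function(lrf, tau, sign = c("+", "-")) {
  stopifnot(inherits(lrf, "condensed_lrf"))
  sign <- match.arg(sign)
  if (tau <= 0) stop("tau must be positive")
  members <- if (sign == "+") lrf$matrix > tau else lrf$matrix < -tau
  structure(
    list(tau = tau, sign = sign, members = members,
         atom_counts = rowSums(members), labels = lrf$labels,
         kind = lrf$kind),
    class = "section_set")
}

#' @export
print.section_set <- function(x, ...) {
  cat(sprintf("section_set (%s, sign %s, tau = %g): %d of %d pairs marked\n",
              x$kind, x$sign, x$tau, sum(x$members), length(x$members)))
  invisible(x)
}

# Per-atom coupling scores against a reaction-center set.
.rc_scores <- function(lrf, rc) {
  apply(abs(lrf$matrix[rc, , drop = FALSE]), 2, max)
}

# Covalent connectivity: bond when distance < 1.3 x sum of covalent radii.
.connectivity <- function(geom, scale = 1.3) {
  nat <- n_atoms(geom)
  rad <- covalent_radius(geom$element)
  bonds <- matrix(FALSE, nat, nat)
  if (nat > 1) {
    d <- as.matrix(stats::dist(geom$xyz))
    lim <- scale * outer(rad, rad, "+")
    bonds <- d < lim & d > 0
  }
  bonds
}

#' Suggest a QM region from reaction-center atoms
#'
#' Atom `J` enters the QM region when its maximum response coupling to any
#' reaction-center atom reaches either threshold:
#' `max over I in RC of |K_rho[I, J]| >= tau_rho` or
#' `max over I in RC of |K_z[I, J]| >= tau_m`. With `complete_fragments`,
#' the selection is expanded to whole covalently connected fragments (bond:
#' distance < 1.3 x sum of covalent radii) so cut points are chemically
#' cappable; bonds crossing the final boundary are reported as the cut-bond
#' list rather than edited.
#'
#' @param k_rho density `condensed_lrf`
#' @param k_z spin `condensed_lrf` on the same atom labeling
#' @param rc reaction-center atom indices (non-empty)
#' @param tau_rho,tau_m selection thresholds (defaults 0.01, the criteria
#'   used for boundary placement)
#' @param complete_fragments expand to whole covalent fragments
#' @param geom geometry, required when `complete_fragments = TRUE`
#' @return an object of class `region_suggestion`
#' @export
suggest_qm_region <- function(k_rho, k_z, rc, tau_rho = 0.01, tau_m = 0.01,
                              complete_fragments = FALSE, geom = NULL) {
  stopifnot(inherits(k_rho, "condensed_lrf"), inherits(k_z, "condensed_lrf"))
  nat <- nrow(k_rho$matrix)
  if (!identical(k_rho$labels, k_z$labels)) {
    stop("density and spin matrices do not share an atom labeling")
  }
  if (length(rc) == 0) stop("reaction-center set must be non-empty")
  if (!all(rc %in% seq_len(nat))) stop("reaction-center atom outside the system")
  c_rho <- .rc_scores(k_rho, rc)
  c_z <- .rc_scores(k_z, rc)
  rule <- rep("", nat)
  rule[c_z >= tau_m] <- "spin"
  rule[c_rho >= tau_rho] <- "density"
  rule[c_rho >= tau_rho & c_z >= tau_m] <- "density+spin"
  rule[rc] <- "reaction_center"
  selected <- which(nzchar(rule))
  cut_bonds <- NULL
  if (complete_fragments) {
    if (is.null(geom)) stop("fragment completion requires a geometry")
    bonds <- .connectivity(geom)
    repeat {
      grow <- which(!nzchar(rule) &
                      apply(bonds[, selected, drop = FALSE], 1, any))
      if (length(grow) == 0) break
      rule[grow] <- "fragment"
      selected <- which(nzchar(rule))
    }
  } else if (!is.null(geom)) {
    bonds <- .connectivity(geom)
    outside <- setdiff(seq_len(nat), selected)
    cb <- which(bonds[selected, outside, drop = FALSE], arr.ind = TRUE)
    if (length(cb)) {
      cut_bonds <- data.frame(inside = selected[cb[, 1]],
                              outside = outside[cb[, 2]])
    }
  }
  structure(
    list(rc = sort(unique(rc)), selected = selected, rule = rule,
         score_rho = c_rho, score_z = c_z,
         tau_rho = tau_rho, tau_m = tau_m,
         complete_fragments = complete_fragments,
         cut_bonds = cut_bonds, labels = k_rho$labels),
    class = "region_suggestion")
}

#' @export
print.region_suggestion <- function(x, ...) {
  cat(sprintf("QM region suggestion (tau_rho = %g, tau_m = %g): %d of %d atoms\n",
              x$tau_rho, x$tau_m, length(x$selected), length(x$rule)))
  for (j in x$selected) {
    cat(sprintf("  %-8s %-14s c_rho = %.4g  c_z = %.4g\n",
                x$labels[j], x$rule[j], x$score_rho[j], x$score_z[j]))
  }
  if (!is.null(x$cut_bonds) && nrow(x$cut_bonds)) {
    cat("  cut bonds (inside-outside):",
        paste(sprintf("%d-%d", x$cut_bonds$inside, x$cut_bonds$outside),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Model-error report between a cluster model and a full model
#'
#' Per-atom differences `model - full` for condensed densities and spin
#' densities over an explicit injective atom map.
#'
#' @param full list with per-atom `rho` and `rhoz` vectors of the full model
#' @param model same for the cluster model
#' @param atom_map data.frame/matrix with columns `model` and `full`
#'   (1-based indices), injective from model atoms into full-model atoms
#' @param label optional model label carried into the report
#' @return an object of class `model_error_report` with `delta_rho`,
#'   `delta_rhoz` and max-|error| summaries
#' @export
model_error_report <- function(full, model, atom_map, label = "model") {
  atom_map <- as.data.frame(atom_map)
  if (!all(c("model", "full") %in% names(atom_map))) {
    stop("atom_map needs columns `model` and `full`")
  }
  if (anyDuplicated(atom_map$model) || anyDuplicated(atom_map$full)) {
    stop("atom_map must be injective")
  }
  if (any(atom_map$model > length(model$rho)) ||
      any(atom_map$full > length(full$rho)) ||
      any(atom_map$model < 1) || any(atom_map$full < 1)) {
    stop("atom_map references an unmapped atom")
  }
  d_rho <- unname(model$rho[atom_map$model] - full$rho[atom_map$full])
  d_rhoz <- unname(model$rhoz[atom_map$model] - full$rhoz[atom_map$full])
  structure(
    list(label = label, atom_map = atom_map,
         delta_rho = d_rho, delta_rhoz = d_rhoz,
         max_abs_rho = if (length(d_rho)) max(abs(d_rho)) else 0,
         max_abs_rhoz = if (length(d_rhoz)) max(abs(d_rhoz)) else 0,
         direction = "model - full"),
    class = "model_error_report")
}

#' @export
print.model_error_report <- function(x, ...) {
  cat(sprintf("model_error_report [%s] (errors are %s)\n", x$label, x$direction))
  tab <- data.frame(model_atom = x$atom_map$model, full_atom = x$atom_map$full,
                    delta_rho = x$delta_rho, delta_rhoz = x$delta_rhoz)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("  max |delta rho| = %.4g   max |delta rho_z| = %.4g\n",
              x$max_abs_rho, x$max_abs_rhoz))
  invisible(x)
}

#' Export a condensed response matrix for heat-map rendering
#'
#' Writes the atom-labeled matrix as CSV plus a JSON sidecar carrying the
#' canonical isosurface/section thresholds and the color rule (positive:
#' blue, negative: red); rendering is delegated to external tools.
#'
#' @param lrf a `condensed_lrf`
#' @param path output CSV path; the sidecar is `<path>.json`
#' @param thresholds section thresholds recorded in the sidecar
#' @param color_rule named list recorded verbatim in the sidecar
#' @return the CSV path, invisibly
#' @export
heatmap_export <- function(lrf, path, thresholds = c(0.1, 0.01, 0.001),
                           color_rule = list(positive = "blue", negative = "red")) {
  write_lrf_csv(lrf, path)
  jsonlite::write_json(
    list(kind = lrf$kind, thresholds = thresholds, color_rule = color_rule,
         provenance = lrf$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a heat-map CSV as a plain matrix
#' @param path CSV written by [heatmap_export] or [write_lrf_csv]
#' @return numeric matrix with atom-label dimnames
#' @export
read_lrf_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
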