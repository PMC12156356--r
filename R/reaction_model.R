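## Pairwise reaction assessment: electrophilicity difference and polarity,
## direction of electron-density flux, and regiochemistry prediction.

#' Electrophilicity difference of a reacting pair
#'
#' \eqn{\Delta\omega = |\omega_A - \omega_B|}, the polarity index of a
#' cycloaddition: large differences mean strongly asymmetric
#' electron-density reorganization at the transition state.
#'
#' @param gi_a,gi_b [global_indices()] objects (or numeric \eqn{\omega}
#'   values).
#' @return nonnegative difference in eV; symmetric in its arguments.
#' @export
delta_omega <- function(gi_a, gi_b) {
  wa <- if (inherits(gi_a, "global_indices")) gi_a$omega else as.numeric(gi_a)
  wb <- if (inherits(gi_b, "global_indices")) gi_b$omega else as.numeric(gi_b)
  abs(wa - wb)
}

#' Polar versus non-polar classification
#'
#' A cycloaddition between a strong nucleophile and a strong electrophile
#' is predicted to proceed through a polar mechanism when
#' \eqn{\Delta\omega} strictly exceeds the threshold (default 1 eV);
#' otherwise a non-polar pathway is predicted. A value exactly at the
#' threshold is classified non-polar with `borderline = TRUE` (strict
#' reading of the "> 1 eV" rule).
#'
#' @param dw nonnegative \eqn{\Delta\omega} in eV (vectorized).
#' @param threshold polarity threshold in eV.
#' @return list with character vector `polarity` (`"polar"`/`"nonpolar"`)
#'   and logical vector `borderline`.
#' @export
classify_polarity <- function(dw, threshold = 1.0) {
  if (any(!is.finite(dw)) || any(dw < 0))
    stop("delta-omega must be finite and nonnegative", call. = FALSE)
  list(polarity = ifelse(dw > threshold, "polar", "nonpolar"),
       borderline = dw == threshold)
}

#' Direction of electron-density flux
#'
#' Electron density flows downhill in chemical potential. When
#' \eqn{\mu_{diene} > \mu_{dienophile}} the flux runs diene to dienophile —
#' forward electron density flux (FEDF), the normal-demand situation;
#' the opposite ordering is the reverse flux. Differences within `tol`
#' are reported as undetermined to keep floating-point noise from flipping
#' the sign.
#'
#' @param mu_diene,mu_dienophile chemical potentials in eV.
#' @param tol dead-band half-width in eV.
#' @return `"forward"`, `"reverse"` or `"undetermined"` (vectorized).
#' @export
flux_direction <- function(mu_diene, mu_dienophile, tol = 1e-6) {
  if (any(!is.finite(mu_diene)) || any(!is.finite(mu_dienophile)))
    stop("chemical potentials must be finite", call. = FALSE)
  d <- mu_diene - mu_dienophile
  ifelse(d > tol, "forward", ifelse(d < -tol, "reverse", "undetermined"))
}

#' Predicted regiochemistry of a diene/dienophile pair
#'
#' In a polar cycloaddition the dominant two-center interaction couples
#' the diene's most nucleophilic atom with the dienophile's most
#' electrophilic atom; the predicted first-formed bond is that atom pair.
#' Tie flags from either center search propagate to `borderline`.
#'
#' @param li_diene [local_indices()] of the diene, with `$centers` (see
#'   [local_analysis()]) or computable via [reactive_centers()].
#' @param li_dienophile [local_indices()] of the dienophile, likewise.
#' @return list with `bond_pair` (diene atom index, dienophile atom
#'   index), `regio_label` (e.g. `"C4-C2"`), and `borderline`.
#' @export
predict_regiochemistry <- function(li_diene, li_dienophile) {
  stopifnot(inherits(li_diene, "local_indices"),
            inherits(li_dienophile, "local_indices"))
  cd <- if (!is.null(li_diene$centers)) li_diene$centers
  else reactive_centers(li_diene)
  cp <- if (!is.null(li_dienophile$centers)) li_dienophile$centers
  else reactive_centers(li_dienophile)
  if (is.na(cd$top_nucleophilic_atom))
    stop("diene ", li_diene$species_id,
         " has no nucleophilicity data (missing N scale?)", call. = FALSE)
  a_d <- cd$top_nucleophilic_atom
  a_p <- cp$top_electrophilic_atom
  lab <- function(li, atom) {
    sym <- li$table$symbol[atom]
    if (is.na(sym)) paste0("a", atom) else paste0(sym, atom)
  }
  list(bond_pair = c(diene_atom = a_d, dienophile_atom = a_p),
       regio_label = paste0(lab(li_diene, a_d), "-", lab(li_dienophile, a_p)),
       borderline = cd$tie_nucleophilic || cp$tie_electrophilic)
}

#' Assess every diene/dienophile combination
#'
#' Cartesian product of the two lists in deterministic diene-major order.
#' Each pair gets \eqn{\Delta\omega}, the polarity class, the flux
#' direction and the predicted bond pair.
#'
#' @param dienes,dienophiles lists of [calc_record()] objects.
#' @param reference TCE reference record for the N scale.
#' @param threshold polarity threshold in eV.
#' @param thresholds scale cut-offs, see [default_thresholds()].
#' @return data.frame of class `reaction_table`, one row per pair:
#'   `diene_id`, `dienophile_id`, `delta_omega`, `polarity`, `flux`,
#'   `diene_atom`, `dienophile_atom`, `regio_label`, `borderline`.
#' @export
assess_all <- function(dienes, dienophiles, reference = NULL, threshold = 1.0,
                       thresholds = default_thresholds()) {
  if (inherits(dienes, "calc_record")) dienes <- list(dienes)
  if (inherits(dienophiles, "calc_record")) dienophiles <- list(dienophiles)
  if (length(dienes) == 0L || length(dienophiles) == 0L)
    stop("both species lists must be nonempty", call. = FALSE)
  ids_d <- vapply(dienes, `[[`, "", "species_id")
  ids_p <- vapply(dienophiles, `[[`, "", "species_id")
  dup <- intersect(ids_d, ids_p)
  if (length(dup))
    stop("species_id used in both roles: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ids_d) || anyDuplicated(ids_p))
    stop("duplicate species_id within a role", call. = FALSE)
  la_d <- lapply(dienes, local_analysis, reference = reference,
                 thresholds = thresholds)
  la_p <- lapply(dienophiles, local_analysis, reference = reference,
                 thresholds = thresholds)
  mu_d <- vapply(dienes, function(r) chemical_potential(r$e_homo, r$e_lumo), 0)
  mu_p <- vapply(dienophiles, function(r) chemical_potential(r$e_homo, r$e_lumo), 0)
  rows <- vector("list", length(dienes) * length(dienophiles))
  k <- 0L
  for (i in seq_along(dienes)) {
    for (j in seq_along(dienophiles)) {
      k <- k + 1L
      dw <- delta_omega(la_d[[i]]$omega, la_p[[j]]$omega)
      pol <- classify_polarity(dw, threshold)
      regio <- predict_regiochemistry(la_d[[i]], la_p[[j]])
      rows[[k]] <- data.frame(
        diene_id = ids_d[i], dienophile_id = ids_p[j], delta_omega = dw,
        polarity = pol$polarity, flux = flux_direction(mu_d[i], mu_p[j]),
        diene_atom = regio$bond_pair[["diene_atom"]],
        dienophile_atom = regio$bond_pair[["dienophile_atom"]],
        regio_label = regio$regio_label,
        borderline = pol$borderline || regio$borderline,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reaction_table", class(out))
  out
}

#' @export
print.reaction_table <- function(x, ...) {
  cat(sprintf("<reaction_table> %d diene x dienophile assessments\n", nrow(x)))
  NextMethod()
}
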