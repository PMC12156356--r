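## Global conceptual-DFT reactivity indices from frontier-orbital energies,
## and the electrophilicity / nucleophilicity scale classification.

#' Electronic chemical potential
#'
#' Frontier-orbital estimate of the chemical potential,
#' \eqn{\mu \approx (E_{HOMO} + E_{LUMO})/2}. Electrons flow from the
#' species with the higher (less negative) potential to the lower one.
#'
#' @param e_homo,e_lumo orbital energies in eV (vectorized).
#' @return chemical potential in eV.
#' @examples
#' chemical_potential(-9, -1) # -5
#' @export
chemical_potential <- function(e_homo, e_lumo) {
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo)))
    stop("orbital energies must be finite", call. = FALSE)
  (e_homo + e_lumo) / 2
}

#' Chemical hardness
#'
#' \eqn{\eta \approx E_{LUMO} - E_{HOMO}}, the HOMO-LUMO gap. A zero or
#' negative gap makes every downstream index undefined, so it is rejected.
#'
#' @inheritParams chemical_potential
#' @return hardness in eV, strictly positive.
#' @export
chemical_hardness <- function(e_homo, e_lumo) {
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo)))
    stop("orbital energies must be finite", call. = FALSE)
  if (any(e_lumo <= e_homo))
    stop("degenerate frontier gap: e_lumo must exceed e_homo", call. = FALSE)
  e_lumo - e_homo
}

#' Global electrophilicity index
#'
#' \eqn{\omega = \mu^2 / 2\eta}: the stabilization energy a species gains
#' on acquiring electron density from the environment. Nonnegative and
#' invariant under a sign flip of \eqn{\mu}.
#'
#' @param mu chemical potential, eV.
#' @param eta chemical hardness, eV, positive.
#' @return electrophilicity in eV.
#' @export
global_electrophilicity <- function(mu, eta) {
  if (any(!is.finite(mu)) || any(!is.finite(eta)))
    stop("mu and eta must be finite", call. = FALSE)
  if (any(eta <= 0)) stop("eta must be positive", call. = FALSE)
  mu^2 / (2 * eta)
}

#' Global nucleophilicity index
#'
#' \eqn{N = E_{HOMO}(species) - E_{HOMO}(reference)} on the
#' tetracyanoethylene (TCE) scale: TCE, the archetypal strong electrophile,
#' anchors the zero so that ordinary nucleophiles get positive N.
#'
#' @param e_homo_species HOMO energy of the species, eV.
#' @param e_homo_reference HOMO energy of the scale reference (TCE), eV.
#' @return nucleophilicity in eV; zero for the reference itself.
#' @export
global_nucleophilicity <- function(e_homo_species, e_homo_reference) {
  if (any(!is.finite(e_homo_species)) || any(!is.finite(e_homo_reference)))
    stop("HOMO energies must be finite", call. = FALSE)
  e_homo_species - e_homo_reference
}

#' Default electrophilicity / nucleophilicity scale cut-offs
#'
#' Class boundaries (eV) for the standard reactivity scales: electrophiles
#' are strong at \eqn{\omega \ge 1.50}, moderate in `[0.80, 1.50)`, else
#' marginal; nucleophiles are strong at \eqn{N \ge 3.00}, moderate in
#' `[2.00, 3.00)`, else marginal, and flagged superstrong at
#' \eqn{N \ge 4.00}. Boundary values belong to the higher class.
#'
#' @return a list with components `omega` and `n`, each a named numeric
#'   vector of closed lower bounds.
#' @export
default_thresholds <- function() {
  list(omega = c(moderate = 0.80, strong = 1.50),
       n = c(moderate = 2.00, strong = 3.00, superstrong = 4.00))
}

.check_thresholds <- function(thresholds) {
  if (!is.list(thresholds) || !all(c("omega", "n") %in% names(thresholds)))
    stop("thresholds must be a list with components 'omega' and 'n'", call. = FALSE)
  for (comp in c("omega", "n")) {
    th <- thresholds[[comp]]
    if (is.unsorted(th, strictly = TRUE))
      stop("thresholds$", comp, " must be strictly increasing", call. = FALSE)
  }
  thresholds
}

#' Classify a species on the electrophilicity and nucleophilicity scales
#'
#' Deterministic mapping from \eqn{(\omega, N)} to class labels under the
#' configured cut-offs; values exactly on a boundary take the higher class.
#'
#' @param omega global electrophilicity, eV (vectorized).
#' @param n_index global nucleophilicity, eV (vectorized).
#' @param thresholds cut-off configuration, see [default_thresholds()].
#' @return list with character vectors `e_class` (marginal / moderate /
#'   strong) and `n_class` (marginal / moderate / strong / superstrong).
#' @export
classify_species <- function(omega, n_index, thresholds = default_thresholds()) {
  thresholds <- .check_thresholds(thresholds)
  grade <- function(x, cuts, base = "marginal") {
    labs <- c(base, names(cuts))
    idx <- vapply(x, function(v) sum(v >= cuts), integer(1)) + 1L
    labs[idx]
  }
  list(e_class = grade(omega, thresholds$omega),
       n_class = grade(n_index, thresholds$n))
}

#' Global reactivity indices for one record
#'
#' Computes \eqn{\mu}, \eqn{\eta}, \eqn{\omega} and (given a reference
#' record) \eqn{N} for a [calc_record()], plus the scale classes. If the
#' reference's `level_tag` differs from the record's, a warning is emitted
#' (mixing theory levels shifts the N scale) but the value is computed.
#'
#' @param record a [calc_record()].
#' @param reference the TCE reference [calc_record()] (role `"reference"`),
#'   or `NULL` to skip N.
#' @param thresholds see [default_thresholds()].
#' @return object of class `global_indices`: list with `species_id`, `mu`,
#'   `eta`, `omega`, `n_index`, `e_class`, `n_class`.
#' @export
global_indices <- function(record, reference = NULL,
                           thresholds = default_thresholds()) {
  stopifnot(inherits(record, "calc_record"))
  mu <- chemical_potential(record$e_homo, record$e_lumo)
  eta <- chemical_hardness(record$e_homo, record$e_lumo)
  omega <- global_electrophilicity(mu, eta)
  n_index <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "calc_record"))
    if (reference$role != "reference")
      stop("reference record must have role = 'reference'", call. = FALSE)
    if (!identical(reference$level_tag, record$level_tag))
      warning("level_tag of ", record$species_id,
              " differs from the reference's; N values may not be comparable")
    n_index <- global_nucleophilicity(record$e_homo, reference$e_homo)
  }
  cls <- classify_species(omega, if (is.na(n_index)) -Inf else n_index, thresholds)
  structure(
    list(species_id = record$species_id, mu = mu, eta = eta, omega = omega,
         n_index = n_index, e_class = cls$e_class,
         n_class = if (is.na(n_index)) NA_character_ else cls$n_class),
    class = "global_indices")
}

#' @export
print.global_indices <- function(x, ...) {
  cat(sprintf("<global_indices> %s\n", x$species_id))
  cat(sprintf("  mu = %.4f eV   eta = %.4f eV   omega = %.4f eV (%s)\n",
              x$mu, x$eta, x$omega, x$e_class))
  if (!is.na(x$n_index))
    cat(sprintf("  N  = %.4f eV (%s)\n", x$n_index, x$n_class))
  invisible(x)
}

#' Descriptor table for a set of records
#'
#' One row per species with \eqn{\mu}, \eqn{\eta}, \eqn{\omega}, \eqn{N}
#' and the scale classes — the tabulation users export next to their
#' species lists.
#'
#' @param records list of [calc_record()] objects.
#' @param reference optional TCE reference [calc_record()].
#' @inheritParams global_indices
#' @return data.frame with columns `species_id`, `role`, `mu`, `eta`,
#'   `omega`, `n_index`, `e_class`, `n_class`.
#' @export
descriptor_table <- function(records, reference = NULL,
                             thresholds = default_thresholds()) {
  if (inherits(records, "calc_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    gi <- global_indices(r, reference, thresholds)
    data.frame(species_id = gi$species_id, role = r$role, mu = gi$mu,
               eta = gi$eta, omega = gi$omega, n_index = gi$n_index,
               e_class = gi$e_class, n_class = gi$n_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
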