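## Local reactivity: Parr functions from radical-ion spin densities,
## per-atom electrophilicity / nucleophilicity, and reactive-center search.

#' Electrophilic and nucleophilic Parr functions
#'
#' The Parr functions distribute global reactivity over atoms using the
#' Mulliken atomic spin densities (ASD) of the vertical radical ions:
#' \eqn{P^+_k} is the ASD of the radical *anion* (where an incoming
#' electron localizes — the electrophilic map) and \eqn{P^-_k} the ASD of
#' the radical *cation* (where an electron is removed from — the
#' nucleophilic map). This cation/anion mapping is the standard convention;
#' reversing it silently flips every regiochemistry prediction. Raw ASD
#' vectors are renormalized to sum exactly 1; negative components (a known
#' artifact of Mulliken partitioning) are retained.
#'
#' @param record a [calc_record()] with both ASD vectors.
#' @return list with numeric vectors `p_plus` and `p_minus`, each summing
#'   to 1.
#' @export
parr_functions <- function(record) {
  stopifnot(inherits(record, "calc_record"))
  if (length(record$asd_anion) == 0L || length(record$asd_cation) == 0L)
    stop("Parr functions unavailable: species ", record$species_id,
         " lacks radical-ion spin densities", call. = FALSE)
  list(p_plus = record$asd_anion / sum(record$asd_anion),
       p_minus = record$asd_cation / sum(record$asd_cation))
}

#' Local reactivity indices
#'
#' Condenses the global indices onto atoms:
#' \eqn{\omega_k = P^+_k \cdot \omega} and \eqn{N_k = P^-_k \cdot N}.
#' By construction \eqn{\sum_k \omega_k = \omega} and
#' \eqn{\sum_k N_k = N}.
#'
#' @param parr output of [parr_functions()] (or a list with `p_plus`,
#'   `p_minus`).
#' @param gi a [global_indices()] object.
#' @param record optional originating [calc_record()]; supplies
#'   `reactive_atoms` and element symbols for the center search.
#' @return object of class `local_indices`: per-atom data.frame `table`
#'   (columns `atom`, `symbol`, `p_plus`, `p_minus`, `omega_k`, `n_k`)
#'   plus `species_id` and the candidate list.
#' @export
local_indices <- function(parr, gi, record = NULL) {
  stopifnot(inherits(gi, "global_indices"))
  p_plus <- parr$p_plus
  p_minus <- parr$p_minus
  if (length(p_plus) != length(p_minus))
    stop("p_plus and p_minus differ in length", call. = FALSE)
  n_atoms <- length(p_plus)
  if (!is.null(record)) {
    stopifnot(inherits(record, "calc_record"))
    if (length(record$asd_cation) != n_atoms)
      stop("Parr vectors do not match the record's atom count", call. = FALSE)
  }
  symbols <- if (!is.null(record) && !is.null(record$geometry))
    record$geometry$symbols else rep(NA_character_, n_atoms)
  candidates <- NULL
  if (!is.null(record)) {
    candidates <- record$reactive_atoms
    # default center search: all carbon atoms, when the geometry names them
    if (is.null(candidates) && !is.null(record$geometry))
      candidates <- which(record$geometry$symbols == "C")
  }
  if (is.null(candidates) || length(candidates) == 0L)
    candidates <- seq_len(n_atoms)
  tab <- data.frame(atom = seq_len(n_atoms), symbol = symbols,
                    p_plus = p_plus, p_minus = p_minus,
                    omega_k = p_plus * gi$omega,
                    n_k = if (is.na(gi$n_index)) NA_real_ else p_minus * gi$n_index,
                    stringsAsFactors = FALSE)
  structure(list(species_id = gi$species_id, table = tab,
                 candidates = as.integer(candidates),
                 omega = gi$omega, n_index = gi$n_index),
            class = "local_indices")
}

#' @export
print.local_indices <- function(x, ...) {
  cat(sprintf("<local_indices> %s (%d atoms)\n", x$species_id, nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# argmax restricted to candidates; negative Parr components are skipped
# unless nothing positive remains; ties -> lowest atom index, flagged
.top_site <- function(values, parr, candidates) {
  v <- values[candidates]
  p <- parr[candidates]
  keep <- p > 0
  if (!any(keep)) keep <- rep(TRUE, length(v))
  v[!keep] <- -Inf
  best <- max(v)
  hits <- candidates[which(v == best)]
  list(atom = min(hits), tie = length(hits) > 1L)
}

#' Most electrophilic and most nucleophilic centers
#'
#' Argmax of \eqn{\omega_k} and of \eqn{N_k} restricted to the candidate
#' atoms (the record's `reactive_atoms`, defaulting to all carbons).
#' Exact ties are broken toward the lowest atom index and flagged.
#'
#' @param li a [local_indices()] object.
#' @param candidates optional integer vector overriding the stored
#'   candidate list.
#' @return list with `top_electrophilic_atom`, `top_nucleophilic_atom`,
#'   and logical tie flags `tie_electrophilic`, `tie_nucleophilic`.
#' @export
reactive_centers <- function(li, candidates = NULL) {
  stopifnot(inherits(li, "local_indices"))
  if (is.null(candidates)) candidates <- li$candidates
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L)
    stop("candidate atom list is empty", call. = FALSE)
  if (any(candidates < 1L | candidates > nrow(li$table)))
    stop("candidate indices out of range", call. = FALSE)
  e <- .top_site(li$table$omega_k, li$table$p_plus, candidates)
  n <- if (all(is.na(li$table$n_k))) list(atom = NA_integer_, tie = FALSE)
  else .top_site(li$table$n_k, li$table$p_minus, candidates)
  list(top_electrophilic_atom = e$atom, top_nucleophilic_atom = n$atom,
       tie_electrophilic = e$tie, tie_nucleophilic = n$tie)
}

#' Full local-reactivity analysis of one record
#'
#' Convenience wrapper: Parr functions, local indices and reactive centers
#' in one call.
#'
#' @param record a [calc_record()].
#' @param reference TCE reference record for the N scale (optional).
#' @param thresholds see [default_thresholds()].
#' @return a [local_indices()] object with the reactive-center result
#'   attached as `$centers`.
#' @export
local_analysis <- function(record, reference = NULL,
                           thresholds = default_thresholds()) {
  gi <- global_indices(record, reference, thresholds)
  li <- local_indices(parr_functions(record), gi, record)
  li$centers <- reactive_centers(li)
  li
}
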