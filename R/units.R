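## Physical constants used throughout. All electronic energies are carried
## internally in eV; cube grids are in bohr, molecular geometries in Angstrom.

#' Unit conversion constants
#'
#' `HARTREE_TO_EV` converts hartree to electron-volt; `BOHR_TO_ANGSTROM`
#' converts bohr to Angstrom. Both are fixed in one place so that every
#' reader/writer and every descriptor uses the same values.
#'
#' @format Numeric scalars.
#' @name units
NULL

#' @rdname units
#' @export
HARTREE_TO_EV <- 27.2114

#' @rdname units
#' @export
BOHR_TO_ANGSTROM <- 0.52917721

#' Convert energies between hartree and eV
#'
#' @param x numeric vector of energies.
#' @return numeric vector in the target unit.
#' @examples
#' ev_to_hartree(hartree_to_ev(-0.25)) # -0.25
#' @export
hartree_to_ev <- function(x) {
  stopifnot(is.numeric(x))
  x * HARTREE_TO_EV
}

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x) {
  stopifnot(is.numeric(x))
  x / HARTREE_TO_EV
}

## Seed-stable RNG scope: evaluates `expr` under set.seed(seed) and restores
## the caller's RNG state afterwards, so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
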