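## Deterministic generators for every fixture the pipeline consumes:
## calculation records with prescribed descriptor values, spin-density
## vectors with prescribed site symmetry, Hammett series with a known
## linear law, and analytic Gaussian densities with known basin integrals.
## All randomness is Mersenne-Twister under a caller-supplied seed, one
## stream per generator call; identical arguments give identical output.

#' Default fixture substituent set
#'
#' Eight common para substituents spanning strong donors to the nitro
#' group (`sigma_p` from -0.27 to 0.78), the span typical of a
#' substituent-effect study.
#'
#' @return character vector of substituent labels.
#' @export
fixture_substituents <- function() {
  c("H", "Me", "OMe", "F", "Cl", "Br", "CF3", "NO2")
}

#' Generate per-atom spin-density vectors
#'
#' Draws a nonnegative unit-sum vector per radical ion. `concentration`
#' controls peakedness: 0 gives (in expectation) a flat vector, large
#' values concentrate the density on one site (one-hot in the limit).
#' Sites listed in `symmetry_pairs` are made exactly equal, emulating
#' symmetry-equivalent atoms.
#'
#' @param n_atoms number of atoms.
#' @param symmetry_pairs list of disjoint index pairs forced equal.
#' @param concentration nonnegative peakedness exponent.
#' @param seed RNG seed.
#' @return list with unit-sum vectors `asd_cation` and `asd_anion`.
#' @export
gen_asd <- function(n_atoms, symmetry_pairs = NULL, concentration = 2,
                    seed = 1) {
  stopifnot(n_atoms >= 1, concentration >= 0)
  if (!is.null(symmetry_pairs)) {
    flat <- unlist(symmetry_pairs)
    if (anyDuplicated(flat))
      stop("symmetry pairs must be disjoint", call. = FALSE)
    if (any(flat < 1 | flat > n_atoms))
      stop("symmetry pair index out of range", call. = FALSE)
  }
  one <- function() {
    u <- stats::runif(n_atoms)
    # log-space power keeps large exponents from underflowing
    w <- exp(concentration * (log(u) - max(log(u))))
    if (!is.null(symmetry_pairs))
      for (p in symmetry_pairs) w[p] <- mean(w[p])
    w / sum(w)
  }
  with_seed(seed, list(asd_cation = one(), asd_anion = one()))
}

#' Generate a calculation record with prescribed global descriptors
#'
#' Inverts the frontier-orbital formulas: `e_homo = mu - eta/2`,
#' `e_lumo = mu + eta/2`, so recomputing \eqn{\mu}, \eqn{\eta},
#' \eqn{\omega} from the record reproduces the targets exactly. When a
#' nucleophilicity target and reference HOMO are both given,
#' `e_homo = reference_homo + target_n` must agree with the
#' \eqn{\mu, \eta} route to 1e-9 (or `target_mu` may be omitted and is
#' then derived). The attached geometry is a planar carbon ring so that
#' the default all-carbon reactive-center search applies.
#'
#' @param target_mu chemical potential target, eV (may be `NULL` when
#'   `target_n` and `reference_homo` are given).
#' @param target_eta hardness target, eV, positive.
#' @param reference_homo HOMO energy of the TCE reference, eV.
#' @param target_n nucleophilicity target, eV.
#' @param seed RNG seed for the spin densities.
#' @param n_atoms atoms in the dummy geometry / ASD vectors.
#' @param species_id,role,level_tag passed to [calc_record()].
#' @param symmetry_pairs,concentration passed to [gen_asd()].
#' @return a [calc_record()].
#' @export
gen_record <- function(target_mu = NULL, target_eta, reference_homo = NULL,
                       target_n = NULL, seed = 1, n_atoms = 5,
                       species_id = "synthetic", role = "diene",
                       level_tag = "synthetic", symmetry_pairs = NULL,
                       concentration = 2) {
  if (!is.numeric(target_eta) || target_eta <= 0)
    stop("target_eta must be positive", call. = FALSE)
  if (is.null(target_mu)) {
    if (is.null(target_n) || is.null(reference_homo))
      stop("supply target_mu, or both target_n and reference_homo",
           call. = FALSE)
    e_homo <- reference_homo + target_n
    e_lumo <- e_homo + target_eta
  } else {
    e_homo <- target_mu - target_eta / 2
    e_lumo <- target_mu + target_eta / 2
    if (!is.null(target_n) && !is.null(reference_homo) &&
        abs(e_homo - (reference_homo + target_n)) > 1e-9)
      stop("inconsistent (mu, eta, N, reference) specification: ",
           "mu - eta/2 = ", format(e_homo), " but reference + N = ",
           format(reference_homo + target_n), call. = FALSE)
  }
  asd <- gen_asd(n_atoms, symmetry_pairs, concentration, seed)
  ang <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
  geom <- qc_geometry(rep("C", n_atoms),
                      cbind(1.2 * cos(ang), 1.2 * sin(ang), 0))
  calc_record(species_id, role, geom, e_homo = e_homo, e_lumo = e_lumo,
              asd_cation = asd$asd_cation, asd_anion = asd$asd_anion,
              level_tag = level_tag)
}

#' Generate a substituent series with a known linear law
#'
#' \eqn{\Delta\omega_i = c + \rho\,\sigma_i + \epsilon_i} with
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)}, seed-stable. The
#' default design is the eight-member para set of
#' [fixture_substituents()] on the `sigma_p` scale.
#'
#' @param slope true slope \eqn{\rho}, eV per sigma unit.
#' @param intercept true intercept, eV.
#' @param sigma_values numeric design constants; a named vector supplies
#'   substituent labels. Default: `sigma_p` of [fixture_substituents()].
#' @param noise_sd Gaussian noise sd, eV (>= 0).
#' @param seed RNG seed.
#' @param series_id identifier of the generated series.
#' @param scale which sigma column the design fills.
#' @return a [substituent_series()]; attribute `"truth"` records the
#'   generating parameters.
#' @export
gen_hammett_series <- function(slope, intercept, sigma_values = NULL,
                               noise_sd = 0.05, seed = 1,
                               series_id = "synthetic", scale = "sigma_p") {
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (is.null(sigma_values)) {
    subs <- fixture_substituents()
    sigma_values <- stats::setNames(sigma_lookup(subs, scale), subs)
  }
  if (length(sigma_values) < 3L)
    stop("need at least 3 sigma values", call. = FALSE)
  labels <- names(sigma_values)
  if (is.null(labels))
    labels <- paste0("S", seq_along(sigma_values))
  eps <- with_seed(seed, stats::rnorm(length(sigma_values), 0, noise_sd))
  d <- data.frame(substituent = labels, delta_omega =
                    intercept + slope * as.numeric(sigma_values) + eps,
                  stringsAsFactors = FALSE)
  d[[scale]] <- as.numeric(sigma_values)
  out <- substituent_series(series_id, d)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd, seed = seed, scale = scale)
  out
}

#' Analytic multi-Gaussian density with known basin integrals
#'
#' Builds \eqn{\rho(r) = \sum_i q_i\,(2\pi w_i^2)^{-3/2}
#' e^{-|r-c_i|^2/2w_i^2}} on a regular cubic grid, so each center
#' contributes exactly `electrons[i]` analytically; well-separated centers
#' therefore have known basin populations. Optionally a companion
#' kinetic-energy field is returned with the closed form
#' \eqn{\tau = |\nabla\rho|^2/(8\rho) + a\,D_h(\rho)} where
#' \eqn{a = \sqrt{1/\mathrm{elf\_target} - 1}}, which makes the exact ELF
#' equal to `elf_target` everywhere the density is nonzero.
#'
#' @param centers matrix (m x 3) of Gaussian centers, bohr.
#' @param electrons numeric vector of electrons per center.
#' @param widths numeric vector of Gaussian sd per center, bohr.
#' @param spacing cubic grid spacing in bohr (default 0.25 for
#'   desk-sized fixtures; the analysis default for production cubes is
#'   0.1).
#' @param margin grid margin around the centers, in multiples of the
#'   largest width.
#' @param origin,shape explicit grid placement, overriding
#'   `margin`-based construction.
#' @param elf_target if non-`NULL`, also return the companion tau field.
#' @param elf_bumps if `TRUE`, also return an analytic ELF-like field in
#'   `[0, 0.9]` with one bump per center (width matching the density), so
#'   the basin machinery can be exercised with known attractor positions.
#' @param atom_numbers atomic numbers to place at the centers (default
#'   carbon), so synapticity analysis can run on the fixture; `NA`
#'   suppresses atoms.
#' @return list with `density` (and `tau` when requested) as
#'   [scalar_field()]s, plus `populations` (the analytic integrals),
#'   `centers`, `widths`.
#' @export
gen_gaussian_field <- function(centers, electrons, widths, spacing = 0.25,
                               margin = 5, origin = NULL, shape = NULL,
                               elf_target = NULL, elf_bumps = FALSE,
                               atom_numbers = 6L) {
  centers <- matrix(centers, ncol = 3)
  m <- nrow(centers)
  stopifnot(length(electrons) == m, length(widths) == m)
  if (any(widths <= 0)) stop("widths must be positive", call. = FALSE)
  if (is.null(origin) || is.null(shape)) {
    pad <- margin * max(widths)
    lo <- apply(centers, 2, min) - pad
    hi <- apply(centers, 2, max) + pad
    shape <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  }
  axes <- diag(spacing, 3)
  hi_corner <- origin + (shape - 1L) * spacing
  inside <- apply(centers, 1, function(cc)
    all(cc >= origin - 1e-9) && all(cc <= hi_corner + 1e-9))
  if (!all(inside))
    stop("center(s) outside the grid: ",
         paste(which(!inside), collapse = ", "), call. = FALSE)
  dummy <- scalar_field(array(0, dim = shape), origin, axes, "other")
  xyz <- voxel_coords(dummy)
  rho <- numeric(nrow(xyz))
  grad <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(m)) {
    d2 <- rowSums(sweep(xyz, 2L, centers[i, ])^2)
    gi <- electrons[i] * (2 * pi * widths[i]^2)^(-1.5) *
      exp(-d2 / (2 * widths[i]^2))
    rho <- rho + gi
    grad <- grad - sweep(xyz, 2L, centers[i, ]) * gi / widths[i]^2
  }
  atoms <- NULL
  if (length(atom_numbers) && !all(is.na(atom_numbers))) {
    atom_numbers <- rep_len(as.integer(atom_numbers), m)
    atoms <- data.frame(number = atom_numbers, x = centers[, 1],
                        y = centers[, 2], z = centers[, 3])
  }
  density <- scalar_field(array(rho, dim = shape), origin, axes,
                          field_kind = "density", atoms = atoms)
  out <- list(density = density, populations = electrons,
              centers = centers, widths = widths)
  if (elf_bumps) {
    bump <- numeric(nrow(xyz))
    for (i in seq_len(m)) {
      d2 <- rowSums(sweep(xyz, 2L, centers[i, ])^2)
      bump <- bump + exp(-d2 / (2 * widths[i]^2))
    }
    bump <- 0.9 * bump / max(bump)
    out$elf <- scalar_field(array(bump, dim = shape), origin, axes,
                            field_kind = "elf", atoms = atoms)
  }
  if (!is.null(elf_target)) {
    stopifnot(elf_target > 0, elf_target <= 1)
    a <- sqrt(1 / elf_target - 1)
    d_h <- 0.3 * (3 * pi^2)^(2 / 3) * rho^(5 / 3)
    tau_w <- rowSums(grad^2) / (8 * pmax(rho, .Machine$double.xmin))
    out$tau <- scalar_field(array(tau_w + a * d_h, dim = shape), origin,
                            axes, field_kind = "kinetic_energy_density",
                            atoms = atoms)
  }
  out
}
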