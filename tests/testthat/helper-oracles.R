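# Independent oracles and fixture builders shared across tests.

# Brute-force steepest-ascent oracle: for every voxel, follow the
# highest-valued 26-neighbor (ties -> lowest linear index) step by step
# until a local maximum is reached. Implemented from first principles on a
# neighbor-index matrix, independently of the package's pointer-doubling
# path. Returns the root voxel index reached from each voxel.
oracle_ascent_roots <- function(values) {
  sh <- dim(values)
  nvox <- prod(sh)
  idx <- arrayInd(seq_len(nvox), sh)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  v <- as.vector(values)
  # neighbor linear indices (NA outside the grid), one column per offset
  nb <- sapply(seq_len(nrow(offs)), function(r) {
    p <- sweep(idx, 2L, offs[r, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= sh[1] & p[, 2] >= 1 & p[, 2] <= sh[2] &
      p[, 3] >= 1 & p[, 3] <= sh[3]
    out <- rep(NA_integer_, nvox)
    out[ok] <- p[ok, 1] + (p[ok, 2] - 1L) * sh[1] +
      (p[ok, 3] - 1L) * sh[1] * sh[2]
    out
  })
  step_once <- function(at) {
    vapply(at, function(s) {
      cand <- nb[s, ]
      cand <- cand[!is.na(cand)]
      best <- max(v[cand])
      if (best > v[s]) min(cand[v[cand] == best]) else s
    }, integer(1))
  }
  cur <- seq_len(nvox)
  repeat {
    nxt <- step_once(cur)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# Smooth random field on a cubic grid: white noise blurred by a few
# passes of nearest-neighbor averaging along each axis.
random_smooth_field <- function(shape, seed, spacing = 0.2, passes = 4) {
  arr <- polarDA:::with_seed(seed, array(runif(prod(shape)), dim = shape))
  blur1 <- function(a, d) {
    n <- dim(a)[d]
    pick <- function(i) {
      args <- rep(list(quote(expr = )), 3)
      args[[d]] <- i
      do.call(`[`, c(list(a), args, list(drop = FALSE)))
    }
    (pick(c(1, 1:(n - 1))) + a + pick(c(2:n, n))) / 3
  }
  for (p in seq_len(passes)) for (d in 1:3) arr <- blur1(arr, d)
  scalar_field(arr, c(0, 0, 0), diag(spacing, 3), field_kind = "other")
}

# Minimal independent Gaussian-cube parser used to cross-check the
# package reader/writer: token-level scan of the documented layout.
naive_cube_parse <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, skip = 2)
  nums <- suppressWarnings(as.numeric(toks))
  n_atoms <- as.integer(nums[1])
  origin <- nums[2:4]
  shape <- as.integer(nums[c(5, 9, 13)])
  axes <- rbind(nums[6:8], nums[10:12], nums[14:16])
  at <- 17
  atoms <- NULL
  if (n_atoms > 0) {
    block <- matrix(nums[at:(at + 5 * n_atoms - 1)], ncol = 5, byrow = TRUE)
    atoms <- data.frame(number = as.integer(block[, 1]),
                        x = block[, 3], y = block[, 4], z = block[, 5])
    at <- at + 5 * n_atoms
  }
  vals <- nums[at:length(nums)]
  list(n_atoms = n_atoms, origin = origin, shape = shape, axes = axes,
       atoms = atoms, values = vals)
}

# Closed-form OLS oracle (means and sums of squares written out long-hand).
naive_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  list(slope = sxy / sxx, intercept = my - (sxy / sxx) * mx,
       r = sxy / sqrt(sxx * syy))
}

# Reference record for the nucleophilicity scale (tetracyanoethylene-like
# deep HOMO) with a matching level tag.
make_reference <- function(e_homo = -9.3, level_tag = "synthetic") {
  calc_record("TCE", "reference", NULL, e_homo = e_homo, e_lumo = e_homo + 7,
              asd_cation = rep(0.25, 4), asd_anion = rep(0.25, 4),
              level_tag = level_tag)
}

# Record with hand-set spin densities on an n-carbon ring geometry.
make_record <- function(species_id, role, asd_cation, asd_anion,
                        e_homo = -6, e_lumo = -1, reactive_atoms = NULL,
                        level_tag = "synthetic") {
  n <- length(asd_cation)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  geom <- qc_geometry(rep("C", n), cbind(cos(ang), sin(ang), 0))
  calc_record(species_id, role, geom, e_homo = e_homo, e_lumo = e_lumo,
              asd_cation = asd_cation, asd_anion = asd_anion,
              reactive_atoms = reactive_atoms, level_tag = level_tag)
}
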