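# ELF computation, attractor search, basin assignment (against the
# brute-force ascent oracle), populations, synapticity, Lewis summary.

test_that("ELF hits its analytic limits on constructed fields", {
  # 0.1 bohr spacing (the production grid); the check region is where the
  # grid resolves the density (> 20% of the peak) — gradient-based ELF is
  # intrinsically noisy in exponential tails
  # tau built so the Pauli excess equals the homogeneous-gas reference
  g05 <- gen_gaussian_field(matrix(c(0, 0, 0), 1), 2, 0.8, spacing = 0.1,
                            margin = 4, elf_target = 0.5)
  elf05 <- elf_from_fields(g05$density, g05$tau)
  core <- g05$density$values > 0.2 * max(g05$density$values)
  expect_lt(max(abs(elf05$values[core] - 0.5)), 0.02)
  # tau with twice the reference: ELF = 1/(1+4) = 0.2
  g02 <- gen_gaussian_field(matrix(c(0, 0, 0), 1), 2, 0.8, spacing = 0.1,
                            margin = 4, elf_target = 0.2)
  elf02 <- elf_from_fields(g02$density, g02$tau)
  expect_lt(max(abs(elf02$values[core] - 0.2)), 0.02)
  # Weizsaecker-only kinetic energy (single orbital): perfect localization
  g1 <- gen_gaussian_field(matrix(c(0, 0, 0), 1), 2, 0.8, spacing = 0.1,
                           margin = 4, elf_target = 1)
  elf1 <- elf_from_fields(g1$density, g1$tau)
  expect_gt(min(elf1$values[core]), 0.98)
  expect_true(all(elf05$values >= 0 & elf05$values <= 1))
  # grid mismatch is an error
  other <- scalar_field(array(1, c(2, 2, 2)), c(0, 0, 0), diag(1, 3),
                        "kinetic_energy_density")
  expect_error(elf_from_fields(g05$density, other), "same grid")
})

test_that("attractors sit on the bumps; plateaus merge and are flagged", {
  g <- gen_gaussian_field(rbind(c(-2, 0, 0), c(2, 0, 0)), c(2, 2),
                          c(0.5, 0.5), spacing = 0.25, elf_bumps = TRUE)
  att <- find_attractors(g$elf)
  expect_equal(nrow(att$attractors), 2L)
  pos <- as.matrix(att$attractors[, c("x", "y", "z")])
  d <- apply(g$centers, 1, function(cc)
    min(sqrt(rowSums(sweep(pos, 2L, cc)^2))))
  expect_lt(max(d), 0.25)  # within one voxel of the true centers
  # single bump
  g1 <- gen_gaussian_field(matrix(0, 1, 3), 2, 0.5, spacing = 0.25,
                           elf_bumps = TRUE)
  expect_equal(nrow(find_attractors(g1$elf)$attractors), 1L)
  # flat-topped plateau coalesces into one flagged attractor
  arr <- array(0, c(7, 7, 7))
  arr[3:5, 4, 4] <- 1
  fld <- scalar_field(arr, c(0, 0, 0), diag(0.1, 3), "other")
  attp <- find_attractors(fld)
  expect_equal(nrow(attp$attractors), 1L)
  expect_true(attp$attractors$plateau[1])
  # constant field has no attractors
  expect_error(find_attractors(scalar_field(array(1, c(3, 3, 3)), c(0, 0, 0),
                                            diag(1, 3), "other")),
               "constant")
})

test_that("steepest-ascent labels match the brute-force oracle on random fields", {
  for (s in 1:20) {
    fld <- random_smooth_field(c(20, 20, 20), seed = 1000 + s)
    att <- find_attractors(fld, merge_radius = 0)
    labels <- assign_basins(fld, att)
    roots <- oracle_ascent_roots(fld$values)
    expect_identical(as.vector(labels), att$root_map[roots])
  }
})

test_that("basin populations recover analytic integrals and conserve charge", {
  # widely separated Gaussians: populations equal the analytic electrons
  g <- gen_gaussian_field(rbind(c(-2.5, 0, 0), c(2.5, 0, 0)), c(2, 3),
                          c(0.45, 0.45), spacing = 0.22, elf_bumps = TRUE)
  bs <- elf_basins(g$density, elf = g$elf)
  expect_equal(nrow(bs$basins), 2L)
  pops <- sort(bs$basins$population)
  expect_lt(max(abs(pops - c(2, 3)) / c(2, 3)), 0.01)
  expect_lt(abs(sum(bs$basins$population) + bs$unassigned_charge -
                  bs$total_electrons) / bs$total_electrons, 5e-3)
  # single uniform-density basin: population = value * volume * voxels
  u <- scalar_field(array(1, c(4, 4, 4)), c(0, 0, 0), diag(0.1, 3), "density")
  lab <- array(1L, c(4, 4, 4))
  lab[1, 1, 1] <- 0L
  pb <- basin_populations(lab, u)
  expect_equal(pb$basins$population, 63 * 0.001, tolerance = 1e-12)
  expect_equal(pb$unassigned_charge, 0.001, tolerance = 1e-12)
})

test_that("populations are stable under grid refinement", {
  pops_at <- function(h) {
    g <- gen_gaussian_field(rbind(c(-2, 0, 0), c(2, 0, 0)), c(2, 2),
                            c(0.5, 0.5), spacing = h, elf_bumps = TRUE)
    sort(elf_basins(g$density, elf = g$elf)$basins$population)
  }
  coarse <- pops_at(0.4)
  fine <- pops_at(0.2)
  expect_lt(max(abs(coarse - fine) / fine), 0.01)
})

test_that("mirror-symmetric fields give mirror-paired populations", {
  g <- gen_gaussian_field(rbind(c(-1.8, 0, 0), c(1.8, 0, 0)), c(2, 2),
                          c(0.5, 0.5), spacing = 0.25, elf_bumps = TRUE)
  bs <- elf_basins(g$density, elf = g$elf)
  expect_lt(abs(bs$basins$population[1] - bs$basins$population[2]), 1e-3)
})

test_that("synapticity classification distinguishes core, bond and lone pair", {
  # two heavy atoms with a bridging bump: disynaptic V(C1,C2)
  centers <- rbind(c(-1, 0, 0), c(1, 0, 0))
  g <- gen_gaussian_field(centers, c(2, 2), c(0.5, 0.5), spacing = 0.2)
  bump <- function(xyz, c0, w) exp(-rowSums(sweep(xyz, 2L, c0)^2) / (2 * w^2))
  xyz <- voxel_coords(g$density)
  ev <- 0.85 * bump(xyz, c(0, 0, 0), 0.45) +
    0.6 * bump(xyz, c(-1, 0, 0), 0.3) + 0.6 * bump(xyz, c(1, 0, 0), 0.3)
  elf <- scalar_field(array(pmin(ev, 1), dim = g$density$shape),
                      g$density$origin, g$density$axes, "elf",
                      atoms = g$density$atoms)
  bs <- elf_basins(g$density, elf = elf)
  expect_setequal(bs$basins$kind, c("core", "disynaptic"))
  di <- bs$basins[bs$basins$kind == "disynaptic", ]
  expect_identical(di$label, "V(C1,C2)")
  expect_identical(di$atoms, "1,2")
  # lone-pair bump near a single oxygen: monosynaptic V(O1)
  go <- gen_gaussian_field(matrix(c(0, 0, 0), 1), 6, 0.5, spacing = 0.2,
                           atom_numbers = 8L)
  xyz2 <- voxel_coords(go$density)
  ev2 <- 0.9 * bump(xyz2, c(0.9, 0, 0), 0.35) + 0.7 * bump(xyz2, c(0, 0, 0), 0.25)
  elf2 <- scalar_field(array(ev2, dim = go$density$shape), go$density$origin,
                       go$density$axes, "elf", atoms = go$density$atoms)
  bs2 <- elf_basins(go$density, elf = elf2)
  expect_true(any(bs2$basins$label == "C(O1)"))
  expect_true(any(bs2$basins$kind == "monosynaptic" &
                    bs2$basins$label == "V(O1)"))
})

test_that("equivalent basins merge for reporting and feed the Lewis summary", {
  b <- structure(list(
    basins = data.frame(basin_id = 1:4,
                        population = c(1.7, 1.8, 2.1, 5.8),
                        kind = c("disynaptic", "disynaptic", "disynaptic",
                                 "monosynaptic"),
                        atoms = c("1,2", "1,2", "2,3", "3"),
                        label = c("V(C1,C2)", "V'(C1,C2)", "V(C2,C3)",
                                  "V(C3)"),
                        stringsAsFactors = FALSE),
    labels = NULL, unassigned_charge = 0, total_electrons = 11.4),
    class = "basin_set")
  m <- merge_equivalent(b)
  expect_equal(nrow(m), 3L)
  cc <- m[m$atoms == "1,2", ]
  expect_equal(cc$population, 3.5)
  expect_equal(cc$n_basins, 2L)
  lw <- lewis_summary(b)
  expect_identical(lw$bonds$order[lw$bonds$atoms == "1,2"], "double")
  expect_identical(lw$bonds$order[lw$bonds$atoms == "2,3"], "single")
  expect_equal(lw$lone_pairs$n_pairs, 3)
  # a population between the windows is flagged intermediate
  b$basins$population[3] <- 2.9
  expect_identical(lewis_summary(b)$bonds$order[2], "intermediate")
})
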