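# Record and cube I/O: unit handling, validation, round trips.

test_that("energy unit conversion is exact and involutive", {
  expect_equal(hartree_to_ev(-0.25), -6.80285, tolerance = 1e-12)
  x <- c(-3.7, 0, 12.345)
  expect_equal(ev_to_hartree(hartree_to_ev(x)), x, tolerance = 1e-12)
})

test_that("record reading converts hartree, validates ASD sums and fields", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  doc <- list(energy_unit = "hartree", records = list(list(
    species_id = "s1", role = "dienophile", e_homo = -0.25, e_lumo = -0.05,
    asd_cation = c(0.5, 0.5), asd_anion = c(0.2, 0.8))))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  rec <- read_records(tmp)[[1]]
  expect_equal(rec$e_homo, -6.80285, tolerance = 1e-9)
  expect_equal(rec$e_lumo, -0.05 * 27.2114, tolerance = 1e-9)

  # degenerate gap accepted at I/O
  doc$records[[1]]$e_lumo <- -0.25
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  expect_silent(read_records(tmp))

  # ASD sum far from 1 rejected, naming the offender
  doc$records[[1]]$asd_cation <- c(0.4, 0.4)
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(read_records(tmp), "s1")

  # missing mandatory field named in the error
  doc$records[[1]]$asd_cation <- NULL
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(read_records(tmp), "asd_cation")
})

test_that("records round-trip through JSON and CSV readers", {
  rec <- make_record("rt", "diene", c(0.4, 0.3, 0.3), c(0.1, 0.2, 0.7),
                     e_homo = -6.123456789, reactive_atoms = c(1L, 3L))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_records(list(rec), tmp)
  back <- read_records(tmp)[[1]]
  for (f in c("e_homo", "e_lumo", "asd_cation", "asd_anion"))
    expect_equal(back[[f]], rec[[f]], tolerance = 1e-9)
  expect_equal(back$reactive_atoms, rec$reactive_atoms)
  expect_equal(back$geometry$coords, rec$geometry$coords, tolerance = 1e-9)

  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  writeLines(paste(
    "species_id,role,energy_unit,e_homo,e_lumo,asd_cation,asd_anion",
    "c1,diene,eV,-6.5,-1.25,0.5;0.5,0.25;0.75", sep = "\n"), csv)
  crec <- read_records(csv)[[1]]
  expect_equal(crec$asd_anion, c(0.25, 0.75))
  expect_equal(crec$e_lumo, -1.25)
})

test_that("cube reader integrates, scales with the voxel volume, and round-trips", {
  f <- scalar_field(array(1, dim = c(2, 2, 2)), c(0, 0, 0), diag(1, 3),
                    field_kind = "density",
                    atoms = data.frame(number = 6L, x = 0.5, y = 0.5, z = 0.5))
  tmp <- tempfile(fileext = ".cube")
  on.exit(unlink(tmp))
  write_cube(f, tmp)
  g <- read_cube(tmp)
  expect_equal(grid_integral(g), 8.0, tolerance = 1e-10)

  f2 <- scalar_field(array(1, dim = c(2, 2, 2)), c(0, 0, 0), diag(2, 3),
                     field_kind = "density")
  expect_equal(voxel_volume(f2) / voxel_volume(f), 8)
  expect_equal(grid_integral(f2), 64)

  # value-level round trip and header agreement with an independent parser
  set.seed(11)
  h <- scalar_field(array(runif(3 * 4 * 5), dim = c(3, 4, 5)),
                    c(-1, 0.5, 2), diag(0.3, 3), field_kind = "density",
                    atoms = data.frame(number = c(6L, 8L), x = c(0, 1),
                                       y = c(0, 1), z = c(0, 1)))
  write_cube(h, tmp)
  back <- read_cube(tmp)
  expect_equal(back$values, h$values, tolerance = 1e-10)
  expect_equal(back$origin, h$origin, tolerance = 1e-10)
  ref <- naive_cube_parse(tmp)
  expect_identical(ref$shape, back$shape)
  expect_equal(ref$axes, back$axes, tolerance = 1e-10)
  expect_equal(ref$values,
               as.vector(aperm(back$values, c(3, 2, 1))), tolerance = 1e-10)
  expect_identical(ref$atoms$number, back$atoms$number)
})

test_that("malformed cubes are rejected", {
  f <- scalar_field(array(1, dim = c(2, 2, 2)), c(0, 0, 0), diag(1, 3))
  tmp <- tempfile(fileext = ".cube")
  on.exit(unlink(tmp))
  write_cube(f, tmp)
  lines <- readLines(tmp)
  # truncated body
  writeLines(lines[1:(length(lines) - 1)], tmp)
  expect_error(read_cube(tmp), "does not match grid size")
  # header declares an atom that is not there
  lines2 <- lines
  lines2[3] <- sub("^\\s*0", "    3", lines2[3])
  writeLines(lines2, tmp)
  expect_error(read_cube(tmp))
  # trailing blank lines tolerated
  writeLines(c(lines, "", "   "), tmp)
  expect_silent(read_cube(tmp))
})

test_that("result tables round-trip numerics to 1e-9", {
  df <- data.frame(species_id = c("a", "b"), omega = c(1.23456789012, 2/3),
                   n_index = c(3.3, 4.14159265358979))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_results(df, tmp)
  back <- read_results(tmp)
  expect_equal(back$omega, df$omega, tolerance = 1e-9)
  expect_equal(back$n_index, df$n_index, tolerance = 1e-9)
  expect_identical(names(back), names(df))
  # empty table: header only
  write_results(df[0, ], tmp)
  expect_equal(nrow(read_results(tmp)), 0L)
})
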