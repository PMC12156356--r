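## I/O layer: calculation records (JSON/CSV), Gaussian cube scalar fields,
## and flat result tables. Everything else in the package consumes the
## containers defined here.

# symbols for Z = 1..36; covers H..Kr (enough for C, N, O, Si, Br chemistry)
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

element_number <- function(symbol) {
  z <- match(symbol, .ELEMENTS)
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "), call. = FALSE)
  z
}

element_symbol <- function(z) {
  if (any(z < 1L | z > length(.ELEMENTS)))
    stop("atomic number out of supported range 1..36", call. = FALSE)
  .ELEMENTS[z]
}

#' Molecular geometry container
#'
#' Holds element symbols, Cartesian coordinates in Angstrom, total charge
#' and spin multiplicity. Coordinates elsewhere in the package (cube grids)
#' are in bohr; geometries attached to calculation records are in Angstrom,
#' the unit quantum-chemistry engines print.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param charge integer total charge (elementary charges).
#' @param multiplicity positive integer spin multiplicity.
#' @return An object of class `qc_geometry`.
#' @export
qc_geometry <- function(symbols, coords, charge = 0L, multiplicity = 1L) {
  coords <- as.matrix(coords)
  if (length(symbols) < 1L) stop("geometry needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(symbols) || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching the atom count", call. = FALSE)
  if (multiplicity < 1L) stop("multiplicity must be >= 1", call. = FALSE)
  structure(
    list(symbols = as.character(symbols),
         numbers = element_number(symbols),
         coords = unname(coords),
         charge = as.integer(charge),
         multiplicity = as.integer(multiplicity)),
    class = "qc_geometry")
}

#' Quantum-chemistry summary record for one species
#'
#' A `calc_record` carries everything the reactivity pipeline needs about
#' one species: frontier-orbital energies and the per-atom spin densities
#' of its vertical radical cation and anion (the inputs to the Parr
#' functions). Energies are stored in eV; `unit = "hartree"` converts on
#' input. Each atomic-spin-density (ASD) vector must sum to 1 within
#' `asd_tol` (Mulliken sums deviate slightly from unity).
#'
#' @param species_id character identifier.
#' @param role one of `"diene"`, `"dienophile"`, `"reference"`.
#' @param geometry a [qc_geometry()], or `NULL` when only energetics are
#'   available (ASD vectors then define the atom count).
#' @param e_homo,e_lumo frontier-orbital energies.
#' @param asd_cation,asd_anion per-atom Mulliken spin densities of the
#'   vertical radical cation / anion.
#' @param reactive_atoms optional integer vector of atom indices eligible
#'   as reaction centers.
#' @param level_tag free-text provenance string (theory level, whether the
#'   radical ions were vertical or relaxed, ...).
#' @param unit `"eV"` (default) or `"hartree"` for the input energies.
#' @param asd_tol tolerance on `sum(asd) - 1` (default 0.05 e).
#' @return An object of class `calc_record`.
#' @export
calc_record <- function(species_id, role = c("diene", "dienophile", "reference"),
                        geometry = NULL, e_homo, e_lumo,
                        asd_cation, asd_anion,
                        reactive_atoms = NULL, level_tag = "",
                        unit = c("eV", "hartree"), asd_tol = 0.05) {
  role <- match.arg(role)
  unit <- match.arg(unit)
  if (!is.finite(e_homo) || !is.finite(e_lumo))
    stop("non-finite orbital energy for species ", species_id, call. = FALSE)
  if (unit == "hartree") {
    e_homo <- hartree_to_ev(e_homo)
    e_lumo <- hartree_to_ev(e_lumo)
  }
  if (e_lumo < e_homo)
    stop("e_lumo < e_homo for species ", species_id, call. = FALSE)
  asd_cation <- as.numeric(asd_cation)
  asd_anion <- as.numeric(asd_anion)
  if (length(asd_cation) != length(asd_anion))
    stop("asd_cation and asd_anion differ in length for species ",
         species_id, call. = FALSE)
  n_atoms <- length(asd_cation)
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "qc_geometry"))
    if (length(geometry$symbols) != n_atoms)
      stop("ASD length does not match atom count for species ",
           species_id, call. = FALSE)
  }
  for (nm in c("asd_cation", "asd_anion")) {
    s <- sum(get(nm))
    if (abs(s - 1) > asd_tol)
      stop(nm, " of species ", species_id, " sums to ", format(s),
           ", outside tolerance ", asd_tol, " of 1", call. = FALSE)
  }
  if (!is.null(reactive_atoms)) {
    reactive_atoms <- as.integer(reactive_atoms)
    if (any(reactive_atoms < 1L | reactive_atoms > n_atoms))
      stop("reactive_atoms out of range for species ", species_id, call. = FALSE)
  }
  structure(
    list(species_id = as.character(species_id), role = role,
         geometry = geometry, e_homo = e_homo, e_lumo = e_lumo,
         asd_cation = asd_cation, asd_anion = asd_anion,
         reactive_atoms = reactive_atoms, level_tag = as.character(level_tag)),
    class = "calc_record")
}

#' @export
print.calc_record <- function(x, ...) {
  cat(sprintf("<calc_record> %s (%s), %d atoms\n", x$species_id, x$role,
              length(x$asd_cation)))
  cat(sprintf("  E(HOMO) = %.4f eV, E(LUMO) = %.4f eV\n", x$e_homo, x$e_lumo))
  invisible(x)
}

.split_num <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}
.join_num <- function(x) paste(format(x, digits = 17, trim = TRUE), collapse = ";")

.record_from_list <- function(rec, default_unit = "eV", asd_tol = 0.05) {
  for (f in c("species_id", "role", "e_homo", "e_lumo", "asd_cation", "asd_anion")) {
    if (is.null(rec[[f]]) || (is.atomic(rec[[f]]) && all(is.na(rec[[f]]))))
      stop("record is missing mandatory field '", f, "'",
           if (!is.null(rec$species_id)) paste0(" (species ", rec$species_id, ")"),
           call. = FALSE)
  }
  geom <- NULL
  if (!is.null(rec$geometry)) {
    g <- rec$geometry
    geom <- qc_geometry(unlist(g$symbols),
                        matrix(unlist(g$coords), ncol = 3, byrow = TRUE),
                        charge = if (is.null(g$charge)) 0L else g$charge,
                        multiplicity = if (is.null(g$multiplicity)) 1L else g$multiplicity)
  }
  calc_record(rec$species_id, rec$role, geom,
              e_homo = rec$e_homo, e_lumo = rec$e_lumo,
              asd_cation = unlist(rec$asd_cation), asd_anion = unlist(rec$asd_anion),
              reactive_atoms = if (length(rec$reactive_atoms)) unlist(rec$reactive_atoms),
              level_tag = if (is.null(rec$level_tag)) "" else rec$level_tag,
              unit = if (is.null(rec$energy_unit)) default_unit else rec$energy_unit,
              asd_tol = asd_tol)
}

#' Read calculation records from JSON or CSV
#'
#' The JSON schema is an object with an optional file-level `energy_unit`
#' (`"eV"` or `"hartree"`, per-record `energy_unit` overrides it) and a
#' `records` array; each record carries `species_id`, `role`, `e_homo`,
#' `e_lumo`, `asd_cation`, `asd_anion` and optionally `geometry`
#' (`symbols`, `coords`, `charge`, `multiplicity`), `reactive_atoms` and
#' `level_tag`. The CSV dialect is one row per species with vector-valued
#' columns (`symbols`, `x`, `y`, `z`, `asd_cation`, `asd_anion`,
#' `reactive_atoms`) joined by `";"`.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @param asd_tol spin-density normalization tolerance (e).
#' @return list of [calc_record()] objects.
#' @export
read_records <- function(path, asd_tol = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    unit <- if (is.null(doc$energy_unit)) "eV" else doc$energy_unit
    recs <- if (!is.null(doc$records)) doc$records else doc
    lapply(recs, .record_from_list, default_unit = unit, asd_tol = asd_tol)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("species_id", "role", "e_homo", "e_lumo", "asd_cation", "asd_anion")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("record table is missing mandatory column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      row <- df[i, ]
      rec <- list(species_id = row$species_id, role = row$role,
                  e_homo = row$e_homo, e_lumo = row$e_lumo,
                  asd_cation = .split_num(row$asd_cation),
                  asd_anion = .split_num(row$asd_anion))
      if (!is.null(row$energy_unit) && nzchar(row$energy_unit))
        rec$energy_unit <- row$energy_unit
      if (!is.null(row$symbols) && !is.na(row$symbols) && nzchar(row$symbols))
        rec$geometry <- list(
          symbols = strsplit(row$symbols, ";", fixed = TRUE)[[1]],
          coords = cbind(.split_num(row$x), .split_num(row$y), .split_num(row$z)),
          charge = if (is.null(row$charge)) 0L else row$charge,
          multiplicity = if (is.null(row$multiplicity)) 1L else row$multiplicity)
      if (!is.null(row$reactive_atoms) && !is.na(row$reactive_atoms) &&
          nzchar(row$reactive_atoms))
        rec$reactive_atoms <- .split_num(row$reactive_atoms)
      if (!is.null(row$level_tag) && !is.na(row$level_tag))
        rec$level_tag <- row$level_tag
      .record_from_list(rec, asd_tol = asd_tol)
    })
  }
}

#' Write calculation records to JSON
#'
#' Inverse of [read_records()]; energies are written in eV. Round-trips all
#' numeric fields to better than 1e-9.
#'
#' @param records list of [calc_record()] objects.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  if (inherits(records, "calc_record")) records <- list(records)
  doc <- list(
    energy_unit = "eV",
    records = lapply(records, function(r) {
      out <- list(species_id = r$species_id, role = r$role,
                  e_homo = r$e_homo, e_lumo = r$e_lumo,
                  asd_cation = r$asd_cation, asd_anion = r$asd_anion,
                  level_tag = r$level_tag)
      if (!is.null(r$geometry))
        out$geometry <- list(symbols = r$geometry$symbols,
                             coords = apply(r$geometry$coords, 1, as.numeric,
                                            simplify = FALSE),
                             charge = r$geometry$charge,
                             multiplicity = r$geometry$multiplicity)
      if (!is.null(r$reactive_atoms)) out$reactive_atoms <- r$reactive_atoms
      out
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Volumetric scalar field on a regular grid
#'
#' The container behind cube-file I/O and the ELF machinery. `values` is a
#' 3-d array indexed `[i, j, k]` along the three axes; `axes` holds the
#' three step vectors (rows, bohr); `origin` is the position of voxel
#' `[1, 1, 1]` (bohr). Atom positions, if any, are nuclei in bohr.
#'
#' @param values numeric 3-d array of voxel values.
#' @param origin numeric length-3 origin in bohr.
#' @param axes 3 x 3 matrix whose rows are the grid step vectors in bohr.
#' @param field_kind one of `"density"`, `"kinetic_energy_density"`,
#'   `"elf"`, `"other"`.
#' @param atoms optional data.frame with columns `number` (atomic number)
#'   and `x`, `y`, `z` nuclear positions in bohr.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(values, origin, axes,
                         field_kind = c("density", "kinetic_energy_density",
                                        "elf", "other"),
                         atoms = NULL) {
  field_kind <- match.arg(field_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-d array", call. = FALSE)
  if (any(dim(values) < 2L))
    stop("each grid axis needs at least 2 points", call. = FALSE)
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  vol <- abs(det(axes))
  if (vol <= 0) stop("voxel volume must be positive", call. = FALSE)
  if (field_kind == "density" && min(values) < -1e-10)
    stop("density field has negative voxels", call. = FALSE)
  if (field_kind == "elf" && (min(values) < -1e-9 || max(values) > 1 + 1e-9))
    stop("elf field must lie in [0, 1]", call. = FALSE)
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    stopifnot(all(c("number", "x", "y", "z") %in% names(atoms)))
  }
  structure(
    list(values = values, origin = as.numeric(origin), axes = unname(axes),
         shape = dim(values), field_kind = field_kind, atoms = atoms),
    class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %s, %d x %d x %d grid, voxel volume %.4g bohr^3\n",
              x$field_kind, x$shape[1], x$shape[2], x$shape[3], voxel_volume(x)))
  invisible(x)
}

#' Voxel volume of a scalar field (bohr^3)
#' @param field a [scalar_field()].
#' @export
voxel_volume <- function(field) abs(det(field$axes))

#' Grid integral of a scalar field
#'
#' Sum of voxel values times voxel volume; for a density field this is the
#' electron count represented on the grid.
#'
#' @param field a [scalar_field()].
#' @export
grid_integral <- function(field) sum(field$values) * voxel_volume(field)

#' Cartesian coordinates (bohr) of every voxel center
#'
#' @param field a [scalar_field()].
#' @return matrix `prod(shape)` x 3 in the array's linear-index order.
#' @export
voxel_coords <- function(field) {
  sh <- field$shape
  idx <- arrayInd(seq_len(prod(sh)), sh) - 1L
  sweep(idx %*% field$axes, 2L, field$origin, "+")
}

#' Read a Gaussian-cube scalar field
#'
#' Standard cube layout: two comment lines; a line with the atom count and
#' the grid origin (bohr); three axis lines (voxel count and step vector);
#' one line per atom (`Z  charge  x y z` in bohr); then values with the
#' third (z) index varying fastest. Trailing whitespace and blank lines are
#' tolerated; a value-count mismatch or a negative voxel count is an error.
#'
#' @param path cube file path.
#' @param field_kind what the values represent (see [scalar_field()]).
#' @return a [scalar_field()].
#' @export
read_cube <- function(path, field_kind = "density") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- nums(lines[3])
  n_atoms <- as.integer(hdr[1])
  if (is.na(n_atoms)) stop("malformed cube header", call. = FALSE)
  if (n_atoms < 0L)
    stop("cube files with orbital data sets (negative atom count) are not supported",
         call. = FALSE)
  origin <- hdr[2:4]
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (a in 1:3) {
    v <- nums(lines[3 + a])
    shape[a] <- as.integer(v[1])
    axes[a, ] <- v[2:4]
  }
  if (any(is.na(shape)) || any(shape < 0L))
    stop("negative or missing voxel count in cube header", call. = FALSE)
  atom_lines <- lines[seq(7, length.out = n_atoms)]
  atoms <- NULL
  if (n_atoms > 0L) {
    am <- t(vapply(atom_lines, nums, numeric(5), USE.NAMES = FALSE))
    if (anyNA(am))
      stop("cube header declares ", n_atoms,
           " atoms but the atom block is malformed or short", call. = FALSE)
    atoms <- data.frame(number = as.integer(am[, 1]),
                        x = am[, 3], y = am[, 4], z = am[, 5])
  }
  body <- lines[seq(7 + n_atoms, length(lines))]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    stop("cube value count ", length(vals), " does not match grid size ",
         prod(shape), " (truncated file?)", call. = FALSE)
  # file order: z fastest -> array dim (n3, n2, n1), then permute to [i,j,k]
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  scalar_field(arr, origin, axes, field_kind = field_kind, atoms = atoms)
}

#' Write a scalar field as a Gaussian cube
#'
#' @param field a [scalar_field()].
#' @param path output path.
#' @param comment first comment line.
#' @export
write_cube <- function(field, path, comment = "cube written by polarDA") {
  atoms <- field$atoms
  n_atoms <- if (is.null(atoms)) 0L else nrow(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, field$field_kind), con)
  fmt <- function(n, v) sprintf("%5d %15.8f %15.8f %15.8f", n, v[1], v[2], v[3])
  writeLines(fmt(n_atoms, field$origin), con)
  for (a in 1:3) writeLines(fmt(field$shape[a], field$axes[a, ]), con)
  if (n_atoms > 0L)
    for (i in seq_len(n_atoms))
      writeLines(sprintf("%5d %15.8f %15.8f %15.8f %15.8f", atoms$number[i],
                         as.numeric(atoms$number[i]),
                         atoms$x[i], atoms$y[i], atoms$z[i]), con)
  v <- as.vector(aperm(field$values, c(3, 2, 1)))  # back to z-fastest
  n <- length(v)
  for (start in seq(1, n, by = 6)) {
    chunk <- v[start:min(start + 5, n)]
    writeLines(paste(sprintf("%20.12e", chunk), collapse = " "), con)
  }
  invisible(path)
}

#' Write / read flat result tables
#'
#' `write_results()` writes any result data.frame (descriptor tables,
#' reaction assessments, scale comparisons) as CSV with full numeric
#' precision; `read_results()` reads it back. `read(write(x))` reproduces
#' every numeric field to better than 1e-9.
#'
#' @param x a data.frame.
#' @param path file path.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- names(x)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
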