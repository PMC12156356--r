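## ELF topology: compute the electron localization function on a grid,
## locate attractors, partition voxels into basins by discrete steepest
## ascent, integrate populations, classify synapticity and summarize the
## Lewis-like structure.

.check_congruent <- function(a, b, tol = 1e-8) {
  if (!identical(a$shape, b$shape) ||
      max(abs(a$axes - b$axes)) > tol ||
      max(abs(a$origin - b$origin)) > tol)
    stop("scalar fields are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

# index-space central differences along dimension d (one-sided at edges)
.index_gradient <- function(arr, d) {
  n <- dim(arr)[d]
  if (n < 2L) stop("axis too short for differences", call. = FALSE)
  idx <- function(i) {
    args <- rep(list(quote(expr = )), 3)
    args[[d]] <- i
    do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  fwd <- idx(c(2:n, n))
  bwd <- idx(c(1, 1:(n - 1)))
  den <- array(2, dim = dim(arr))
  edge <- function(i, val) {
    args <- rep(list(quote(expr = )), 3)
    args[[d]] <- i
    do.call(`[<-`, c(list(den), args, list(value = val)))
  }
  den <- edge(1, 1)
  den <- edge(n, 1)
  (fwd - bwd) / den
}

# squared Cartesian gradient magnitude of a field (handles oblique axes)
.grad_sq <- function(field) {
  gu <- vapply(1:3, function(d) as.vector(.index_gradient(field$values, d)),
               numeric(length(field$values)))
  gx <- gu %*% t(solve(field$axes))
  array(rowSums(gx^2), dim = field$shape)
}

#' Electron localization function from density and kinetic-energy fields
#'
#' Closed-shell Becke-Edgecombe form:
#' \deqn{ELF = 1 / (1 + (D/D_h)^2)}
#' with the Pauli kinetic-energy density
#' \eqn{D = \tau - |\nabla\rho|^2 / (8\rho)} and the homogeneous-gas
#' reference \eqn{D_h = (3/10)(3\pi^2)^{2/3} \rho^{5/3}}. The density
#' gradient is taken by central differences on the grid; voxels with
#' density below `rho_floor` get ELF 0, and small negative `D` values
#' (numerical noise near nuclei) are clamped to 0.
#'
#' @param density a [scalar_field()] with `field_kind = "density"`
#'   (e/bohr^3).
#' @param tau positive-definite kinetic-energy density on the same grid
#'   (hartree/bohr^3).
#' @param rho_floor density below which ELF is set to 0.
#' @return a [scalar_field()] of kind `"elf"` with values in `[0, 1]`.
#' @export
elf_from_fields <- function(density, tau, rho_floor = 1e-10) {
  stopifnot(inherits(density, "scalar_field"), inherits(tau, "scalar_field"))
  .check_congruent(density, tau)
  rho <- density$values
  if (min(rho) < -1e-10)
    stop("density field has negative voxels", call. = FALSE)
  rho <- pmax(rho, 0)
  d_pauli <- tau$values - .grad_sq(density) / (8 * pmax(rho, rho_floor))
  d_pauli <- pmax(d_pauli, 0)
  d_h <- 0.3 * (3 * pi^2)^(2 / 3) * rho^(5 / 3)
  chi <- ifelse(rho > rho_floor, d_pauli / pmax(d_h, .Machine$double.xmin), Inf)
  elf <- 1 / (1 + chi^2)
  elf[rho <= rho_floor] <- 0
  scalar_field(array(elf, dim = density$shape), density$origin, density$axes,
               field_kind = "elf", atoms = density$atoms)
}

## ---- steepest-ascent machinery -------------------------------------------

# 26-neighbor offsets ordered by their linear-index delta (column-major),
# so that "first strict improvement" == "lowest-index neighbor on ties"
.neighbor_offsets <- function(shape) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  delta <- off[, 1] + off[, 2] * shape[1] + off[, 3] * shape[1] * shape[2]
  off[order(delta), , drop = FALSE]
}

# For every voxel: linear index of the steepest strictly-greater neighbor,
# or the voxel itself when it is a (plateau) local maximum. Ties between
# equal-valued neighbors go to the lowest linear index.
.steepest_parents <- function(values) {
  sh <- dim(values)
  n1 <- sh[1]; n2 <- sh[2]; n3 <- sh[3]
  pad <- array(-Inf, dim = sh + 2L)
  pad[2:(n1 + 1), 2:(n2 + 1), 2:(n3 + 1)] <- values
  nvox <- prod(sh)
  best_val <- as.vector(values)
  parent <- seq_len(nvox)
  offs <- .neighbor_offsets(sh)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- as.vector(pad[(2:(n1 + 1)) + o[1], (2:(n2 + 1)) + o[2],
                        (2:(n3 + 1)) + o[3]])
    delta <- o[1] + o[2] * n1 + o[3] * n1 * n2
    better <- nb > best_val
    best_val[better] <- nb[better]
    parent[better] <- which(better) + delta
  }
  parent
}

#' Locate ELF attractors
#'
#' Attractors are 26-connected local maxima of the field. Maxima that are
#' grid-adjacent (equal-valued plateaus) or closer than `merge_radius` are
#' coalesced into one attractor at their field-weighted centroid; a
#' coalesced group of equal-valued maxima is flagged as a plateau.
#'
#' @param field a [scalar_field()] (typically ELF).
#' @param merge_radius coalescence distance in bohr.
#' @param min_value discard maxima with field value at or below this.
#' @return object of class `attractor_set`: data.frame `attractors`
#'   (`id`, `x`, `y`, `z`, `value`, `n_maxima`, `plateau`) plus the
#'   maximum-voxel to attractor map used by [assign_basins()].
#' @export
find_attractors <- function(field, merge_radius = 0.2, min_value = 0) {
  stopifnot(inherits(field, "scalar_field"))
  vals <- as.vector(field$values)
  if (max(vals) == min(vals))
    stop("constant field has no attractors", call. = FALSE)
  parent <- .steepest_parents(field$values)
  roots <- which(parent == seq_along(parent))
  roots <- roots[vals[roots] > min_value]
  if (length(roots) == 0L)
    stop("no attractor above min_value", call. = FALSE)
  sh <- field$shape
  rc <- (arrayInd(roots, sh) - 1L) %*% field$axes
  rc <- sweep(rc, 2L, field$origin, "+")
  # union-find: merge grid-adjacent maxima and maxima within merge_radius
  uf <- seq_along(roots)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  ridx <- arrayInd(roots, sh)
  if (length(roots) > 1L) {
    for (i in seq_along(roots)) {
      for (j in seq_len(i - 1L)) {
        adj <- all(abs(ridx[i, ] - ridx[j, ]) <= 1L)
        near <- sqrt(sum((rc[i, ] - rc[j, ])^2)) <= merge_radius
        if (adj || near) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  grp <- vapply(seq_along(roots), find, integer(1))
  ugrp <- sort(unique(grp))
  att <- do.call(rbind, lapply(seq_along(ugrp), function(g) {
    sel <- grp == ugrp[g]
    w <- vals[roots[sel]]
    ctr <- colSums(rc[sel, , drop = FALSE] * w) / sum(w)
    data.frame(id = g, x = ctr[1], y = ctr[2], z = ctr[3],
               value = max(w), n_maxima = sum(sel),
               plateau = sum(sel) > 1L && length(unique(w)) == 1L)
  }))
  root_map <- integer(length(vals))
  root_map[roots] <- match(grp, ugrp)
  structure(list(attractors = att, root_map = root_map, shape = sh,
                 axes = field$axes, origin = field$origin),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor_set> %d attractors\n", nrow(x$attractors)))
  print(x$attractors, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Partition voxels into basins by discrete steepest ascent
#'
#' Every voxel moves to its highest-valued 26-neighbor until a local
#' maximum is reached (ties toward the lowest voxel index); the voxel
#' inherits that maximum's attractor. The pointer chains are resolved by
#' pointer doubling, which gives exactly the labels of the per-voxel full
#' path ascent. Voxels whose reference density falls below
#' `density_floor` are left unassigned (label 0).
#'
#' @param field the field whose gradient drives the ascent (ELF).
#' @param attractors an `attractor_set` from [find_attractors()]; computed
#'   if `NULL`.
#' @param density optional congruent density [scalar_field()] supplying
#'   the floor mask.
#' @param density_floor e/bohr^3; voxels below it stay unassigned.
#' @param ... passed to [find_attractors()] when it is computed here.
#' @return integer 3-d array of attractor ids (0 = unassigned).
#' @export
assign_basins <- function(field, attractors = NULL, density = NULL,
                          density_floor = 1e-6, ...) {
  stopifnot(inherits(field, "scalar_field"))
  if (is.null(attractors)) attractors <- find_attractors(field, ...)
  if (!identical(attractors$shape, field$shape))
    stop("attractor set does not match the field grid", call. = FALSE)
  parent <- .steepest_parents(field$values)
  # pointer doubling: after ceiling(log2(path length)) sweeps all chains
  # terminate at their root
  repeat {
    nxt <- parent[parent]
    if (identical(nxt, parent)) break
    parent <- nxt
  }
  labels <- attractors$root_map[parent]
  labels[is.na(labels)] <- 0L  # ascent ended on a sub-threshold maximum
  if (!is.null(density)) {
    .check_congruent(field, density)
    labels[as.vector(density$values) < density_floor] <- 0L
  }
  array(labels, dim = field$shape)
}

#' Integrate basin populations
#'
#' Population of basin b is \eqn{\sum_{v \in b} \rho_v \Delta V}. Density
#' in unassigned voxels is accumulated into `unassigned_charge`, so basin
#' populations plus the unassigned charge always reproduce the grid
#' integral.
#'
#' @param labels integer label array from [assign_basins()].
#' @param density congruent density [scalar_field()].
#' @param attractors optional `attractor_set` to attach attractor
#'   positions.
#' @return object of class `basin_set`: data.frame `basins` (`basin_id`,
#'   attractor position, `population`), the label array, the unassigned
#'   charge and the grid total.
#' @export
basin_populations <- function(labels, density, attractors = NULL) {
  stopifnot(inherits(density, "scalar_field"))
  if (!identical(dim(labels), density$shape))
    stop("label grid does not match the density grid", call. = FALSE)
  dv <- voxel_volume(density)
  lab <- as.vector(labels)
  rho <- as.vector(density$values)
  ids <- sort(unique(lab[lab > 0L]))
  pops <- vapply(ids, function(b) sum(rho[lab == b]) * dv, numeric(1))
  unassigned <- sum(rho[lab == 0L]) * dv
  total <- grid_integral(density)
  basins <- data.frame(basin_id = ids, population = pops)
  if (!is.null(attractors)) {
    m <- match(ids, attractors$attractors$id)
    basins$x <- attractors$attractors$x[m]
    basins$y <- attractors$attractors$y[m]
    basins$z <- attractors$attractors$z[m]
    basins$attractor_value <- attractors$attractors$value[m]
  }
  structure(list(basins = basins, labels = labels,
                 unassigned_charge = unassigned, total_electrons = total,
                 origin = density$origin, axes = density$axes,
                 shape = density$shape, atoms = density$atoms),
            class = "basin_set")
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("<basin_set> %d basins, %.4f e total (%.4f e unassigned)\n",
              nrow(x$basins), x$total_electrons, x$unassigned_charge))
  print(x$basins, row.names = FALSE, digits = 4)
  invisible(x)
}

.default_core_radius <- function(z) ifelse(z <= 10, 0.5, 0.9)

#' Classify basin synapticity and generate labels
#'
#' A basin whose attractor sits within the core radius of a heavy nucleus
#' is a core basin `C(A)`. Otherwise its synaptic order is the number of
#' atoms whose core region touches the basin: a heavy atom is associated
#' when the basin reaches within `core_radius(Z)` plus one voxel diagonal
#' of its nucleus, a hydrogen (which has no core) when the basin reaches
#' within `h_radius` of the proton. One atom gives a monosynaptic basin
#' `V(A)` (lone pair), two a disynaptic `V(A,B)` (bond), three or more a
#' polysynaptic basin. Multiple basins sharing an atom set are
#' distinguished with primes: `V(A,B)`, `V'(A,B)`, ...
#'
#' @param basin_set a [basin_populations()] result carrying attractor
#'   positions and atoms.
#' @param atoms optional data.frame (`number`, `x`, `y`, `z` in bohr)
#'   overriding the atoms stored in the basin set.
#' @param core_radius function of atomic number returning the core radius
#'   in bohr.
#' @param h_radius proton association distance in bohr.
#' @return the basin set with columns `kind`, `atoms` (comma-joined atom
#'   indices) and `label` added.
#' @export
classify_synapticity <- function(basin_set, atoms = NULL,
                                 core_radius = .default_core_radius,
                                 h_radius = 1.2) {
  stopifnot(inherits(basin_set, "basin_set"))
  if (is.null(atoms)) atoms <- basin_set$atoms
  if (is.null(atoms))
    stop("no atom positions available for synapticity analysis", call. = FALSE)
  if (!all(c("x", "y", "z") %in% names(basin_set$basins)))
    stop("basin set lacks attractor positions; pass attractors to ",
         "basin_populations()", call. = FALSE)
  apos <- as.matrix(atoms[, c("x", "y", "z")])
  az <- atoms$number
  asym <- paste0(element_symbol(az), seq_along(az))
  vdiag <- sqrt(sum((colSums(abs(basin_set$axes)))^2))
  lab <- as.vector(basin_set$labels)
  allc <- NULL  # voxel coords computed lazily (only when valence basins exist)
  b <- basin_set$basins
  kind <- character(nrow(b)); atom_sets <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    attr_pos <- c(b$x[i], b$y[i], b$z[i])
    d_attr <- sqrt(rowSums(sweep(apos, 2L, attr_pos)^2))
    core_hit <- which(az > 1 & d_attr <= core_radius(az))
    if (length(core_hit)) {
      kind[i] <- "core"
      atom_sets[[i]] <- core_hit[which.min(d_attr[core_hit])]
      next
    }
    if (is.null(allc))
      allc <- voxel_coords(structure(list(shape = basin_set$shape,
                                          axes = basin_set$axes,
                                          origin = basin_set$origin),
                                     class = "scalar_field"))
    vox <- allc[lab == b$basin_id[i], , drop = FALSE]
    mind <- vapply(seq_along(az), function(a)
      sqrt(min(rowSums(sweep(vox, 2L, apos[a, ])^2))), numeric(1))
    reach <- ifelse(az > 1, core_radius(az) + vdiag, h_radius)
    assoc <- which(mind <= reach)
    if (length(assoc) == 0L) {
      warning("basin ", b$basin_id[i],
              " touches no atomic core; assigning nearest atom")
      assoc <- which.min(mind)
    }
    kind[i] <- c("monosynaptic", "disynaptic")[min(length(assoc), 2L)]
    if (length(assoc) >= 3L) kind[i] <- "polysynaptic"
    atom_sets[[i]] <- sort(assoc)
  }
  set_key <- vapply(seq_len(nrow(b)), function(i)
    paste(kind[i], paste(atom_sets[[i]], collapse = ","), sep = "|"), "")
  label <- character(nrow(b))
  for (k in unique(set_key)) {
    sel <- which(set_key == k)
    base <- if (kind[sel[1]] == "core")
      paste0("C(", asym[atom_sets[[sel[1]]]], ")")
    else paste0("V(", paste(asym[atom_sets[[sel[1]]]], collapse = ","), ")")
    primes <- strrep("'", seq_along(sel) - 1L)
    label[sel] <- vapply(primes, function(p) sub("^(C|V)", paste0("\\1", p), base),
                         "", USE.NAMES = FALSE)
  }
  b$kind <- kind
  b$atoms <- vapply(atom_sets, paste, "", collapse = ",")
  b$label <- label
  basin_set$basins <- b
  basin_set$atom_symbols <- asym
  basin_set
}

#' Merge V/V' basins sharing an atom set
#'
#' Reporting convention: basins with identical kind and atom set are
#' summed into one row (the individual basins stay in the basin set).
#'
#' @param basin_set a [classify_synapticity()] result.
#' @return data.frame with `label` (unprimed), `kind`, `atoms`,
#'   `n_basins`, `population`.
#' @export
merge_equivalent <- function(basin_set) {
  stopifnot(inherits(basin_set, "basin_set"))
  b <- basin_set$basins
  if (is.null(b$kind))
    stop("run classify_synapticity() first", call. = FALSE)
  key <- paste(b$kind, b$atoms, sep = "|")
  rows <- lapply(unique(key), function(k) {
    sel <- b[key == k, , drop = FALSE]
    data.frame(label = sub("'", "", sel$label[1], fixed = TRUE),
               kind = sel$kind[1], atoms = sel$atoms[1],
               n_basins = nrow(sel), population = sum(sel$population),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lewis-like bonding summary
#'
#' Interprets merged basin populations as formal structure: a disynaptic
#' population at or above `double_bond` (default 3.2 e) is a double bond,
#' one inside the single-bond window (default 1.6-2.6 e) a single bond,
#' one between the windows is flagged `intermediate` and one below the
#' window `partial`. Monosynaptic populations divided by two and rounded
#' give lone-pair counts.
#'
#' @param basin_set a [classify_synapticity()] result (merging is applied
#'   internally).
#' @param single_window numeric length-2 single-bond population window (e).
#' @param double_bond minimum combined population of a double bond (e).
#' @return list with data.frames `bonds` (`atoms`, `label`, `population`,
#'   `order`) and `lone_pairs` (`atoms`, `label`, `population`,
#'   `n_pairs`), plus the thresholds used.
#' @export
lewis_summary <- function(basin_set, single_window = c(1.6, 2.6),
                          double_bond = 3.2) {
  merged <- merge_equivalent(basin_set)
  di <- merged[merged$kind %in% c("disynaptic", "polysynaptic"), , drop = FALSE]
  order_of <- function(p) {
    if (p >= double_bond) "double"
    else if (p >= single_window[1] && p <= single_window[2]) "single"
    else if (p > single_window[2]) "intermediate"
    else "partial"
  }
  bonds <- if (nrow(di)) data.frame(
    atoms = di$atoms, label = di$label, population = di$population,
    order = vapply(di$population, order_of, ""), stringsAsFactors = FALSE)
  else data.frame(atoms = character(), label = character(),
                  population = numeric(), order = character())
  mono <- merged[merged$kind == "monosynaptic", , drop = FALSE]
  lone <- if (nrow(mono)) data.frame(
    atoms = mono$atoms, label = mono$label, population = mono$population,
    n_pairs = round(mono$population / 2), stringsAsFactors = FALSE)
  else data.frame(atoms = character(), label = character(),
                  population = numeric(), n_pairs = numeric())
  list(bonds = bonds, lone_pairs = lone,
       thresholds = list(single_window = single_window,
                         double_bond = double_bond))
}

#' Full ELF basin analysis of a density (+ kinetic energy) pair
#'
#' Pipeline wrapper: compute (or take) the ELF, find attractors, assign
#' basins, integrate populations against the density, and — when atom
#' positions are available — classify synapticity.
#'
#' @param density density [scalar_field()].
#' @param tau kinetic-energy density field (ignored when `elf` given).
#' @param elf optional precomputed ELF field.
#' @param merge_radius attractor coalescence radius (bohr).
#' @param density_floor unassigned-charge floor (e/bohr^3).
#' @param ... passed to [classify_synapticity()].
#' @return a [basin_populations()] `basin_set`, with synapticity columns
#'   when atoms are known.
#' @export
elf_basins <- function(density, tau = NULL, elf = NULL, merge_radius = 0.2,
                       density_floor = 1e-6, ...) {
  if (is.null(elf)) {
    if (is.null(tau))
      stop("supply either a precomputed elf field or a tau field", call. = FALSE)
    elf <- elf_from_fields(density, tau)
  } else .check_congruent(density, elf)
  # the ELF is numerically meaningless where the density has decayed to
  # noise; zero it below the floor so tail voxels cannot seed attractors
  ev <- elf$values
  ev[density$values < density_floor] <- 0
  elf <- scalar_field(ev, elf$origin, elf$axes, "elf", atoms = elf$atoms)
  att <- find_attractors(elf, merge_radius = merge_radius)
  labels <- assign_basins(elf, att, density = density,
                          density_floor = density_floor)
  bs <- basin_populations(labels, density, att)
  if (!is.null(density$atoms)) bs <- classify_synapticity(bs, ...)
  bs
}
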