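#' Van der Waals radii for heavy atoms
#'
#' Bondi-style element-keyed radii (Angstrom) used to build the
#' probe-expanded spheres of the Shrake-Rupley quadrature. Hydrogens are
#' listed for completeness but crystal-structure inputs are expected to be
#' heavy-atom only.
#'
#' @param overrides Named numeric vector of element -> radius replacements
#'   or additions.
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radii()[["P"]]
#' vdw_radii(c(C = 1.8))[["C"]]
vdw_radii <- function(overrides = NULL) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)), all(overrides > 0))
    r[names(overrides)] <- overrides
  }
  r
}

#' ASA computation settings
#'
#' @param probe_radius Solvent probe radius in Angstrom. The default 0.75
#'   corresponds to a probe *diameter* of 1.5 Angstrom; set 1.4 for the
#'   conventional water-probe radius.
#' @param n_sphere_points Number of quadrature points per atom (deterministic
#'   Fibonacci lattice). At least 24.
#' @param norm_constant Area (Angstrom^2) dividing raw residue ASA to give the
#'   dimensionless regression target; default 400.
#' @return A list of class `asa_config`.
#' @export
asa_config <- function(probe_radius = 0.75, n_sphere_points = 960,
                       norm_constant = 400) {
  if (!is.numeric(probe_radius) || probe_radius < 0) {
    stop("`probe_radius` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(n_sphere_points) || n_sphere_points < 24) {
    stop("`n_sphere_points` must be at least 24", call. = FALSE)
  }
  if (!is.numeric(norm_constant) || norm_constant <= 0) {
    stop("`norm_constant` must be positive", call. = FALSE)
  }
  structure(
    list(
      probe_radius = probe_radius,
      n_sphere_points = as.integer(n_sphere_points),
      norm_constant = norm_constant
    ),
    class = "asa_config"
  )
}

# Quasi-uniform unit-sphere points; deterministic, no RNG.
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom accessible surface area (Shrake-Rupley)
#'
#' Places a deterministic quasi-uniform point lattice on each atom's
#' probe-expanded sphere and counts points not buried inside any neighbour's
#' expanded sphere; the exposed fraction times the sphere area is the atom's
#' ASA.
#'
#' @param atoms A data frame with columns `x`, `y`, `z` (Angstrom) and
#'   `vdw_radius` (Angstrom); typically an atom table from [read_rna_structure()]
#'   or [make_synthetic_chain()].
#' @param cfg An [asa_config()].
#' @return The input tibble with an added `asa` column (Angstrom^2 per atom).
#' @export
#' @examples
#' one <- tibble::tibble(x = 0, y = 0, z = 0, vdw_radius = 1.9)
#' compute_atom_asa(one)$asa       # ~ 4*pi*(1.9+0.75)^2
compute_atom_asa <- function(atoms, cfg = asa_config()) {
  stopifnot(is.data.frame(atoms), all(c("x", "y", "z", "vdw_radius") %in% names(atoms)))
  n <- nrow(atoms)
  if (n == 0) stop("`atoms` must contain at least one atom", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinate", call. = FALSE)
  rad <- atoms$vdw_radius
  if (any(!is.finite(rad)) || any(rad <= 0)) {
    stop("every `vdw_radius` must be positive and finite", call. = FALSE)
  }
  R <- rad + cfg$probe_radius
  pts <- fibonacci_sphere(cfg$n_sphere_points)
  np <- nrow(pts)

  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded sphere can reach atom i's shell
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    shell <- pts * R[i]
    shell <- sweep(shell, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, np)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- shell[exposed, 1] - xyz[j, 1]
      dy <- shell[exposed, 2] - xyz[j, 2]
      dz <- shell[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- (dx * dx + dy * dy + dz * dz) >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(exposed) / np
  }
  dplyr::mutate(tibble::as_tibble(atoms), asa = area)
}

#' Aggregate atom areas to per-residue ASA
#'
#' Residue ASA is the sum of its atoms' areas, so the residue total
#' partitions the atom total exactly.
#'
#' @param atom_asa Atom tibble carrying `asa`, `residue_index` (0-based) and
#'   `residue_base` columns, as returned by [compute_atom_asa()].
#' @param cfg An [asa_config()]; supplies `norm_constant`.
#' @return A tibble with one row per residue: `residue_index`, `base`,
#'   `asa` (Angstrom^2) and `asa_norm` (= asa / norm_constant).
#' @export
aggregate_residue_asa <- function(atom_asa, cfg = asa_config()) {
  stopifnot(is.data.frame(atom_asa),
            all(c("asa", "residue_index", "residue_base") %in% names(atom_asa)))
  if (any(atom_asa$asa < 0)) stop("negative atom area", call. = FALSE)
  atom_asa |>
    dplyr::group_by(residue_index = .data$residue_index) |>
    dplyr::summarise(
      base = dplyr::first(.data$residue_base),
      asa = sum(.data$asa),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$residue_index) |>
    dplyr::mutate(asa_norm = .data$asa / cfg$norm_constant)
}

#' Standard heavy-atom inventories for RNA nucleotides
#'
#' Full ribonucleotide heavy-atom name sets (sugar + phosphate + base) used
#' by the completeness filter. Synthetic fixtures use their own reduced
#' inventories; pass those via the `expected` argument of
#' [completeness_mask()] instead.
#'
#' @param base One of "A", "C", "G", "U".
#' @return Character vector of expected atom names, or `NULL` for an unknown
#'   base.
#' @export
rna_atom_inventory <- function(base) {
  sugar <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
             "C2'", "O2'", "C1'")
  bases <- list(
    A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
  )
  if (!base %in% names(bases)) return(NULL)
  c(sugar, bases[[base]])
}

#' Completeness filter over a residue chain
#'
#' A residue is usable as a regression target only if it and its two nearest
#' sequence neighbours (those that exist; terminals have one) each contain
#' their full expected atom inventory — missing atoms would bias the local
#' ASA. Unknown base types with no inventory are marked invalid with a
#' warning.
#'
#' @param residues A tibble with columns `residue_index` (0-based, ordered)
#'   and `base`, plus a list-column `atom_names` of observed atom names per
#'   residue. [atoms_to_residues()] builds this from an atom table.
#' @param expected Either `NULL` (use [rna_atom_inventory()]) or a named list
#'   base -> character vector of expected atom names.
#' @return The input tibble with logical columns `complete` (this residue has
#'   all expected atoms) and `valid` (it and its existing neighbours are all
#'   complete).
#' @export
completeness_mask <- function(residues, expected = NULL) {
  stopifnot(is.data.frame(residues),
            all(c("residue_index", "base", "atom_names") %in% names(residues)))
  lookup <- function(b) {
    if (is.null(expected)) rna_atom_inventory(b) else expected[[b]]
  }
  complete <- purrr::map2_lgl(residues$base, residues$atom_names, function(b, obs) {
    inv <- lookup(b)
    if (is.null(inv)) {
      warning("no atom inventory for base '", b, "'; residue marked invalid",
              call. = FALSE)
      return(FALSE)
    }
    all(inv %in% obs)
  })
  n <- length(complete)
  valid <- vapply(seq_len(n), function(i) {
    all(complete[max(1, i - 1):min(n, i + 1)])
  }, logical(1))
  dplyr::mutate(tibble::as_tibble(residues), complete = complete, valid = valid)
}

#' Collapse an atom table into the per-residue shape the completeness filter reads
#'
#' @param atoms Atom tibble with `atom_name`, `residue_index`, `residue_base`.
#' @return Tibble with `residue_index`, `base`, and list-column `atom_names`.
#' @export
atoms_to_residues <- function(atoms) {
  stopifnot(all(c("atom_name", "residue_index", "residue_base") %in% names(atoms)))
  atoms |>
    dplyr::group_by(residue_index = .data$residue_index) |>
    dplyr::summarise(
      base = dplyr::first(.data$residue_base),
      atom_names = list(.data$atom_name),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$residue_index)
}

#' Normalize / denormalize ASA
#'
#' Raw areas are divided uniformly by the configured constant (default
#' 400 Angstrom^2) to give the dimensionless regression target. Values above
#' the constant map above 1 and are deliberately not clipped here, so the
#' transform is invertible; clipping applies only to model predictions.
#'
#' @param asa Non-negative areas in Angstrom^2.
#' @param cfg An [asa_config()].
#' @return Dimensionless values.
#' @export
normalize_asa <- function(asa, cfg = asa_config()) {
  if (any(asa < 0)) stop("ASA must be non-negative", call. = FALSE)
  asa / cfg$norm_constant
}

#' @rdname normalize_asa
#' @param asa_norm Dimensionless normalized values.
#' @export
denormalize_asa <- function(asa_norm, cfg = asa_config()) {
  asa_norm * cfg$norm_constant
}

#' Per-residue ASA of one RNA chain, end to end
#'
#' Runs the quadrature, aggregates to residues, and applies the completeness
#' filter in one call.
#'
#' @inheritParams compute_atom_asa
#' @param expected Atom inventories for the completeness filter; see
#'   [completeness_mask()].
#' @return Tibble: `residue_index`, `base`, `asa`, `asa_norm`, `valid`.
#' @export
chain_asa <- function(atoms, cfg = asa_config(), expected = NULL) {
  per_atom <- compute_atom_asa(atoms, cfg)
  res <- aggregate_residue_asa(per_atom, cfg)
  mask <- completeness_mask(atoms_to_residues(atoms), expected = expected)
  dplyr::left_join(res, mask[, c("residue_index", "valid")], by = "residue_index")
}
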