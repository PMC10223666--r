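# Molecule/role topology: maps atoms to molecules and tags the roles every
# analyzer needs (headgroup O1/O2, ordered tail carbons, peptide C-alphas).

#' Construct a molecule map
#'
#' @param atoms tibble with one row per atom and columns `atom` (1-based
#'   index), `molecule_id`, `species` (one of amphiphile/peptide/water/ion),
#'   `role` (one of `"o1"`, `"o2"`, `"tail"`, `"calpha"`, `"other"`),
#'   `role_index` (tail carbon number C1..C10 or peptide residue number; `NA`
#'   otherwise) and `element`.
#' @return an object of class `molecule_map` with `$atoms` (the atom table)
#'   and `$molecules` (one row per molecule: `molecule_id`, `species`,
#'   `n_atoms`).
#' @export
new_molecule_map <- function(atoms) {
  req <- c("atom", "molecule_id", "species", "role", "role_index", "element")
  if (!all(req %in% names(atoms))) {
    abort(paste("atom table must have columns:", paste(req, collapse = ", ")),
      class = "vesitraj_topology_error")
  }
  atoms <- tibble::as_tibble(atoms)
  bad <- setdiff(unique(atoms$species), c("amphiphile", "peptide", "water", "ion"))
  if (length(bad) > 0) {
    abort(paste("unknown species:", paste(bad, collapse = ", ")),
      class = "vesitraj_topology_error")
  }
  if (anyDuplicated(atoms$atom)) {
    abort("atom claimed by more than one molecule", class = "vesitraj_topology_error")
  }
  molecules <- atoms |>
    dplyr::count(.data$molecule_id, .data$species, name = "n_atoms") |>
    dplyr::arrange(.data$molecule_id)
  structure(list(atoms = atoms, molecules = molecules), class = "molecule_map")
}

#' @export
print.molecule_map <- function(x, ...) {
  tab <- table(x$molecules$species)
  cat(sprintf(
    "<molecule_map> %d atoms in %d molecules (%s)\n",
    nrow(x$atoms), nrow(x$molecules),
    paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", ")
  ))
  invisible(x)
}

#' Read a topology declaration file
#'
#' The topology is declared in a small YAML file rather than inferred from
#' atom names (XYZ files carry no names). Schema: a top-level `molecules`
#' list; each block has `species`, `count`, `atoms` (atoms per molecule),
#' optional `first_atom` (default: consecutive after the previous block),
#' optional `elements` (length-1 or per-atom) and optional `roles` with keys
#' `o1`, `o2` (scalar within-molecule 1-based indices), `tail` (ordered
#' within-molecule indices of C1..C10, carboxyl carbon first) and `calpha`
#' (ordered by residue).
#'
#' @param path YAML file path.
#' @return the parsed specification (list), validated structurally.
#' @export
read_topology_spec <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("topology file not found: %s", path), class = "vesitraj_io_error")
  }
  spec <- yaml::read_yaml(path)
  if (is.null(spec$molecules) || length(spec$molecules) == 0) {
    abort("topology must declare a non-empty `molecules` list",
      class = "vesitraj_topology_error")
  }
  spec
}

#' Build a molecule map from a trajectory and a topology declaration
#'
#' Every atom of the trajectory must be claimed by exactly one molecule
#' block; blocks claiming an atom twice or leaving atoms unclaimed raise a
#' topology error.
#'
#' @param trajectory a `trajectory` object (supplies the atom count and
#'   default elements).
#' @param topology_spec a list as returned by [read_topology_spec()].
#' @return a [new_molecule_map()] object.
#' @export
build_molecule_map <- function(trajectory, topology_spec) {
  n_total <- trajectory$atom_count
  rows <- list()
  next_atom <- 1L
  next_mol <- 1L
  claimed <- integer(n_total)
  for (blk in topology_spec$molecules) {
    species <- blk$species %||% abort("molecule block missing `species`",
      class = "vesitraj_topology_error")
    count <- as.integer(blk$count %||% 1L)
    apm <- as.integer(blk$atoms %||% abort("molecule block missing `atoms`",
      class = "vesitraj_topology_error"))
    first <- as.integer(blk$first_atom %||% next_atom)
    elements <- blk$elements
    roles <- blk$roles %||% list()
    role <- rep("other", apm)
    role_index <- rep(NA_integer_, apm)
    if (!is.null(roles$o1)) role[roles$o1] <- "o1"
    if (!is.null(roles$o2)) role[roles$o2] <- "o2"
    if (!is.null(roles$tail)) {
      role[unlist(roles$tail)] <- "tail"
      role_index[unlist(roles$tail)] <- seq_along(unlist(roles$tail))
    }
    if (!is.null(roles$calpha)) {
      role[unlist(roles$calpha)] <- "calpha"
      role_index[unlist(roles$calpha)] <- seq_along(unlist(roles$calpha))
    }
    el <- if (is.null(elements)) {
      NULL
    } else if (length(elements) == 1) {
      rep(as.character(elements), apm)
    } else {
      as.character(unlist(elements))
    }
    if (!is.null(el) && length(el) != apm) {
      abort("`elements` must be length 1 or one per atom in the molecule",
        class = "vesitraj_topology_error")
    }
    for (m in seq_len(count)) {
      at <- first + (m - 1L) * apm + seq_len(apm) - 1L
      if (any(at > n_total)) {
        abort("topology claims atoms beyond the trajectory atom count",
          class = "vesitraj_topology_error")
      }
      claimed[at] <- claimed[at] + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        atom = at,
        molecule_id = next_mol,
        species = species,
        role = role,
        role_index = role_index,
        element = el %||% trajectory$elements[at]
      )
      next_mol <- next_mol + 1L
    }
    next_atom <- max(next_atom, first + count * apm)
  }
  if (any(claimed > 1L)) {
    abort(sprintf("topology claims %d atom(s) more than once", sum(claimed > 1L)),
      class = "vesitraj_topology_error")
  }
  if (any(claimed == 0L)) {
    abort(sprintf("topology leaves %d atom(s) unclaimed", sum(claimed == 0L)),
      class = "vesitraj_topology_error")
  }
  new_molecule_map(dplyr::bind_rows(rows))
}

#' Select atom indices by species and role
#'
#' @param map a `molecule_map`.
#' @param species optional species filter.
#' @param role optional role filter (`"o1"`, `"o2"`, `"tail"`, `"calpha"`,
#'   `"other"`).
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(map, species = NULL, role = NULL) {
  at <- map$atoms
  if (!is.null(species)) at <- at[at$species %in% species, ]
  if (!is.null(role)) at <- at[at$role %in% role, ]
  at$atom
}

#' Molecule ids of a species
#' @param map a `molecule_map`.
#' @param species species name.
#' @return integer vector of molecule ids.
#' @export
molecule_ids <- function(map, species = "amphiphile") {
  map$molecules$molecule_id[map$molecules$species %in% species]
}

# Per-monomer cached index lists used by hot loops. Returns a list with
# integer matrices/vectors aligned with molecule_ids(map, "amphiphile").
amphiphile_index <- function(map) {
  at <- map$atoms[map$atoms$species == "amphiphile", ]
  ids <- sort(unique(at$molecule_id))
  o1 <- at$atom[at$role == "o1"][order(at$molecule_id[at$role == "o1"])]
  o2 <- at$atom[at$role == "o2"][order(at$molecule_id[at$role == "o2"])]
  tails <- at[at$role == "tail", ]
  tails <- tails[order(tails$molecule_id, tails$role_index), ]
  n_tail <- length(unique(tails$role_index))
  tail_mat <- matrix(tails$atom, ncol = n_tail, byrow = TRUE)
  all_by_mol <- split(at$atom, at$molecule_id)
  list(
    ids = ids, o1 = o1, o2 = o2, tail = tail_mat,
    atoms = all_by_mol, n_tail = n_tail
  )
}

# Midpoints of O1/O2 per amphiphile for one frame: n_amph x 3 matrix.
headgroup_midpoints <- function(coords, idx) {
  (coords[idx$o1, , drop = FALSE] + coords[idx$o2, , drop = FALSE]) / 2
}

# Unweighted heavy-atom centroids of the selected molecules for one frame.
molecule_centroids <- function(coords, map, species = "amphiphile") {
  at <- map$atoms[map$atoms$species %in% species, ]
  cs <- rowsum(coords[at$atom, , drop = FALSE], group = at$molecule_id)
  n <- as.vector(table(at$molecule_id)[rownames(cs)])
  sweep(cs, 1, n, "/")
}

#' Default van der Waals radius table
#'
#' Bondi-style radii (Angstrom) for the elements that occur in amphiphile /
#' peptide systems, with a water probe. Override entries by passing a named
#' numeric vector to the `radii` argument of [sasa()].
#'
#' @param probe_radius probe sphere radius in Angstrom (default 1.4, water).
#' @return list with `radii` (named numeric, Angstrom) and `probe_radius`.
#' @export
default_radius_table <- function(probe_radius = 1.4) {
  stopifnot(probe_radius >= 0)
  radii <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Na = 2.27, K = 2.75
  )
  list(radii = radii, probe_radius = probe_radius)
}
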