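# Helix tilt against the local bilayer normal and orientation classes.

#' Peptide axis from the terminal C-alpha atoms
#'
#' The unit vector from the C-alpha of the first residue to the C-alpha of
#' the last residue. Antisymmetric: reversing the residue order negates it.
#'
#' @param frame a frame (list with `coords`) or coordinate matrix.
#' @param map a `molecule_map` with a peptide C-alpha trace.
#' @return unit 3-vector.
#' @export
peptide_axis <- function(frame, map) {
  coords <- if (is.matrix(frame)) frame else frame$coords
  ca <- map$atoms[map$atoms$role == "calpha", ]
  if (nrow(ca) < 2) {
    abort("peptide axis needs at least 2 C-alpha atoms",
      class = "vesitraj_axis_undefined")
  }
  ca <- ca[order(ca$role_index), ]
  unit_vec(coords[ca$atom[nrow(ca)], ] - coords[ca$atom[1], ])
}

#' Local bilayer normal near the peptide
#'
#' Amphiphile monomers with any heavy atom within `cutoff` of any peptide
#' atom qualify; the normal is the normalised average of their outward
#' radial unit vectors (vesicle center to headgroup midpoint). Referencing
#' only nearby monomers avoids curvature perturbations from the rest of the
#' vesicle.
#'
#' @param frame a frame (list with `coords`) or coordinate matrix.
#' @param map a `molecule_map`.
#' @param cutoff qualification distance in Angstrom (default 8).
#' @param min_support minimum number of qualifying monomers (default 5);
#'   below it the normal is undefined for the frame.
#' @param center vesicle center; default [vesicle_center()].
#' @param weighting `"linear"` tapers each qualifying monomer's contribution
#'   as `1 - d/cutoff` with its distance `d` to the peptide, which damps the
#'   sampling noise from monomers entering and leaving at the cutoff edge;
#'   `"uniform"` is the plain average.
#' @return list with `normal` (unit 3-vector, or `NULL` when undefined) and
#'   `support` (qualifying monomer count).
#' @export
local_bilayer_normal <- function(frame, map, cutoff = 8, min_support = 5,
                                 center = NULL,
                                 weighting = c("linear", "uniform")) {
  weighting <- match.arg(weighting)
  coords <- if (is.matrix(frame)) frame else frame$coords
  if (is.null(center)) center <- vesicle_center(coords, map)
  pep_atoms <- select_atoms(map, species = "peptide")
  if (length(pep_atoms) == 0) {
    abort("no peptide atoms in the map", class = "vesitraj_selection_error")
  }
  pep <- coords[pep_atoms, , drop = FALSE]
  idx <- amphiphile_index(map)
  heads <- headgroup_midpoints(coords, idx)
  n_mono <- length(idx$ids)
  pep_ctr <- colMeans(pep)
  pep_ext <- max(row_norms(sweep(pep, 2, pep_ctr)))
  # vectorised centroid prefilter, exact min distance only for candidates
  at <- map$atoms[map$atoms$species == "amphiphile", ]
  amph_co <- coords[at$atom, , drop = FALSE]
  cents <- rowsum(amph_co, group = at$molecule_id)
  n_per <- as.vector(table(at$molecule_id))
  cents <- cents / n_per
  mol_row <- match(at$molecule_id, idx$ids)
  ext <- tapply(row_norms(amph_co - cents[mol_row, , drop = FALSE]),
    at$molecule_id, max)
  cand <- which(row_norms(sweep(cents, 2, pep_ctr)) <= cutoff + ext + pep_ext)
  dmin <- rep(Inf, n_mono)
  for (i in cand) {
    mono <- coords[idx$atoms[[as.character(idx$ids[i])]], , drop = FALSE]
    d2 <- matrix(rowSums(mono^2), nrow(mono), nrow(pep)) +
      matrix(rowSums(pep^2), nrow(mono), nrow(pep), byrow = TRUE) -
      2 * tcrossprod(mono, pep)
    dmin[i] <- sqrt(max(min(d2), 0))
  }
  qual <- dmin <= cutoff
  support <- sum(qual)
  if (support < min_support) {
    return(list(normal = NULL, support = support))
  }
  w <- if (weighting == "linear") pmax(0, 1 - dmin / cutoff) else as.numeric(qual)
  u <- sweep(heads, 2, center)
  u <- u / row_norms(u)
  list(normal = unit_vec(colSums(u * w)), support = support)
}

TILT_WINDOWS_DEFAULT <- list(
  inserted_c_to_n = c(0, 30),
  surface = c(60, 120),
  inserted_n_to_c = c(150, 180)
)

#' Classify a tilt angle
#'
#' Default windows: 0--30 degrees `inserted_c_to_n` (helix pointing along
#' the outward normal, i.e. inserted C-terminus to N-terminus), 60--120
#' `surface` (lying on the bilayer), 150--180 `inserted_n_to_c`; anything
#' else `intermediate`.
#'
#' @param angle_deg tilt angle(s) in degrees.
#' @param windows named list of `c(lo, hi)` degree windows.
#' @return character class vector.
#' @export
classify_tilt <- function(angle_deg, windows = TILT_WINDOWS_DEFAULT) {
  vapply(angle_deg, function(a) {
    if (is.na(a)) return(NA_character_)
    for (nm in names(windows)) {
      w <- windows[[nm]]
      if (a >= w[1] && a <= w[2]) return(nm)
    }
    "intermediate"
  }, character(1))
}

#' Tilt angle between peptide axis and bilayer normal
#'
#' @param axis unit peptide axis from [peptide_axis()].
#' @param normal unit local bilayer normal from [local_bilayer_normal()].
#' @param windows class windows for [classify_tilt()].
#' @return list with `angle_deg` in `[0, 180]` and `class`.
#' @export
tilt_angle <- function(axis, normal, windows = TILT_WINDOWS_DEFAULT) {
  axis <- unit_vec(axis)
  normal <- unit_vec(normal)
  ang <- deg(acos(pmin(pmax(sum(axis * normal), -1), 1)))
  list(angle_deg = ang, class = classify_tilt(ang, windows))
}

#' Per-frame tilt series
#'
#' Computes the peptide axis, the local bilayer normal and the tilt angle
#' for every selected frame. Frames whose local normal is undefined (too few
#' amphiphiles within the cutoff) get a missing tilt and are flagged.
#'
#' @param trajectory a `trajectory`.
#' @param map a `molecule_map` with a peptide.
#' @param cutoff,min_support forwarded to [local_bilayer_normal()].
#' @param windows forwarded to [classify_tilt()].
#' @param frames integer frame indices (default all).
#' @return tibble of class `tilt_series`: `frame`, `time_ns`, `tilt_deg`,
#'   `class`, `support`, `missing`.
#' @export
tilt_series <- function(trajectory, map, cutoff = 8, min_support = 5,
                        windows = TILT_WINDOWS_DEFAULT, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(trajectory))
  times <- frame_times(trajectory)
  rows <- purrr::map_dfr(frames, function(f) {
    co <- frame_coords(trajectory, f)
    ax <- peptide_axis(co, map)
    nl <- local_bilayer_normal(co, map, cutoff = cutoff, min_support = min_support)
    if (is.null(nl$normal)) {
      tibble::tibble(frame = f, time_ns = times[f], tilt_deg = NA_real_,
        class = NA_character_, support = nl$support, missing = TRUE)
    } else {
      ta <- tilt_angle(ax, nl$normal, windows)
      tibble::tibble(frame = f, time_ns = times[f], tilt_deg = ta$angle_deg,
        class = ta$class, support = nl$support, missing = FALSE)
    }
  })
  structure(rows, class = c("tilt_series", class(rows)))
}
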