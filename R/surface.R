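# Surface and ordering observables: Shrake-Rupley SASA, curvature-corrected
# chain order parameters, 2-D headgroup density maps, radial distribution
# functions.

# grid-cell candidate lists: for each atom, the atoms in its 27-cell
# neighbourhood (computed once per occupied cell, not per atom)
cell_candidates <- function(coords, cutoff) {
  key_of <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
  cell <- floor(coords / cutoff)
  keys <- key_of(cell)
  bucket <- split(seq_len(nrow(coords)), keys)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cell_first <- !duplicated(keys)
  nb_by_cell <- lapply(which(cell_first), function(i) {
    nb_keys <- key_of(sweep(offsets, 2, as.numeric(cell[i, ]), "+"))
    unlist(bucket[nb_keys], use.names = FALSE)
  })
  names(nb_by_cell) <- keys[cell_first]
  lapply(seq_len(nrow(coords)), function(i) nb_by_cell[[keys[i]]])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, `n_points` quasi-uniform points are placed on its expanded
#' sphere (van der Waals radius + probe); the accessible fraction (points
#' not buried inside any neighbour's expanded sphere) times the expanded
#' sphere area is the atom's contribution. An isolated atom therefore gets
#' exactly `4 pi (r + probe)^2`.
#'
#' @param frame a frame (list with `coords`) or coordinate matrix (Angstrom).
#' @param map a `molecule_map` (supplies elements); or pass `elements`.
#' @param radii radius table from [default_radius_table()]; `$probe_radius`
#'   sets the probe.
#' @param n_points sphere points per atom (>= 100; default 960).
#' @param selection integer atom indices to include (default: all atoms of
#'   the map). SASA is computed among the selected atoms only, so the choice
#'   of selection (e.g. amphiphiles only vs the whole system) is explicit.
#' @param elements optional explicit element vector overriding the map.
#' @return object of class `sasa_result`: `total_nm2`, `per_atom` (tibble
#'   `atom`, `element`, `area_A2`, `area_nm2`), `probe_radius`, `n_points`.
#' @export
sasa <- function(frame, map = NULL, radii = default_radius_table(),
                 n_points = 960, selection = NULL, elements = NULL) {
  stopifnot(n_points >= 100)
  coords <- if (is.matrix(frame)) frame else frame$coords
  if (is.null(elements)) {
    if (is.null(map)) abort("need either a molecule map or an elements vector",
      class = "vesitraj_config_error")
    elements <- map$atoms$element[order(map$atoms$atom)]
  }
  selection <- selection %||% seq_len(nrow(coords))
  coords <- coords[selection, , drop = FALSE]
  el <- elements[selection]
  missing_el <- setdiff(unique(el), names(radii$radii))
  if (length(missing_el) > 0) {
    abort(paste("no van der Waals radius for element(s):",
      paste(missing_el, collapse = ", ")), class = "vesitraj_config_error")
  }
  r_exp <- radii$radii[el] + radii$probe_radius
  n <- nrow(coords)
  pts <- fibonacci_sphere(n_points)
  cutoff <- 2 * max(r_exp)
  cand <- if (n > 1) cell_candidates(coords, cutoff) else NULL
  pt_norm2 <- rowSums(pts^2)  # == 1; kept for clarity of the d2 expansion
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    if (!is.null(cand)) {
      cc <- cand[[i]]
      cc <- cc[cc != i]
      if (length(cc) > 0) {
        dd <- row_norms(sweep(coords[cc, , drop = FALSE], 2, coords[i, ]))
        nb <- cc[dd < r_exp[i] + r_exp[cc]]
      }
    }
    if (length(nb) > 0) {
      P <- sweep(pts * r_exp[i], 2, coords[i, ], "+")
      nbco <- coords[nb, , drop = FALSE]
      d2 <- matrix(rowSums(P^2), n_points, length(nb)) +
        matrix(rowSums(nbco^2), n_points, length(nb), byrow = TRUE) -
        2 * tcrossprod(P, nbco)
      buried <- rowSums(d2 < matrix(r_exp[nb]^2, n_points, length(nb),
        byrow = TRUE)) > 0
      frac <- mean(!buried)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * r_exp[i]^2
  }
  per_atom <- tibble::tibble(
    atom = selection, element = el, area_A2 = area, area_nm2 = area / 100
  )
  structure(
    list(
      total_nm2 = sum(per_atom$area_nm2), per_atom = per_atom,
      probe_radius = radii$probe_radius, n_points = n_points
    ),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.2f nm^2 over %d atoms (probe %.2f A, %d points)\n",
    x$total_nm2, nrow(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Order parameter from orientation cosines
#'
#' `S = <3 cos^2(theta) - 1> / 2` for a sample of angles between the CH
#' (or proxy) vector and the reference axis. `S = -0.5` for perpendicular
#' alignment, `1` for parallel, `0` for isotropic orientations (and at the
#' magic angle, 54.74 degrees).
#'
#' @param cos_theta numeric vector of orientation cosines.
#' @return scalar order parameter in `[-0.5, 1]`.
#' @export
chain_order_s <- function(cos_theta) {
  mean(3 * cos_theta^2 - 1) / 2
}

#' Curvature-corrected chain order parameters
#'
#' For each monomer the local membrane normal is the outward radial
#' direction at its headgroup, which is equivalent to reorienting every
#' molecule so that its local normal maps onto the z axis before measuring
#' angles (the curvature correction). For each interior tail carbon `C_i`
#' the segment vector `C_(i-1) -> C_(i+1)` defines the chain direction; the
#' CH-proxy direction at `C_i` is the in-plane bisector of the two C-C
#' bonds, projected perpendicular to the segment (a standard heavy-atom
#' reconstruction when hydrogens are absent). `S` is averaged over molecules
#' and frames per carbon.
#'
#' @param trajectory a `trajectory`.
#' @param map a `molecule_map`.
#' @param frames integer frame indices (default all).
#' @param center optional fixed vesicle center; default per-frame
#'   [vesicle_center()].
#' @return tibble of class `order_profile`: `carbon` (index along the
#'   chain), `s_ch`, `n_samples`. Monomers with degenerate geometry are
#'   skipped and reported via the `n_samples` column.
#' @export
order_parameters <- function(trajectory, map, frames = NULL, center = NULL) {
  frames <- frames %||% seq_len(n_frames(trajectory))
  idx <- amphiphile_index(map)
  nC <- idx$n_tail
  if (nC < 3) abort("need at least 3 ordered tail carbons", class = "vesitraj_topology_error")
  carbons <- 2:(nC - 1)
  s_sum <- numeric(length(carbons))
  n_samp <- integer(length(carbons))
  for (f in frames) {
    co <- frame_coords(trajectory, f)
    ctr <- center %||% vesicle_center(co, map)
    heads <- headgroup_midpoints(co, idx)
    u <- sweep(heads, 2, ctr)
    u <- u / row_norms(u)
    for (k in seq_along(carbons)) {
      i <- carbons[k]
      prev <- co[idx$tail[, i - 1], , drop = FALSE]
      cur <- co[idx$tail[, i], , drop = FALSE]
      nxt <- co[idx$tail[, i + 1], , drop = FALSE]
      v <- nxt - prev
      vn <- row_norms(v)
      b1 <- prev - cur
      b2 <- nxt - cur
      h <- b1 / row_norms(b1) + b2 / row_norms(b2)
      # project the bisector perpendicular to the segment vector
      vhat <- v / pmax(vn, 1e-12)
      h <- h - vhat * rowSums(h * vhat)
      hn <- row_norms(h)
      ok <- vn > 1e-6 & hn > 1e-6
      cosb <- rowSums((h / pmax(hn, 1e-12)) * u)
      s_sum[k] <- s_sum[k] + sum((3 * cosb[ok]^2 - 1) / 2)
      n_samp[k] <- n_samp[k] + sum(ok)
    }
  }
  structure(
    tibble::tibble(carbon = carbons, s_ch = s_sum / pmax(n_samp, 1),
      n_samples = n_samp),
    class = c("order_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' 2-D headgroup density map
#'
#' Headgroup midpoints of the chosen leaflet are projected to spherical
#' coordinates about the vesicle center and binned on an equal-area
#' `(cos theta, phi)` grid, so a uniformly covered shell gives a flat map.
#'
#' @param trajectory a `trajectory`.
#' @param map a `molecule_map`.
#' @param labels leaflet labels from [assign_leaflets()].
#' @param leaflet `"outer"` or `"inner"`.
#' @param n_cos,n_phi grid resolution (cells are `2/n_cos` by `2 pi/n_phi`).
#' @param frames integer frame indices (default all).
#' @return tibble of class `density_map2d`: `cos_bin`, `phi_bin`,
#'   `cos_mid`, `phi_mid`, `count`, `rel_density` (1 = uniform). The counts
#'   sum to the number of binned headgroups times the number of frames.
#' @export
density_map <- function(trajectory, map, labels, leaflet = "outer",
                        n_cos = 12, n_phi = 24, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(trajectory))
  idx <- amphiphile_index(map)
  sel <- which(labels$label[match(idx$ids, labels$molecule_id)] == leaflet)
  if (length(sel) == 0) {
    warn(sprintf("no monomers in the %s leaflet: empty map", leaflet))
  }
  counts <- matrix(0L, n_cos, n_phi)
  for (f in frames) {
    co <- frame_coords(trajectory, f)
    ctr <- vesicle_center(co, map)
    heads <- headgroup_midpoints(co, idx)[sel, , drop = FALSE]
    if (nrow(heads) == 0) next
    rel <- sweep(heads, 2, ctr)
    r <- row_norms(rel)
    cz <- rel[, 3] / r
    phi <- atan2(rel[, 2], rel[, 1])
    ic <- pmin(pmax(floor((cz + 1) / 2 * n_cos) + 1, 1), n_cos)
    ip <- pmin(pmax(floor((phi + pi) / (2 * pi) * n_phi) + 1, 1), n_phi)
    for (k in seq_along(ic)) counts[ic[k], ip[k]] <- counts[ic[k], ip[k]] + 1L
  }
  total <- sum(counts)
  grid <- tidyr::expand_grid(cos_bin = seq_len(n_cos), phi_bin = seq_len(n_phi))
  grid$cos_mid <- -1 + (grid$cos_bin - 0.5) * 2 / n_cos
  grid$phi_mid <- -pi + (grid$phi_bin - 0.5) * 2 * pi / n_phi
  grid$count <- counts[cbind(grid$cos_bin, grid$phi_bin)]
  grid$rel_density <- if (total > 0) {
    grid$count / (total / (n_cos * n_phi))
  } else {
    rep(NA_real_, nrow(grid))
  }
  structure(grid, class = c("density_map2d", class(grid)))
}

#' Radial distribution function between two atom groups
#'
#' Pairwise distances between `group_a` and `group_b` atoms are histogrammed
#' in shells of width `bin_width` up to `r_max`, shell-volume normalised and
#' scaled by the mean number density of `group_b` (estimated over its
#' bounding sphere unless `density` is given), averaged over frames.
#' Self-pairs (identical atom indices) are excluded. For strongly
#' inhomogeneous systems such as a vesicle the large-r limit is only
#' approximately 1.
#'
#' @param trajectory a `trajectory`.
#' @param map a `molecule_map` (unused beyond validation; groups are atom
#'   indices).
#' @param group_a,group_b integer atom index vectors (e.g. from
#'   [select_atoms()]).
#' @param r_max histogram range (Angstrom).
#' @param bin_width bin width (Angstrom); `0 < bin_width < r_max`.
#' @param density optional reference number density of `group_b`
#'   (atoms/A^3) overriding the bounding-sphere estimate.
#' @param frames integer frame indices (default all).
#' @return tibble of class `rdf_curve`: `r` (bin centre, Angstrom), `g`,
#'   `count` (raw pairs per bin, summed over frames).
#' @export
rdf <- function(trajectory, map, group_a, group_b, r_max, bin_width,
                density = NULL, frames = NULL) {
  if (!(r_max > bin_width && bin_width > 0)) {
    abort("need r_max > bin_width > 0", class = "vesitraj_config_error")
  }
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty", class = "vesitraj_selection_error")
  }
  frames <- frames %||% seq_len(n_frames(trajectory))
  breaks <- seq(0, r_max, by = bin_width)
  if (max(breaks) < r_max) breaks <- c(breaks, max(breaks) + bin_width)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  n_self <- length(intersect(group_a, group_b))
  for (f in frames) {
    co <- frame_coords(trajectory, f)
    a <- co[group_a, , drop = FALSE]
    b <- co[group_b, , drop = FALSE]
    d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
      matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
      2 * tcrossprod(a, b)
    d <- sqrt(pmax(d2, 0))
    if (n_self > 0) {
      same <- outer(group_a, group_b, "==")
      d <- d[!same]
    }
    d <- d[d < max(breaks) & d > 0]
    if (length(d) > 0) {
      h <- findInterval(d, breaks, rightmost.closed = TRUE)
      tab <- tabulate(h, nbins = nb)
      counts <- counts + tab
    }
  }
  if (is.null(density)) {
    co1 <- frame_coords(trajectory, frames[1])[group_b, , drop = FALSE]
    ctr <- colMeans(co1)
    r_b <- max(row_norms(sweep(co1, 2, ctr)))
    density <- length(group_b) / (4 / 3 * pi * r_b^3)
  }
  shell_vol <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  norm <- length(frames) * length(group_a) * density * shell_vol
  structure(
    tibble::tibble(
      r = (breaks[-1] + breaks[-length(breaks)]) / 2,
      g = counts / norm,
      count = counts
    ),
    class = c("rdf_curve", "tbl_df", "tbl", "data.frame")
  )
}
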