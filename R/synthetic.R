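# Synthetic vesicle trajectories with known ground truth. Every analyzer in
# the package is testable by parameter recovery against the values planted
# here: shell radii and leaflet membership, diffusion coefficient and
# anomalous exponent, flip-flop events, gel/fluid chain conformations, and
# helix tilt. Monomers are rigid bodies during dynamics; only their centers
# diffuse, which isolates the correctness of each estimator.

BOND_CC <- 1.54          # A, C-C bond
ANGLE_CCC <- 111         # degrees
AXIAL_RISE <- BOND_CC * cos((180 - ANGLE_CCC) / 2 * pi / 180)  # per-bond axial
ZIGZAG_HALF <- BOND_CC * sin((180 - ANGLE_CCC) / 2 * pi / 180) # zigzag offset
N_TAIL_C <- 10
MIN_HEAD_SPACING <- 4.5  # A, headgroup diameter scale

#' Specify a synthetic vesicle
#'
#' Defines a two-leaflet spherical vesicle of single-chain ten-carbon
#' amphiphiles: headgroup (O1/O2 midpoint) shells at `r_inner` and `r_outer`,
#' outer-leaflet tails pointing inward and inner-leaflet tails outward so the
#' chains meet at the midplane, plus optional interior water beads.
#'
#' @param r_inner,r_outer headgroup shell radii in nm; `0 < r_inner < r_outer`.
#' @param n_inner,n_outer monomer counts per leaflet (both positive).
#' @param tail_state `"gel"` (all-trans chains, every C-C-C-C dihedral 180
#'   degrees) or `"fluid"` (dihedrals drawn uniformly from -60/60/180
#'   degrees), or a per-monomer character vector of length
#'   `n_inner + n_outer` (inner leaflet first).
#' @param water_fill number of interior water beads (single O atoms).
#' @param jitter_sigma Gaussian jitter (nm) applied to each headgroup's
#'   radial placement; a matching tangential jitter is applied with rejection
#'   at the 0.45 nm minimum headgroup spacing.
#' @param seed RNG seed; the same seed gives bit-identical output.
#' @return a list of class `vesicle_spec`.
#' @export
vesicle_spec <- function(r_inner, r_outer, n_inner, n_outer,
                         tail_state = "gel", water_fill = 0,
                         jitter_sigma = 0.05, seed = 1L) {
  if (!(r_inner > 0 && r_outer > r_inner)) {
    abort("need 0 < r_inner < r_outer (nm)", class = "vesitraj_spec_error")
  }
  if (n_inner <= 0 || n_outer <= 0) {
    abort("both leaflets need at least one monomer (a single leaflet is not a vesicle)",
      class = "vesitraj_packing_error")
  }
  n_mono <- n_inner + n_outer
  if (length(tail_state) == 1) tail_state <- rep(tail_state, n_mono)
  if (length(tail_state) != n_mono || !all(tail_state %in% c("gel", "fluid"))) {
    abort("tail_state must be 'gel', 'fluid', or one of these per monomer",
      class = "vesitraj_spec_error")
  }
  structure(
    list(
      r_inner = r_inner, r_outer = r_outer,
      n_inner = as.integer(n_inner), n_outer = as.integer(n_outer),
      tail_state = tail_state, water_fill = as.integer(water_fill),
      jitter_sigma = jitter_sigma, seed = as.integer(seed)
    ),
    class = "vesicle_spec"
  )
}

#' Named vesicle presets
#'
#' `"DA-25"` is the reference composition: 1000 ten-carbon amphiphiles with
#' 21% in the inner leaflet (210/790), headgroup shells at 2.0 and 3.5 nm
#' (outer radius 3.5 nm, i.e. a 7 nm vesicle with 1.5 nm bilayer thickness),
#' gel tails, 500 interior water beads.
#'
#' @param name preset name.
#' @param seed RNG seed forwarded to [vesicle_spec()].
#' @return a `vesicle_spec`.
#' @export
vesicle_preset <- function(name = "DA-25", seed = 1L) {
  switch(name,
    "DA-25" = vesicle_spec(
      r_inner = 2.0, r_outer = 3.5, n_inner = 210, n_outer = 790,
      tail_state = "gel", water_fill = 500, seed = seed
    ),
    abort(sprintf("unknown preset: %s", name), class = "vesitraj_spec_error")
  )
}

# ---- monomer templates -----------------------------------------------------

# All-trans carbon backbone in a local frame: C1 at origin, chain axis +z.
# C_{k+1} - C_{k-1} is exactly axial, so chains aligned with the membrane
# normal give S = -0.5 at every interior carbon by construction.
gel_backbone <- function() {
  k <- seq_len(N_TAIL_C)
  cbind(
    x = ifelse(k %% 2 == 0, ZIGZAG_HALF, 0),
    y = 0,
    z = (k - 1) * AXIAL_RISE
  )
}

# Next-atom placement from three predecessors plus bond/angle/dihedral.
nerf_place <- function(A, B, C, r, theta_deg, phi_deg) {
  theta <- rad(theta_deg)
  phi <- rad(phi_deg)
  bc <- unit_vec(C - B)
  nv <- unit_vec(cross3(B - A, bc))
  mv <- cross3(nv, bc)
  C + (-r * cos(theta)) * bc + (r * sin(theta) * cos(phi)) * mv +
    (r * sin(theta) * sin(phi)) * nv
}

# Random-dihedral backbone (fluid state); dihedrals uniform on {-60, 60, 180}.
fluid_backbone <- function() {
  xyz <- matrix(0, N_TAIL_C, 3)
  g <- gel_backbone()
  xyz[1:3, ] <- g[1:3, ]
  dihedrals <- sample(c(-60, 60, 180), N_TAIL_C - 3, replace = TRUE)
  for (k in 4:N_TAIL_C) {
    xyz[k, ] <- nerf_place(xyz[k - 3, ], xyz[k - 2, ], xyz[k - 1, ],
      BOND_CC, ANGLE_CCC, dihedrals[k - 3])
  }
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

# Full 12-atom monomer (C1, O1, O2, C2..C10) in a local frame with the
# headgroup midpoint at the origin and the chain running along +z. The
# carboxyl oxygens sit symmetrically about the axis so their midpoint is the
# planted headgroup position exactly.
monomer_template <- function(state = "gel", azimuth = 0) {
  backbone <- if (state == "gel") gel_backbone() else fluid_backbone()
  if (state == "fluid") {
    axis <- backbone[N_TAIL_C, ] - backbone[1, ]
    R <- rotation_align(axis, c(0, 0, 1))
    backbone <- sweep(backbone, 2, backbone[1, ]) %*% t(R)
  }
  c1 <- backbone[1, ]
  o1 <- c1 + c(1.06, 0, -0.66)
  o2 <- c1 + c(-1.06, 0, -0.66)
  xyz <- rbind(c1, o1, o2, backbone[-1, , drop = FALSE])
  head_mid <- (o1 + o2) / 2
  xyz <- sweep(xyz, 2, head_mid)
  ca <- cos(azimuth); sa <- sin(azimuth)
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  xyz <- xyz %*% t(Rz)
  rownames(xyz) <- NULL
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

MONOMER_ELEMENTS <- c("C", "O", "O", rep("C", N_TAIL_C - 1))
MONOMER_ROLES <- c("tail", "o1", "o2", rep("tail", N_TAIL_C - 1))
MONOMER_ROLE_INDEX <- c(1L, NA_integer_, NA_integer_, seq(2L, N_TAIL_C))

# ---- vesicle assembly ------------------------------------------------------

shell_capacity <- function(r_ang) {
  floor(0.9069 * 4 * pi * r_ang^2 / (pi * (MIN_HEAD_SPACING / 2)^2))
}

place_shell <- function(n, r_ang, jitter_ang) {
  pts <- fibonacci_sphere(n) * r_ang
  if (jitter_ang > 0) {
    rad_j <- rnorm(n, 0, jitter_ang)
    tang <- matrix(rnorm(2 * n, 0, jitter_ang), n, 2)
    jittered <- pts
    for (i in seq_len(n)) {
      u <- pts[i, ] / r_ang
      e1 <- perp_vec(u)
      e2 <- cross3(u, e1)
      jittered[i, ] <- (r_ang + rad_j[i]) * u + tang[i, 1] * e1 + tang[i, 2] * e2
    }
    if (n > 1) {
      dm <- as.matrix(stats::dist(jittered))
      diag(dm) <- Inf
      too_close <- apply(dm, 1, min) < MIN_HEAD_SPACING
      jittered[too_close, ] <- pts[too_close, ]
    }
    pts <- jittered
  }
  pts
}

#' Build an assembled synthetic vesicle
#'
#' Places headgroups on the two shell radii using a golden-spiral lattice
#' plus Gaussian jitter (rejected below 0.45 nm spacing), hangs gel or fluid
#' ten-carbon chains off them pointing toward the bilayer midplane, and fills
#' the interior with water beads. Returns the single-frame trajectory, the
#' molecule map and a ground-truth record of everything planted.
#'
#' @param spec a [vesicle_spec()].
#' @return a list of class `vesicle_system` with elements `trajectory`,
#'   `map`, and `truth` (class `vesicle_truth`).
#' @export
make_vesicle <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  set.seed(spec$seed)
  r_in <- nm_to_ang(spec$r_inner)
  r_out <- nm_to_ang(spec$r_outer)
  if (spec$n_inner > shell_capacity(r_in)) {
    abort(sprintf("inner shell can hold at most %d monomers at %.2f nm spacing",
      shell_capacity(r_in), ang_to_nm(MIN_HEAD_SPACING)), class = "vesitraj_packing_error")
  }
  if (spec$n_outer > shell_capacity(r_out)) {
    abort(sprintf("outer shell can hold at most %d monomers at %.2f nm spacing",
      shell_capacity(r_out), ang_to_nm(MIN_HEAD_SPACING)), class = "vesitraj_packing_error")
  }
  jit <- nm_to_ang(spec$jitter_sigma)
  heads_in <- place_shell(spec$n_inner, r_in, jit)
  heads_out <- place_shell(spec$n_outer, r_out, jit)
  n_mono <- spec$n_inner + spec$n_outer

  heads <- rbind(heads_in, heads_out)
  leaflet <- c(rep("inner", spec$n_inner), rep("outer", spec$n_outer))
  # tails outward for the inner leaflet, inward for the outer leaflet
  dirs <- heads / row_norms(heads)
  dirs[leaflet == "outer", ] <- -dirs[leaflet == "outer", ]

  azimuths <- runif(n_mono, 0, 2 * pi)
  coords <- matrix(NA_real_, n_mono * length(MONOMER_ELEMENTS), 3)
  for (i in seq_len(n_mono)) {
    tpl <- monomer_template(spec$tail_state[i], azimuths[i])
    R <- rotation_align(c(0, 0, 1), dirs[i, ])
    rows <- (i - 1) * length(MONOMER_ELEMENTS) + seq_along(MONOMER_ELEMENTS)
    coords[rows, ] <- sweep(tpl %*% t(R), 2, heads[i, ], "+")
  }
  elements <- rep(MONOMER_ELEMENTS, n_mono)
  atoms <- tibble::tibble(
    atom = seq_len(nrow(coords)),
    molecule_id = rep(seq_len(n_mono), each = length(MONOMER_ELEMENTS)),
    species = "amphiphile",
    role = rep(MONOMER_ROLES, n_mono),
    role_index = rep(MONOMER_ROLE_INDEX, n_mono),
    element = elements
  )
  if (spec$water_fill > 0) {
    r_w <- max(r_in - 3, 1)
    rr <- r_w * runif(spec$water_fill)^(1 / 3)
    zz <- runif(spec$water_fill, -1, 1)
    pp <- runif(spec$water_fill, 0, 2 * pi)
    s <- sqrt(1 - zz^2)
    wat <- cbind(rr * s * cos(pp), rr * s * sin(pp), rr * zz)
    coords <- rbind(coords, wat)
    elements <- c(elements, rep("O", spec$water_fill))
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      atom = max(atoms$atom) + seq_len(spec$water_fill),
      molecule_id = n_mono + seq_len(spec$water_fill),
      species = "water", role = "other", role_index = NA_integer_, element = "O"
    ))
  }
  colnames(coords) <- c("x", "y", "z")
  traj <- new_trajectory(list(list(coords = coords, box = NULL)),
    timestep = 0.01, elements = elements)
  map <- new_molecule_map(atoms)
  truth <- structure(
    list(
      center = c(0, 0, 0),
      r_inner_nm = spec$r_inner, r_outer_nm = spec$r_outer,
      thickness_nm = spec$r_outer - spec$r_inner,
      radius_nm = spec$r_outer,
      n_inner = spec$n_inner, n_outer = spec$n_outer,
      inner_fraction_pct = 100 * spec$n_inner / n_mono,
      leaflets = tibble::tibble(
        molecule_id = seq_len(n_mono), leaflet = leaflet
      ),
      tail_state = spec$tail_state,
      monomer_dirs = dirs,
      monomer_radius = row_norms(heads),
      shell_radius = ifelse(leaflet == "inner", r_in, r_out),
      seed = spec$seed
    ),
    class = "vesicle_truth"
  )
  structure(list(trajectory = traj, map = map, truth = truth),
    class = "vesicle_system")
}

#' @export
print.vesicle_system <- function(x, ...) {
  cat(sprintf(
    "<vesicle_system> %d monomers (%d inner / %d outer), %d frame(s), %d atoms\n",
    x$truth$n_inner + x$truth$n_outer, x$truth$n_inner, x$truth$n_outer,
    n_frames(x$trajectory), x$trajectory$atom_count
  ))
  invisible(x)
}

# ---- dynamics --------------------------------------------------------------

#' Specify synthetic monomer motion
#'
#' @param d_true planted diffusion coefficient (nm^2/ns, 3D convention
#'   `MSD = 6 D t^alpha`).
#' @param alpha anomalous exponent; 1 is Brownian. Values other than 1 are
#'   generated as exact fractional Gaussian noise so the time-origin-averaged
#'   MSD follows the planted power law.
#' @param n_frames number of frames to generate (the assembled state is
#'   frame 1).
#' @param timestep ns between frames.
#' @param flip_events optional tibble/data.frame with columns `molecule_id`,
#'   `frame` (transit start) and optionally `direction`; each listed monomer
#'   migrates to the opposite shell across `transit_window` frames.
#' @param transit_window frames taken by a flip transit (monotone radial
#'   interpolation; orientation reverses at the transit midpoint).
#' @param seed RNG seed.
#' @return a list of class `motion_spec`.
#' @export
motion_spec <- function(d_true, alpha = 1, n_frames = 100, timestep = 0.01,
                        flip_events = NULL, transit_window = 10, seed = 1L) {
  if (d_true < 0) abort("d_true must be >= 0", class = "vesitraj_spec_error")
  if (alpha <= 0) abort("alpha must be > 0", class = "vesitraj_spec_error")
  if (n_frames < 2) abort("need at least 2 frames", class = "vesitraj_spec_error")
  if (!is.null(flip_events)) {
    flip_events <- tibble::as_tibble(flip_events)
    if (!all(c("molecule_id", "frame") %in% names(flip_events))) {
      abort("flip_events needs columns molecule_id and frame", class = "vesitraj_spec_error")
    }
    if (any(flip_events$frame < 2 | flip_events$frame + transit_window > n_frames)) {
      abort("flip frames (plus transit window) must fall inside the trajectory",
        class = "vesitraj_spec_error")
    }
  }
  structure(
    list(
      d_true = d_true, alpha = alpha, n_frames = as.integer(n_frames),
      timestep = timestep, flip_events = flip_events,
      transit_window = as.integer(transit_window), seed = as.integer(seed)
    ),
    class = "motion_spec"
  )
}

# n_steps x n_series matrix of increments whose cumulative sums follow
# fractional Brownian motion with Var(B(k)) = g(k) = sigma2 * k^alpha.
fgn_increments <- function(n_steps, n_series, sigma2, alpha) {
  if (abs(alpha - 1) < 1e-12) {
    return(matrix(rnorm(n_steps * n_series, 0, sqrt(sigma2)), n_steps, n_series))
  }
  g <- function(k) sigma2 * abs(k)^alpha
  lag <- abs(outer(seq_len(n_steps), seq_len(n_steps), "-"))
  C <- 0.5 * (g(lag + 1) - 2 * g(lag) + g(lag - 1))
  L <- t(chol(C))
  L %*% matrix(rnorm(n_steps * n_series), n_steps, n_series)
}

#' Generate a dynamic trajectory from an assembled vesicle
#'
#' Each amphiphile moves as a rigid body: its center performs (fractional)
#' Brownian displacement with per-axis increments scaled so that the
#' three-dimensional MSD is `6 d_true t^alpha`. Planted flip events migrate
#' a monomer's radial placement from its shell to the opposite shell across
#' the transit window, reversing its orientation at the midpoint; all other
#' monomers stay leaflet-stable. Water (and any peptide) is static.
#'
#' @param vesicle a `vesicle_system` from [make_vesicle()].
#' @param motion a [motion_spec()].
#' @return a `vesicle_system` whose trajectory has `motion$n_frames` frames
#'   and whose truth records `d_true`, `alpha` and the planted flips.
#' @export
make_dynamic_trajectory <- function(vesicle, motion) {
  stopifnot(inherits(vesicle, "vesicle_system"), inherits(motion, "motion_spec"))
  set.seed(motion$seed)
  truth <- vesicle$truth
  n_mono <- truth$n_inner + truth$n_outer
  flips <- motion$flip_events
  if (!is.null(flips) && !all(flips$molecule_id %in% seq_len(n_mono))) {
    abort("flip event references an unknown molecule", class = "vesitraj_spec_error")
  }
  n_steps <- motion$n_frames - 1L
  # per-axis increment scale: 3D MSD = 6 D t^alpha (nm^2) -> per axis 2 D t^alpha
  sigma2 <- 2 * motion$d_true * motion$timestep^motion$alpha * 100  # A^2 at lag 1
  disp <- array(0, dim = c(motion$n_frames, n_mono, 3))
  if (motion$d_true > 0) {
    for (ax in 1:3) {
      inc <- fgn_increments(n_steps, n_mono, sigma2, motion$alpha)
      disp[2:motion$n_frames, , ax] <- apply(inc, 2, cumsum)
    }
  }

  base <- frame_coords(vesicle$trajectory, 1)
  mono_atoms <- length(MONOMER_ELEMENTS)
  amph_rows <- seq_len(n_mono * mono_atoms)
  mol_of_row <- rep(seq_len(n_mono), each = mono_atoms)

  # per-frame radial offset and orientation for flipping monomers
  flip_ids <- integer(0)
  if (!is.null(flips) && nrow(flips) > 0) flip_ids <- flips$molecule_id
  base_rel <- list()  # head-centred base coords per flipping monomer
  for (id in flip_ids) {
    rows <- (id - 1) * mono_atoms + seq_len(mono_atoms)
    head0 <- truth$monomer_radius[id] * abs_dir(truth, id)
    base_rel[[as.character(id)]] <- sweep(base[rows, , drop = FALSE], 2, head0)
  }

  frames <- vector("list", motion$n_frames)
  w <- motion$transit_window
  label_change_frame <- integer(0)
  directions <- character(0)
  start_leaflet <- truth$leaflets$leaflet
  for (t in seq_len(motion$n_frames)) {
    co <- base
    co[amph_rows, ] <- base[amph_rows, ] + disp[t, mol_of_row, ]
    for (j in seq_along(flip_ids)) {
      id <- flip_ids[j]
      f0 <- flips$frame[j]
      rows <- (id - 1) * mono_atoms + seq_len(mono_atoms)
      r_from <- truth$shell_radius[id]
      r_to <- if (start_leaflet[id] == "inner") {
        nm_to_ang(truth$r_outer_nm)
      } else {
        nm_to_ang(truth$r_inner_nm)
      }
      frac <- if (t < f0) 0 else if (t >= f0 + w) 1 else (t - f0) / w
      r_t <- r_from + frac * (r_to - r_from)
      flipped <- frac >= 0.5
      u <- abs_dir(truth, id)
      rel <- base_rel[[as.character(id)]]
      if (flipped) {
        Rf <- rotation_align(truth$monomer_dirs[id, ], -truth$monomer_dirs[id, ])
        rel <- rel %*% t(Rf)
      }
      co[rows, ] <- sweep(rel, 2, r_t * u + disp[t, id, ], "+")
    }
    frames[[t]] <- list(coords = co, box = NULL)
  }
  if (length(flip_ids) > 0) {
    label_change_frame <- flips$frame + floor(w / 2)
    directions <- ifelse(start_leaflet[flip_ids] == "inner",
      "inner_to_outer", "outer_to_inner")
  }
  truth$d_true <- motion$d_true
  truth$alpha <- motion$alpha
  truth$timestep <- motion$timestep
  truth$flips <- if (length(flip_ids) > 0) {
    tibble::tibble(
      molecule_id = flip_ids,
      transit_start = flips$frame,
      label_change_frame = label_change_frame,
      direction = directions
    )
  } else {
    tibble::tibble(
      molecule_id = integer(0), transit_start = integer(0),
      label_change_frame = integer(0), direction = character(0)
    )
  }
  traj <- new_trajectory(frames, motion$timestep, vesicle$trajectory$elements)
  structure(list(trajectory = traj, map = vesicle$map, truth = truth),
    class = "vesicle_system")
}

# outward radial unit vector of monomer id (independent of leaflet)
abs_dir <- function(truth, id) {
  u <- truth$monomer_dirs[id, ]
  if (truth$leaflets$leaflet[id] == "outer") u <- -u
  u
}

# ---- peptide ---------------------------------------------------------------

#' Specify an embedded helix
#'
#' @param n_residues number of residues (C-alpha trace only).
#' @param planted_tilt angle in degrees between the Calpha(1) -> Calpha(n)
#'   end-to-end vector and the local outward radial normal, in `[0, 180]`.
#' @param insertion_depth radial offset (nm) of the helix midpoint from the
#'   bilayer midplane (positive = outward).
#' @param seed RNG seed (placement site on the vesicle).
#' @return a list of class `peptide_spec`.
#' @export
peptide_spec <- function(n_residues = 16, planted_tilt = 0,
                         insertion_depth = 0, seed = 1L) {
  if (planted_tilt < 0 || planted_tilt > 180) {
    abort("planted_tilt must be in [0, 180] degrees", class = "vesitraj_spec_error")
  }
  if (n_residues < 2) abort("need at least 2 residues", class = "vesitraj_spec_error")
  structure(
    list(n_residues = as.integer(n_residues), planted_tilt = planted_tilt,
         insertion_depth = insertion_depth, seed = as.integer(seed)),
    class = "peptide_spec"
  )
}

# Ideal alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A/residue,
# 100 degrees/residue.
helix_trace <- function(n) {
  k <- seq_len(n) - 1
  th <- rad(100) * k
  cbind(x = 2.3 * cos(th), y = 2.3 * sin(th), z = 1.5 * k)
}

#' Embed a helix in a synthetic vesicle
#'
#' Appends an ideal alpha-helix C-alpha trace whose end-to-end
#' Calpha(first) -> Calpha(last) vector makes exactly `planted_tilt` degrees
#' with the outward radial normal at the helix midpoint. The helix is static
#' across frames.
#'
#' @param vesicle a `vesicle_system` (single- or multi-frame).
#' @param spec a [peptide_spec()].
#' @return the updated `vesicle_system`; `truth$peptide` records the planted
#'   tilt and placement.
#' @export
make_peptide <- function(vesicle, spec) {
  stopifnot(inherits(vesicle, "vesicle_system"), inherits(spec, "peptide_spec"))
  set.seed(spec$seed)
  truth <- vesicle$truth
  # random placement site on the sphere
  u <- unit_vec(rnorm(3))
  r_mid <- nm_to_ang((truth$r_inner_nm + truth$r_outer_nm) / 2) +
    nm_to_ang(spec$insertion_depth)
  thickness_ang <- nm_to_ang(truth$thickness_nm)
  helix_len <- 1.5 * (spec$n_residues - 1)
  if (spec$planted_tilt %in% c(0, 180) && spec$insertion_depth == 0 &&
      helix_len > thickness_ang) {
    warn(sprintf(
      "helix span %.1f A exceeds the %.1f A bilayer region at tilt %g",
      helix_len, thickness_ang, spec$planted_tilt
    ))
  }
  trace <- helix_trace(spec$n_residues)
  e2e <- trace[spec$n_residues, ] - trace[1, ]
  p <- perp_vec(u)
  target <- cos(rad(spec$planted_tilt)) * u + sin(rad(spec$planted_tilt)) * p
  R <- rotation_align(e2e, target)
  mid <- (trace[1, ] + trace[spec$n_residues, ]) / 2
  trace <- sweep(sweep(trace, 2, mid) %*% t(R), 2, r_mid * u, "+")

  old_n <- vesicle$trajectory$atom_count
  frames <- lapply(vesicle$trajectory$frames, function(fr) {
    list(coords = rbind(fr$coords, trace), box = fr$box)
  })
  elements <- c(vesicle$trajectory$elements, rep("C", spec$n_residues))
  traj <- new_trajectory(frames, vesicle$trajectory$timestep, elements)
  atoms <- dplyr::bind_rows(vesicle$map$atoms, tibble::tibble(
    atom = old_n + seq_len(spec$n_residues),
    molecule_id = max(vesicle$map$atoms$molecule_id) + 1L,
    species = "peptide", role = "calpha",
    role_index = seq_len(spec$n_residues), element = "C"
  ))
  truth$peptide <- list(
    planted_tilt = spec$planted_tilt, n_residues = spec$n_residues,
    site_normal = u, midpoint_radius = r_mid
  )
  structure(
    list(trajectory = traj, map = new_molecule_map(atoms), truth = truth),
    class = "vesicle_system"
  )
}

# ---- ground-truth sidecar --------------------------------------------------

#' Write / read the ground-truth sidecar
#'
#' Every synthetic fixture can be persisted with a structured YAML sidecar
#' recording what was planted (per-monomer leaflet labels, shell radii,
#' diffusion coefficient, anomalous exponent, flip events, peptide tilt) so
#' recovery tests compare analyzer output to the sidecar, never to
#' hard-coded constants.
#'
#' @param truth a `vesicle_truth` object.
#' @param path output YAML path.
#' @return `path` invisibly (write) or a `vesicle_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "vesicle_truth"))
  ser <- list(
    r_inner_nm = truth$r_inner_nm, r_outer_nm = truth$r_outer_nm,
    thickness_nm = truth$thickness_nm, radius_nm = truth$radius_nm,
    n_inner = truth$n_inner, n_outer = truth$n_outer,
    inner_fraction_pct = truth$inner_fraction_pct,
    leaflet = truth$leaflets$leaflet,
    tail_state = truth$tail_state,
    seed = truth$seed,
    d_true = truth$d_true, alpha = truth$alpha, timestep = truth$timestep,
    flips = if (!is.null(truth$flips)) lapply(seq_len(nrow(truth$flips)), function(i)
      as.list(truth$flips[i, ])),
    peptide = truth$peptide[c("planted_tilt", "n_residues")]
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- yaml::read_yaml(path)
  truth <- list(
    r_inner_nm = raw$r_inner_nm, r_outer_nm = raw$r_outer_nm,
    thickness_nm = raw$thickness_nm, radius_nm = raw$radius_nm,
    n_inner = raw$n_inner, n_outer = raw$n_outer,
    inner_fraction_pct = raw$inner_fraction_pct,
    leaflets = tibble::tibble(
      molecule_id = seq_along(raw$leaflet), leaflet = unlist(raw$leaflet)
    ),
    tail_state = unlist(raw$tail_state),
    seed = raw$seed, d_true = raw$d_true, alpha = raw$alpha,
    timestep = raw$timestep,
    flips = if (!is.null(raw$flips)) dplyr::bind_rows(lapply(raw$flips, tibble::as_tibble)),
    peptide = raw$peptide
  )
  structure(truth, class = "vesicle_truth")
}
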