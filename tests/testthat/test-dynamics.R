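make_path_traj <- function(pos) {
  # pos: F x n x 3 array of single-atom molecules
  frames <- lapply(seq_len(dim(pos)[1]), function(f) {
    list(coords = matrix(pos[f, , ], dim(pos)[2], 3))
  })
  traj <- new_trajectory(frames, 0.01, elements = rep("C", dim(pos)[2]))
  list(traj = traj, map = toy_map(dim(pos)[2], apm = 1))
}

test_that("stationary particles give zero MSD and ballistic motion the closed form", {
  pos <- array(5, dim = c(10, 3, 3))
  fx <- make_path_traj(pos)
  mc <- msd(fx$traj, fx$map)
  expect_equal(mc$msd_nm2, rep(0, 10))
  expect_equal(mc$lag_ns, (0:9) * 0.01)
  expect_true(all(diff(mc$n_pairs) < 0))

  v <- 7  # A per frame along x
  pos2 <- array(0, dim = c(20, 1, 3))
  pos2[, 1, 1] <- v * (0:19)
  fx2 <- make_path_traj(pos2)
  mc2 <- msd(fx2$traj, fx2$map)
  lag_frames <- 0:19
  expect_equal(mc2$msd_nm2, (v * lag_frames)^2 / 100, tolerance = 1e-10)
})

test_that("fast MSD equals the all-origins brute-force oracle", {
  set.seed(50)
  for (rep in 1:3) {
    F <- sample(5:100, 1)
    n <- sample(1:5, 1)
    pos <- array(rnorm(F * n * 3, sd = 3), dim = c(F, n, 3))
    fx <- make_path_traj(pos)
    mc <- msd(fx$traj, fx$map)
    expect_lt(max(abs(mc$msd_nm2 - msd_oracle(pos))), 1e-12)
  }
})

test_that("MSD is invariant under a global translation of every frame", {
  set.seed(51)
  pos <- array(rnorm(30 * 4 * 3, sd = 5), dim = c(30, 4, 3))
  fx <- make_path_traj(pos)
  shifted <- pos
  shifted[, , 1] <- shifted[, , 1] + 123.4
  shifted[, , 3] <- shifted[, , 3] - 77
  fx2 <- make_path_traj(shifted)
  expect_equal(msd(fx$traj, fx$map)$msd_nm2, msd(fx2$traj, fx2$map)$msd_nm2,
    tolerance = 1e-9)
})

test_that("exact linear MSD yields the Einstein closed form", {
  tau <- (0:100) * 0.01
  curve <- structure(
    tibble::tibble(lag_ns = tau, msd_nm2 = 6 * tau, n_pairs = 101 - (0:100)),
    class = c("msd_curve", "tbl_df", "tbl", "data.frame")
  )
  fit <- diffusion_coefficient(curve, e_dim = 3)
  expect_equal(fit$d, 1.0, tolerance = 1e-10)
  expect_equal(fit$alpha_hat, 1.0, tolerance = 1e-10)
  expect_false(fit$anomalous)
  # E scales the constant
  fit1 <- diffusion_coefficient(curve, e_dim = 1)
  expect_equal(fit1$d, 3.0, tolerance = 1e-10)
  g <- glance(fit)
  expect_equal(g$d, 1.0, tolerance = 1e-10)
  expect_equal(tidy(fit)$term, c("d", "alpha_hat"))
})

test_that("recovered D is linear in the planted coefficient", {
  ds <- c(0.25, 0.5)
  est <- vapply(ds, function(d0) {
    vals <- vapply(1:3, function(sd) {
      ves <- make_vesicle(vesicle_spec(2.0, 3.5, 20, 60, seed = sd))
      dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = d0, alpha = 1,
        n_frames = 800, timestep = 0.01, seed = sd + 100))
      fit <- diffusion_coefficient(msd(dyn$trajectory, dyn$map))
      fit$d
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(est[2] / est[1], 2, tolerance = 0.15)
})

test_that("anomalous sub-diffusion is flagged and D suppressed", {
  ves <- make_vesicle(vesicle_spec(2.0, 3.5, 20, 60, seed = 60))
  dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = 0.5, alpha = 0.5,
    n_frames = 400, timestep = 0.01, seed = 61))
  fit <- diffusion_coefficient(msd(dyn$trajectory, dyn$map))
  expect_true(fit$anomalous)
  expect_true(is.na(fit$d))
  expect_equal(fit$alpha_hat, 0.5, tolerance = 0.2)
})

test_that("degenerate fits raise typed errors and long lags truncate", {
  tau <- (0:20) * 0.01
  flat <- structure(
    tibble::tibble(lag_ns = tau, msd_nm2 = rep(0, 21), n_pairs = 21 - (0:20)),
    class = c("msd_curve", "tbl_df", "tbl", "data.frame")
  )
  expect_error(diffusion_coefficient(flat), class = "vesitraj_fit_error")
  expect_error(diffusion_coefficient(flat, fit_window = c(0.001, 0.002)),
    class = "vesitraj_fit_error")
  pos <- array(rnorm(10 * 2 * 3), dim = c(10, 2, 3))
  fx <- make_path_traj(pos)
  expect_warning(msd(fx$traj, fx$map, max_lag = 100), "truncated")
})

test_that("unwrapping restores continuous paths across the box", {
  box <- c(10, 10, 10)
  # particle crossing the +x face: wrapped x jumps from 9.5 to 0.5
  xs <- c(8.5, 9.5, 0.5, 1.5)
  frames <- lapply(xs, function(x) {
    list(coords = matrix(c(x, 5, 5), 1, 3), box = box)
  })
  traj <- new_trajectory(frames, 0.01, elements = "C")
  un <- unwrap_trajectory(traj)
  expect_equal(vapply(un$frames, function(f) f$coords[1, 1], numeric(1)),
    c(8.5, 9.5, 10.5, 11.5))
})

test_that("planted slow-transit flips are counted with ids and directions", {
  ves <- small_vesicle(seed = 70)
  flips <- data.frame(molecule_id = c(3, 17, 50, 80, 120, 199),
    frame = c(30, 60, 90, 120, 150, 180))
  dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = 0.05, alpha = 1,
    n_frames = 300, timestep = 0.01, flip_events = flips, transit_window = 10,
    seed = 71))
  lts <- leaflet_timeseries(dyn$trajectory, dyn$map)
  rep_ <- detect_flip_flops(lts, min_dwell = 20)
  expect_equal(rep_$count, 6)
  expect_setequal(rep_$events$molecule_id, flips$molecule_id)
  merged <- merge(rep_$events, dyn$truth$flips, by = "molecule_id")
  expect_equal(merged$direction.x, merged$direction.y)
})

test_that("label flicker shorter than the dwell window is ignored", {
  lab <- rep("inner", 100)
  lab[40:45] <- "unassigned"
  lab[60:70] <- "outer"  # 11 frames < min_dwell 20
  ts <- tibble::tibble(frame = 1:100, molecule_id = 1L, label = lab)
  expect_equal(detect_flip_flops(ts, min_dwell = 20)$count, 0)
  lab2 <- c(rep("inner", 30), rep("outer", 30), rep("inner", 40))
  ts2 <- tibble::tibble(frame = 1:100, molecule_id = 1L, label = lab2)
  rep2 <- detect_flip_flops(ts2, min_dwell = 20)
  expect_equal(rep2$count, 2)
  expect_equal(rep2$events$direction, c("inner_to_outer", "outer_to_inner"))
})

test_that("noisy label sequences match the independent state-machine oracle", {
  set.seed(80)
  for (rep in 1:5) {
    n <- 500
    lab <- rep(sample(c("inner", "outer"), 1), n)
    # occasional true switches plus 1% flicker noise
    if (runif(1) < 0.8) {
      at <- sample(50:400, 1)
      lab[at:n] <- setdiff(c("inner", "outer"), lab[1])
    }
    noise <- runif(n) < 0.01
    lab[noise] <- sample(c("inner", "outer", "unassigned"), sum(noise), replace = TRUE)
    ts <- tibble::tibble(frame = seq_len(n), molecule_id = 1L, label = lab)
    got <- detect_flip_flops(ts, min_dwell = 20)
    want <- flip_oracle(lab, 20)
    expect_equal(got$count, length(want))
    if (length(want) > 0) {
      expect_equal(got$events$frame_start, vapply(want, `[[`, numeric(1), "start"))
      expect_equal(got$events$direction, vapply(want, `[[`, character(1), "dir"))
    }
  }
})
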