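test_that("an isolated atom gets the exact expanded-sphere area", {
  co <- matrix(0, 1, 3)
  res <- sasa(co, elements = "C", n_points = 960)
  expect_equal(res$per_atom$area_A2, 4 * pi * 3.1^2, tolerance = 1e-4 / (4 * pi * 3.1^2))
  expect_equal(res$total_nm2, sum(res$per_atom$area_nm2))
})

test_that("non-overlapping atoms are additive and overlap buries area monotonically", {
  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  res <- sasa(far, elements = c("C", "O"), n_points = 960)
  iso <- 4 * pi * (c(1.7, 1.52) + 1.4)^2
  expect_equal(res$per_atom$area_A2, iso, tolerance = 1e-10)

  prev <- Inf
  for (d in seq(6.5, 0.5, by = -0.5)) {
    co <- rbind(c(0, 0, 0), c(d, 0, 0))
    tot <- sasa(co, elements = c("C", "C"), n_points = 960)$total_nm2
    expect_lte(tot, prev + 1e-9)
    prev <- tot
  }
})

test_that("random clusters agree with a high-resolution Monte-Carlo oracle", {
  set.seed(91)
  for (rep in 1:2) {
    co <- matrix(runif(15, -2.5, 2.5), 5, 3)
    el <- sample(c("C", "O", "N"), 5, replace = TRUE)
    res <- sasa(co, elements = el, n_points = 960)
    r_exp <- default_radius_table()$radii[el] + 1.4
    oracle <- sasa_mc_oracle(co, r_exp, n_samples = 200000, seed = 90 + rep)
    expect_equal(res$total_nm2 * 100, oracle, tolerance = 0.02)
  }
})

test_that("SASA is invariant under rigid rotation and translation", {
  set.seed(109)
  co <- matrix(rnorm(30 * 3, sd = 6), 30, 3)
  el <- rep(c("C", "O"), 15)
  base <- sasa(co, elements = el, n_points = 960)$total_nm2
  for (sd in 1:3) {
    R <- random_rotation(sd)
    co2 <- sweep(co %*% t(R), 2, c(15, -8, 3) * sd, "+")
    rot <- sasa(co2, elements = el, n_points = 960)$total_nm2
    expect_equal(rot, base, tolerance = 0.001)
  }
})

test_that("missing element radii are reported by name", {
  expect_error(sasa(matrix(0, 1, 3), elements = "Xx"),
    class = "vesitraj_config_error", regexp = "Xx")
})

test_that("order parameter helper hits its closed-form anchors", {
  expect_equal(chain_order_s(cos(54.7356 * pi / 180)), 0, tolerance = 1e-6)
  expect_equal(chain_order_s(0), -0.5)
  expect_equal(chain_order_s(1), 1)
  set.seed(93)
  iso <- chain_order_s(runif(1e5, -1, 1))
  expect_lt(abs(iso), 0.02)
})

test_that("all-trans radial chains give S = -0.5 at every interior carbon", {
  ves <- make_vesicle(vesicle_spec(2.0, 3.5, 60, 190, jitter_sigma = 0, seed = 94))
  prof <- order_parameters(ves$trajectory, ves$map, center = c(0, 0, 0))
  expect_equal(prof$carbon, 2:9)
  expect_equal(prof$s_ch, rep(-0.5, 8), tolerance = 1e-9)
  expect_true(all(prof$s_ch >= -0.5 - 1e-9 & prof$s_ch <= 1 + 1e-9))
})

test_that("gel chains are more ordered than fluid chains at every mid-chain carbon", {
  og <- order_parameters(dense_vesicle(seed = 95, "gel")$trajectory,
    dense_vesicle(seed = 95, "gel")$map)
  of <- order_parameters(dense_vesicle(seed = 95, "fluid")$trajectory,
    dense_vesicle(seed = 95, "fluid")$map)
  expect_true(all(abs(og$s_ch) > abs(of$s_ch)))
})

test_that("density maps conserve counts and detect uniform coverage", {
  ves <- small_vesicle(seed = 96)
  lab <- assign_leaflets(ves$trajectory$frames[[1]]$coords, ves$map)
  dm <- density_map(ves$trajectory, ves$map, lab, leaflet = "outer",
    n_cos = 4, n_phi = 6)
  expect_equal(sum(dm$count), sum(lab$label == "outer"))
  # near-uniform golden-spiral shell: chi-square not rejected at alpha 0.01
  p <- stats::chisq.test(dm$count)$p.value
  expect_gt(p, 0.01)
})

test_that("headgroups at one pole land in a single density cell", {
  one_mono <- function(mol, base) tibble::tibble(
    atom = (mol - 1) * 12 + 1:12, molecule_id = mol, species = "amphiphile",
    role = c("tail", "o1", "o2", rep("tail", 9)),
    role_index = c(1L, NA, NA, 2:10), element = c("C", "O", "O", rep("C", 9))
  )
  map <- new_molecule_map(dplyr::bind_rows(lapply(1:4, one_mono)))
  co <- matrix(0, 48, 3)
  # three monomers clustered at the north pole, one ballast at the south
  for (m in 1:3) co[(m - 1) * 12 + 1:12, ] <-
    matrix(rep(c(1 + m * 0.1, 0, 30), each = 12), 12, 3)
  co[37:48, ] <- matrix(rep(c(0, 0, -30), each = 12), 12, 3)
  traj <- new_trajectory(list(list(coords = co)), 0.01, rep("C", 48))
  lab <- tibble::tibble(molecule_id = 1:4,
    label = c("outer", "outer", "outer", "inner"),
    cos_orientation = 1)
  dm <- density_map(traj, map, lab, leaflet = "outer", n_cos = 4, n_phi = 4)
  expect_equal(sum(dm$count), 3)
  expect_equal(sum(dm$count > 0), 1)
})

test_that("RDF recovers a delta distance and matches the brute-force histogram", {
  co <- matrix(0, 2, 3)
  co[2, ] <- c(7.3, 0, 0)
  traj <- new_trajectory(list(list(coords = co)), 0.01, c("C", "C"))
  map <- toy_map(2, apm = 1)
  curve <- rdf(traj, map, group_a = 1L, group_b = 2L, r_max = 10, bin_width = 0.5)
  expect_equal(sum(curve$count), 1)
  expect_equal(curve$r[curve$count == 1], 7.25)

  set.seed(97)
  co10 <- matrix(runif(30, 0, 15), 10, 3)
  traj10 <- new_trajectory(list(list(coords = co10)), 0.01, rep("C", 10))
  map10 <- toy_map(10, apm = 1)
  ga <- 1:4; gb <- 3:10
  curve10 <- rdf(traj10, map10, ga, gb, r_max = 20, bin_width = 1)
  d_all <- c()
  for (i in ga) for (j in gb) {
    if (i != j) d_all <- c(d_all, sqrt(sum((co10[i, ] - co10[j, ])^2)))
  }
  oracle <- as.vector(table(cut(d_all, breaks = seq(0, 20, 1))))
  expect_equal(curve10$count, oracle)
})

test_that("an ideal-gas reference gives g(r) near 1 in fully-contained shells", {
  set.seed(98)
  R <- 30
  n <- 6000
  rr <- R * runif(n)^(1 / 3)
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  co <- cbind(rr * s * cos(phi), rr * s * sin(phi), rr * z)
  traj <- new_trajectory(list(list(coords = co)), 0.01, rep("C", n))
  map <- toy_map(n, apm = 1)
  # restrict the reference centres to the core so every shell up to r_max
  # stays inside the sampled sphere
  core <- which(sqrt(rowSums(co^2)) < R / 3)
  curve <- rdf(traj, map, group_a = core, group_b = seq_len(n),
    r_max = R / 3, bin_width = 1, density = n / (4 / 3 * pi * R^3))
  mid <- curve$r >= 3 & curve$r <= 9
  expect_true(all(abs(curve$g[mid] - 1) < 0.05))
})
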