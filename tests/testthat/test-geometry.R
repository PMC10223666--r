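test_that("cluster partition equals the brute-force contact-graph closure", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 20
    centers <- matrix(runif(n * 3, 0, 30), n, 3)
    coords <- centers[rep(seq_len(n), each = 2), ] +
      matrix(rnorm(n * 2 * 3, sd = 0.5), n * 2, 3)
    map <- toy_map(n, apm = 2)
    rep_ <- detect_aggregates(coords, map, contact_cutoff = 6)
    oracle <- cluster_oracle(coords, map, 6)
    # same partition up to relabelling
    expect_equal(length(unique(oracle)), rep_$n_clusters)
    tab <- table(rep_$members$cluster, oracle)
    expect_equal(sum(tab > 0), rep_$n_clusters)
  }
})

test_that("isolated monomers form singletons and a vesicle forms one cluster", {
  n <- 8
  coords <- matrix(0, n, 3)
  coords[, 1] <- seq(0, by = 50, length.out = n)
  rep_ <- detect_aggregates(coords, toy_map(n, apm = 1), contact_cutoff = 6)
  expect_equal(rep_$n_clusters, n)
  expect_equal(rep_$largest_size, 1)

  ves <- small_vesicle(seed = 30)
  agg <- detect_aggregates(ves$trajectory$frames[[1]]$coords, ves$map,
    contact_cutoff = 6)
  expect_equal(agg$n_clusters, 1)
  expect_equal(agg$largest_size, 250)
})

test_that("leaflet labels recover the planted membership", {
  ves <- make_vesicle(vesicle_spec(3.0, 4.5, 210, 790, seed = 31))
  lab <- assign_leaflets(ves$trajectory$frames[[1]]$coords, ves$map)
  agree <- mean(lab$label == ves$truth$leaflets$leaflet)
  expect_gte(agree, 0.99)
  inner_pct <- 100 * mean(lab$label == "inner")
  expect_equal(inner_pct, 21.0, tolerance = 0.5 / 21.0)
})

test_that("tangential monomers fall in the dead zone", {
  # one monomer whose head-to-tail vector is perpendicular to the radial
  atoms <- tibble::tibble(
    atom = 1:12, molecule_id = 1L, species = "amphiphile",
    role = c("tail", "o1", "o2", rep("tail", 9)),
    role_index = c(1L, NA, NA, 2:10), element = c("C", "O", "O", rep("C", 9))
  )
  map <- new_molecule_map(atoms)
  co <- matrix(0, 12, 3)
  co[2, ] <- c(30, 0, 1)   # o1
  co[3, ] <- c(30, 0, -1)  # o2: head midpoint (30, 0, 0)
  co[1, ] <- c(30, 0.5, 0)
  for (k in 4:12) co[k, ] <- c(30, k - 2, 0)  # tail along +y, tangential
  lab <- assign_leaflets(co, map, center = c(0, 0, 0))
  expect_equal(lab$label, "unassigned")
  expect_lt(abs(lab$cos_orientation), 0.2)
})

test_that("labels are invariant under rigid rotation and translation", {
  ves <- small_vesicle(seed = 32)
  co <- ves$trajectory$frames[[1]]$coords
  lab0 <- assign_leaflets(co, ves$map)
  R <- random_rotation(5)
  co2 <- sweep(co %*% t(R), 2, c(100, -50, 20), "+")
  lab1 <- assign_leaflets(co2, ves$map)
  expect_identical(lab0$label, lab1$label)
})

test_that("radius-of-gyration geometry recovers the planted shells", {
  exact <- make_vesicle(vesicle_spec(3.0, 4.5, 210, 790, jitter_sigma = 0, seed = 33))
  co <- exact$trajectory$frames[[1]]$coords
  lab <- assign_leaflets(co, exact$map)
  g <- vesicle_geometry(co, exact$map, lab)
  # zero jitter: headgroup midpoints sit exactly on the shells; the small
  # positive offset is the O1/O2 lever arm about the midpoint
  expect_equal(g$thickness_nm, 1.5, tolerance = 1e-3)
  expect_equal(g$radius_nm, 4.5, tolerance = 2e-3)
  expect_equal(g$inner_fraction_pct + g$outer_fraction_pct +
    g$unassigned_fraction_pct, 100)

  for (seed in 34:36) {
    ves <- make_vesicle(vesicle_spec(3.0, 4.5, 210, 790, seed = seed))
    co <- ves$trajectory$frames[[1]]$coords
    lab <- assign_leaflets(co, ves$map)
    g <- vesicle_geometry(co, ves$map, lab)
    expect_equal(g$thickness_nm, 1.5, tolerance = 0.02 / 1.5)
    expect_gt(g$thickness_nm, 0)
  }
})

test_that("radius convention is selectable and empty leaflets are errors", {
  ves <- small_vesicle(seed = 37)
  co <- ves$trajectory$frames[[1]]$coords
  lab <- assign_leaflets(co, ves$map)
  g_out <- vesicle_geometry(co, ves$map, lab, radius_convention = "outer")
  g_mid <- vesicle_geometry(co, ves$map, lab, radius_convention = "midplane")
  expect_equal(g_mid$radius_nm, (g_out$rg_inner_nm + g_out$rg_outer_nm) / 2)
  bad <- lab
  bad$label[bad$label == "inner"] <- "outer"
  expect_error(vesicle_geometry(co, ves$map, bad),
    class = "vesitraj_geometry_undefined")
})

test_that("orientation and radial assignments agree on a resting vesicle", {
  ves <- small_vesicle(seed = 38)
  co <- ves$trajectory$frames[[1]]$coords
  a <- assign_leaflets(co, ves$map)
  b <- assign_leaflets_radial(co, ves$map)
  keep <- a$label != "unassigned"
  expect_gte(mean(a$label[keep] == b$label[keep]), 0.99)
})

test_that("geometry_series returns one tidy row per frame", {
  ves <- small_vesicle(seed = 39)
  dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = 0.01, n_frames = 4, seed = 1))
  g <- geometry_series(dyn$trajectory, dyn$map)
  expect_equal(nrow(g), 4)
  expect_true(all(c("frame", "time_ns", "radius_nm", "thickness_nm") %in% names(g)))
})
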