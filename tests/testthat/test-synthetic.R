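test_that("same seed gives bit-identical generator output", {
  a <- make_vesicle(vesicle_spec(2.0, 3.5, 30, 100, seed = 11))
  b <- make_vesicle(vesicle_spec(2.0, 3.5, 30, 100, seed = 11))
  expect_identical(a$trajectory$frames[[1]]$coords, b$trajectory$frames[[1]]$coords)
  m <- motion_spec(d_true = 0.3, n_frames = 20, seed = 5)
  da <- make_dynamic_trajectory(a, m)
  db <- make_dynamic_trajectory(b, m)
  expect_identical(da$trajectory$frames[[20]]$coords, db$trajectory$frames[[20]]$coords)
  c <- make_vesicle(vesicle_spec(2.0, 3.5, 30, 100, seed = 12))
  expect_false(identical(a$trajectory$frames[[1]]$coords,
    c$trajectory$frames[[1]]$coords))
})

test_that("planted composition and geometry are recorded in ground truth", {
  ves <- make_vesicle(vesicle_spec(3.0, 4.5, 210, 790, seed = 2))
  expect_equal(ves$truth$thickness_nm, 1.5)
  expect_equal(ves$truth$inner_fraction_pct, 21.0)
  expect_equal(sum(ves$truth$leaflets$leaflet == "inner"), 210)
  da25 <- vesicle_preset("DA-25")
  expect_equal(da25$n_inner + da25$n_outer, 1000L)
  expect_equal(100 * da25$n_inner / (da25$n_inner + da25$n_outer), 21.0)
  expect_equal(da25$r_outer - da25$r_inner, 1.5)
})

test_that("degenerate and over-packed vesicle specs are rejected", {
  expect_error(vesicle_spec(3.0, 4.5, 0, 790), class = "vesitraj_packing_error")
  expect_error(vesicle_spec(4.5, 3.0, 10, 10), class = "vesitraj_spec_error")
  expect_error(make_vesicle(vesicle_spec(0.5, 3.5, 500, 100, seed = 1)),
    class = "vesitraj_packing_error")
})

test_that("headgroup midpoints sit on their shells within jitter", {
  ves <- make_vesicle(vesicle_spec(2.0, 3.5, 60, 190, jitter_sigma = 0, seed = 6))
  co <- ves$trajectory$frames[[1]]$coords
  idx <- vesitraj:::amphiphile_index(ves$map)
  heads <- (co[idx$o1, ] + co[idx$o2, ]) / 2
  r <- sqrt(rowSums(heads^2))
  inner <- ves$truth$leaflets$leaflet == "inner"
  expect_lt(max(abs(r[inner] - 20)), 1e-9)
  expect_lt(max(abs(r[!inner] - 35)), 1e-9)
})

test_that("gel tails are all-trans and fluid dihedrals come from the rotamer set", {
  dihedral <- function(p) {
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- vesitraj:::cross3(b1, b2); n2 <- vesitraj:::cross3(b2, b3)
    m1 <- vesitraj:::cross3(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  set.seed(1)
  gel <- vesitraj:::gel_backbone()
  for (k in 1:7) {
    expect_equal(abs(dihedral(gel[k:(k + 3), ])), 180, tolerance = 1e-6)
  }
  fl <- vesitraj:::fluid_backbone()
  for (k in 1:7) {
    d <- dihedral(fl[k:(k + 3), ])
    expect_true(min(abs(d - c(-60, 60, 180, -180))) < 1e-6)
  }
  # bond geometry preserved by the dihedral builder
  bonds <- sqrt(rowSums(diff(fl)^2))
  expect_equal(bonds, rep(1.54, 9), tolerance = 1e-9)
})

test_that("zero diffusion leaves every frame identical", {
  ves <- small_vesicle(seed = 7)
  dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = 0, n_frames = 5, seed = 1))
  expect_identical(dyn$trajectory$frames[[1]]$coords, dyn$trajectory$frames[[5]]$coords)
})

test_that("flip events move monomers to the opposite shell", {
  ves <- small_vesicle(seed = 8)
  flips <- data.frame(molecule_id = c(5, 100), frame = c(10, 20))
  dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = 0, n_frames = 40,
    flip_events = flips, transit_window = 10, seed = 1))
  expect_equal(nrow(dyn$truth$flips), 2)
  expect_equal(dyn$truth$flips$direction, c("inner_to_outer", "outer_to_inner"))
  co_end <- dyn$trajectory$frames[[40]]$coords
  idx <- vesitraj:::amphiphile_index(dyn$map)
  head5 <- (co_end[idx$o1[5], ] + co_end[idx$o2[5], ]) / 2
  expect_equal(sqrt(sum(head5^2)), 35, tolerance = 0.5)  # moved to outer shell
  expect_error(
    make_dynamic_trajectory(ves, motion_spec(d_true = 0, n_frames = 40,
      flip_events = data.frame(molecule_id = 9999, frame = 10), seed = 1)),
    class = "vesitraj_spec_error"
  )
})

test_that("planted helix axis makes exactly the requested angle with the site normal", {
  ves <- small_vesicle(seed = 9)
  for (tilt in c(0, 45, 90, 135, 180)) {
    vp <- suppressWarnings(make_peptide(ves, peptide_spec(16, planted_tilt = tilt, seed = 3)))
    ax <- peptide_axis(vp$trajectory$frames[[1]]$coords, vp$map)
    u <- vp$truth$peptide$site_normal
    ang <- acos(pmin(pmax(sum(ax * u), -1), 1)) * 180 / pi
    expect_equal(ang, tilt, tolerance = 1e-6)
  }
  expect_warning(
    make_peptide(ves, peptide_spec(16, planted_tilt = 0, seed = 3)),
    "exceeds"
  )
  expect_error(peptide_spec(16, planted_tilt = 190), class = "vesitraj_spec_error")
})

test_that("ground-truth sidecar round-trips through YAML", {
  ves <- small_vesicle(seed = 10)
  dyn <- make_dynamic_trajectory(ves, motion_spec(d_true = 0.2, n_frames = 30,
    flip_events = data.frame(molecule_id = 3, frame = 5), seed = 2))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(dyn$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$thickness_nm, dyn$truth$thickness_nm)
  expect_equal(back$d_true, 0.2)
  expect_equal(back$leaflets$leaflet, dyn$truth$leaflets$leaflet)
  expect_equal(back$flips$molecule_id, 3)
})
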