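# ground-truth generators: determinism, construction guarantees,
# analytic moments

test_that("protomers are reproducible, asymmetric, and validated", {
  p1 <- make_protomer(96, seed = 5)
  p2 <- make_protomer(96, seed = 5)
  expect_identical(p1$atoms, p2$atoms)        # bit-identical rebuild
  p3 <- make_protomer(96, seed = 6)
  expect_false(identical(p1$atoms, p3$atoms))
  # principal moments pairwise distinct by >= 5%
  m <- principal_axes(coords(p1))$moments
  expect_gt(m[1] / m[2], 1.05)
  expect_gt(m[2] / m[3], 1.05)
  expect_error(make_protomer(3), "n_atoms >= 4")
  # selectors used on real structures work unchanged
  expect_equal(nrow(select_atoms(p1, elety = "CB")), 24)
})

test_that("helical filament truth records round-trip bit-identically", {
  p <- default_protomer()
  h1 <- build_helical_filament(p, rise = 48, twist = 27, n = 5)
  tp <- h1$truth$params
  h2 <- build_helical_filament(p, rise = tp$rise, twist = tp$twist,
                               helical_radius = tp$helical_radius,
                               n = tp$n)
  expect_identical(h1$structure$atoms, h2$structure$atoms)
  # a dimer's inter-subunit transform equals the generator operator
  d <- build_helical_filament(p, rise = 48, twist = 27, n = 2)
  tr <- transform_between_subunits(d$structure, "A", "B")
  op <- d$truth$params$operator
  expect_lt(max(abs(tr$transform$rotation - op[, 1:3])), 1e-9)
  expect_lt(max(abs(tr$transform$translation - op[, 4])), 1e-7)
})

test_that("double filament truth reconstructs and places exact C2 axes", {
  p <- default_protomer()
  d1 <- build_double_filament(p, n = 3, rise = 9)
  d2 <- build_double_filament(p, n = 3, rise = 9)
  expect_identical(d1$structure$atoms, d2$structure$atoms)
  # recorded lateral C2 axes map the interface chains onto each other
  lat <- Filter(function(x) grepl("lateral", x$class),
                d1$truth$params$interfaces)
  expect_gt(length(lat), 0)
  for (li in lat[1:2]) {
    c2 <- detect_c2(d1$structure, li$chains)
    expect_true(c2$has_c2)
    # the detected axis direction matches the recorded one (up to sign)
    expect_equal(abs(sum(c2$axis$direction * li$c2_axis$direction)), 1,
                 tolerance = 1e-6)
  }
  # opposing protofilaments are antiparallel
  tr <- transform_between_subunits(d1$structure, "A", "a")
  expect_equal(abs(screw_decompose(tr$transform)$twist_deg), 180,
               tolerance = 1e-6)
})

test_that("arc filaments place centroids on the stated circle", {
  a <- build_arc_filament(default_protomer(), curvature_radius_nm = 16.3,
                          spacing_A = 48, n = 6)
  cent <- chain_centroids(a$structure)
  radii <- sqrt(cent[, 1]^2 + cent[, 2]^2)
  expect_equal(unname(radii), rep(163, 6), tolerance = 1e-9)
  # arc-length spacing
  d <- sqrt(rowSums(diff(cent)^2))
  chord <- 2 * 163 * sin(48 / 163 / 2)
  expect_equal(unname(d), rep(chord, 5), tolerance = 1e-9)
  expect_error(build_arc_filament(default_protomer(), 0.1, 48, 3),
               "circumference")
})

test_that("perturb is seeded, unbiased and analytically calibrated", {
  p <- make_protomer(400, seed = 2)
  expect_identical(perturb(p, 0, seed = 1)$atoms, p$atoms)
  q1 <- perturb(p, 0.5, seed = 9)
  q2 <- perturb(p, 0.5, seed = 9)
  expect_identical(q1$atoms, q2$atoms)
  # mean 3D displacement of a Gaussian with s.d. sigma per coordinate
  # is sigma * sqrt(8/pi); check over many atoms within 5%
  big <- make_protomer(4 * 2500, seed = 3)
  disp <- sqrt(rowSums((coords(perturb(big, 0.5, seed = 10)) -
                          coords(big))^2))
  expect_equal(mean(disp), 0.5 * sqrt(8 / pi), tolerance = 0.05)
})

test_that("isotherm simulation is exact at zero noise and seeded", {
  sim <- simulate_isotherm("single_site", noise_sigma = 0)
  expect_equal(sim$data$y,
               spr_response(sim$data$x, 0.8, 100, 0))
  s1 <- simulate_isotherm("two_step", noise_sigma = 0.01, seed = 4)
  s2 <- simulate_isotherm("two_step", noise_sigma = 0.01, seed = 4)
  expect_identical(s1$data, s2$data)
  # truth record serialises as structured text
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth_record(s1$truth, f)
  y <- yaml::read_yaml(f)
  expect_equal(y$params$params$Kd_Lo, 0.016)
})

test_that("full stack recovers generator parameters within 1% under noise", {
  # seeded random draws over the generator parameter space, analysed on
  # protein-sized subunits
  set.seed(81)
  draws <- replicate(8, c(twist = runif(1, 10, 60),
                          rise = runif(1, 0, 60),
                          radius = runif(1, 50, 200)))
  p <- protein_protomer()
  for (j in seq_len(ncol(draws))) {
    tw <- unname(draws["twist", j]); ri <- unname(draws["rise", j])
    ra <- unname(draws["radius", j])
    h <- build_helical_filament(p, rise = ri, twist = tw,
                                helical_radius = ra, n = 6)
    # noiseless: exact to 1e-6 relative
    hp0 <- helical_parameters_filament(h$structure,
                                       chains = LETTERS[1:6])
    expect_equal(hp0$twist_deg, tw, tolerance = 1e-6)
    expect_lt(abs(hp0$rise - ri), 1e-6 * max(ri, 1))
    expect_equal(hp0$helical_radius, ra, tolerance = 1e-6)
    # sigma = 0.2 A coordinate noise: within 1%
    st <- perturb(h$structure, 0.2, seed = 100 + j)
    hp <- helical_parameters_filament(st, chains = LETTERS[1:6])
    expect_equal(hp$twist_deg, tw, tolerance = 0.01)
    # 1% relative, with a 0.05 A numeric floor for near-zero rises
    expect_lt(abs(hp$rise - ri), max(0.01 * ri, 0.05))
    expect_equal(hp$helical_radius, ra, tolerance = 0.01 * ra)
  }
})
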