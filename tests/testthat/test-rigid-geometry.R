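# rigid transforms, superposition and screw decomposition

test_that("rigid_transform rejects improper and non-orthogonal input", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "improper")
  m <- diag(3); m[1, 2] <- 0.1
  expect_error(rigid_transform(m), "orthogonal")
  expect_silent(rigid_transform(rotation_about_axis(c(1, 1, 1), 33),
                                c(1, 2, 3)))
})

test_that("superpose recovers a known generator rotation to 1e-9", {
  set.seed(11)
  x <- matrix(rnorm(60, sd = 10), 20, 3)
  gen <- rt_from_screw(c(1, -2, 0.5), c(3, 0, 0), 63.7, 0)
  sp <- superpose(x, rt_apply(gen, x))
  expect_lt(sp$rmsd, 1e-9)
  expect_rt_equal(sp$transform, gen, tol = 1e-9)
})

test_that("superpose on identical sets gives identity and rmsd 0", {
  set.seed(12)
  x <- matrix(rnorm(30), 10, 3)
  sp <- superpose(x, x)
  expect_lt(sp$rmsd, 1e-12)
  expect_rt_equal(sp$transform, rt_identity(), tol = 1e-10)
})

test_that("superpose enforces a proper rotation on mirror images", {
  set.seed(13)
  x <- matrix(rnorm(45, sd = 5), 15, 3)
  mirror <- x %*% diag(c(-1, 1, 1))
  sp <- superpose(x, mirror)
  expect_gt(det(sp$transform$rotation), 0)
  expect_gt(sp$rmsd, 0.1)
})

test_that("superpose validates its inputs", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(superpose(x, x[1:9, ]), "mismatch")
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose RMSD is a local minimum of the rotation", {
  set.seed(14)
  x <- matrix(rnorm(60, sd = 8), 20, 3)
  y <- rt_apply(random_transform(), x) +
    matrix(rnorm(60, sd = 0.3), 20, 3)
  sp <- superpose(x, y)
  rmsd_of <- function(tr) sqrt(mean(rowSums((rt_apply(tr, x) - y)^2)))
  for (i in 1:25) {
    wob <- rotation_about_axis(rnorm(3), runif(1, 0.01, 0.5))
    tr2 <- rigid_transform(wob %*% sp$transform$rotation,
                           sp$transform$translation)
    # re-optimise translation for the perturbed rotation (best case)
    tr2$translation <- colMeans(y) - drop(tr2$rotation %*% colMeans(x))
    expect_gte(rmsd_of(tr2) + 1e-12, sp$rmsd)
  }
})

test_that("superposition RMSD agrees with an independent implementation", {
  set.seed(18)
  x <- matrix(rnorm(90, sd = 10), 30, 3)
  y <- rt_apply(random_transform(), x) + matrix(rnorm(90, sd = 0.8), 30, 3)
  ours <- superpose(x, y)$rmsd
  ref <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # ref rounds to 3 decimals
})

test_that("screw decomposition handles degenerate transforms", {
  s0 <- screw_decompose(rt_identity())
  expect_true(s0$pure_translation)
  expect_equal(s0$twist_deg, 0)
  expect_equal(s0$rise, 0)

  s1 <- screw_decompose(rigid_transform(diag(3), c(0, 0, 5)))
  expect_true(s1$pure_translation)
  expect_equal(s1$twist_deg, 0)
  expect_equal(s1$rise, 5)
  expect_equal(s1$direction, c(0, 0, 1))
})

test_that("screw decomposition locates an off-origin rotation axis", {
  t1 <- rt_from_screw(c(0, 0, 1), c(100, 0, 0), 27.6923, 0)
  s <- screw_decompose(t1)
  expect_equal(s$twist_deg, 27.6923, tolerance = 1e-9)
  expect_equal(s$rise, 0)
  # axis is the line x = 100, y = 0: point must lie on it
  expect_lt(abs(s$point[1] - 100) + abs(s$point[2]), 1e-6)
  expect_rt_equal(screw_recompose(s), t1, tol = 1e-9)
})

test_that("decompose/recompose round-trips random transforms", {
  set.seed(15)
  pts <- matrix(rnorm(30, sd = 50), 10, 3)
  for (i in 1:100) {
    t1 <- random_transform(scale = 40)
    t2 <- screw_recompose(screw_decompose(t1))
    expect_lt(max(abs(rt_apply(t1, pts) - rt_apply(t2, pts))), 1e-8)
  }
})

test_that("sign convention: rise >= 0, else twist >= 0; twist in (-180, 180]", {
  set.seed(16)
  for (i in 1:50) {
    s <- screw_decompose(random_transform())
    expect_gte(s$rise, 0)
    if (s$rise == 0) expect_gte(s$twist_deg, 0)
    expect_true(s$twist_deg > -180 && s$twist_deg <= 180)
  }
})

test_that("twist is invariant under conjugation", {
  set.seed(17)
  for (i in 1:20) {
    t1 <- random_transform()
    r <- random_transform(scale = 10)
    t2 <- rt_compose(r, rt_compose(t1, rt_inverse(r)))
    expect_equal(abs(screw_decompose(t2)$twist_deg),
                 abs(screw_decompose(t1)$twist_deg), tolerance = 1e-8)
  }
})

test_that("transform_between_subunits recovers generator screw parameters", {
  h <- build_helical_filament(default_protomer(), rise = 48,
                              twist = 27.7, helical_radius = 100, n = 3)
  tr <- transform_between_subunits(h$structure, "A", "B")
  s <- screw_decompose(tr$transform)
  expect_equal(s$twist_deg, 27.7, tolerance = 1e-6)
  expect_equal(s$rise, 48, tolerance = 1e-6)
  expect_lt(tr$rmsd, 1e-9)
})

test_that("translation-related chains give zero twist", {
  p <- default_protomer()
  a <- p$atoms
  b <- a
  b$chain <- "B"
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] +
    rep(c(0, 0, 30), each = nrow(b))
  s <- fil_structure(rbind(a, b), id = "pair")
  tr <- transform_between_subunits(s, "A", "B")
  expect_equal(screw_decompose(tr$transform)$twist_deg, 0,
               tolerance = 1e-8)
})

test_that("disjoint residue numbering is an error", {
  p <- default_protomer()
  a <- p$atoms
  b <- a
  b$chain <- "B"
  b$resno <- b$resno + 1000
  s <- fil_structure(rbind(a, b), id = "pair")
  expect_error(transform_between_subunits(s, "A", "B"), "common")
})
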