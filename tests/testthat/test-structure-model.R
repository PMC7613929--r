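# reading, writing, selecting and transforming atomic models

test_that("PDB and mmCIF round trips are coordinate-stable", {
  s <- perturb(default_protomer(), 0.5, seed = 3)  # non-grid coordinates
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(s, pdb)
  write_structure(s, cif)
  r_pdb <- read_structure(pdb)
  r_cif <- suppressWarnings(read_structure(cif))
  expect_lt(max(abs(coords(r_pdb) - coords(s))), 1e-3 + 1e-12)
  expect_lt(max(abs(coords(r_cif) - coords(s))), 1e-5 + 1e-12)
  expect_identical(chain_ids(r_pdb), chain_ids(s))
  # read-write-read is stable at format precision
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(r_pdb, pdb2)
  expect_identical(coords(read_structure(pdb2)), coords(r_pdb))
})

test_that("degenerate files raise parse errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_structure(empty), "empty file")
  expect_error(read_structure("no/such/file.pdb"), "no such file")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("hello", bad)
  expect_error(read_structure(bad), "format")
})

test_that("altlocs resolve to highest occupancy, ties lexicographically", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BALA A   2       9.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA CALA A   2       7.000   0.000   0.000  0.50 10.00           C",
    "END"), pdb)
  s <- read_structure(pdb)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(coords(s)[1, 1], 5)   # occupancy 0.6 beats 0.4
  expect_equal(coords(s)[2, 1], 9)   # tie: altloc B before C
})

test_that("hydrogens and waters are dropped on read", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00 10.00           H",
    "HETATM    3  O   HOH A 101       9.000   0.000   0.000  1.00 10.00           O",
    "END"), pdb)
  s <- read_structure(pdb)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$elety, "N")
})

test_that("select_atoms counts, orders and repeats deterministically", {
  s <- tiny_structure()
  mc <- select_atoms(s, chain = "A", elety = c("N", "CA", "C"))
  expect_equal(nrow(mc), 9)          # 3 residues x 3 atoms
  expect_equal(mc$elety[1:3], c("N", "CA", "C"))
  again <- select_atoms(s, chain = "A", elety = c("N", "CA", "C"))
  expect_identical(mc, again)
  expect_error(select_atoms(s, chain = "Z"), "no such chain")
  # glycine has no CB
  expect_warning(gly <- select_atoms(s, chain = "A", resno = 2,
                                     elety = "CB"),
                 "empty")
  expect_equal(nrow(gly), 0)
})

test_that("apply_transform preserves all pairwise distances", {
  s <- default_protomer()
  d0 <- dist(coords(s))
  set.seed(21)
  for (i in 1:10) {
    s2 <- apply_transform(s, random_transform())
    expect_lt(max(abs(dist(coords(s2)) - d0)), 1e-9 * max(d0))
  }
  # identity and pure translation behave trivially
  expect_identical(coords(apply_transform(s, rt_identity())), coords(s))
  shifted <- apply_transform(s, rigid_transform(diag(3), c(1, 0, 0)))
  expect_equal(coords(shifted)[, 1], coords(s)[, 1] + 1)
})

test_that("expand_assembly counts chains and keeps originals", {
  s <- tiny_structure()                      # chains A, B
  op <- rt_from_screw(c(0, 0, 1), twist_deg = 90)
  e1 <- expand_assembly(s, op, copies = 1)
  expect_equal(length(chain_ids(e1)), 4)
  expect_identical(
    coords(select_atoms(e1, chain = "A", warn_empty = FALSE)),
    coords(select_atoms(s, chain = "A", warn_empty = FALSE)))
  # identity op duplicates in place (RMSD 0 onto source)
  e0 <- expand_assembly(s, rt_identity(), copies = 1, chains = "A")
  new_chain <- setdiff(chain_ids(e0), chain_ids(s))
  expect_equal(
    superpose(coords(select_atoms(e0, chain = new_chain)),
              coords(select_atoms(e0, chain = "A")))$rmsd, 0,
    tolerance = 1e-12)
})

test_that("a 360/13 screw op applied 12 times closes a full turn", {
  p <- default_protomer()
  base <- apply_transform(p, rigid_transform(diag(3), c(100, 0, 0) -
                                               colMeans(coords(p))))
  op <- rt_from_screw(c(0, 0, 1), twist_deg = 360 / 13)
  ring <- expand_assembly(base, op, copies = 12, chain_ids = "letters")
  expect_equal(length(chain_ids(ring)), 13)
  cent <- chain_centroids(ring)
  az <- sort(atan2(cent[, 2], cent[, 1]) * 180 / pi)
  gaps <- diff(c(az, az[1] + 360))
  expect_equal(max(gaps), 360 / 13, tolerance = 1e-6)  # even coverage
})

test_that("PDB chain limit is enforced, mmCIF takes over", {
  s <- tiny_structure()
  ops <- list(rt_from_screw(c(0, 0, 1), twist_deg = 1))
  big <- expand_assembly(s, ops, copies = 35)   # 2 + 70 chains
  pdb <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_structure(big, pdb), "mmCIF")
  cif <- withr::local_tempfile(fileext = ".cif")
  expect_silent(write_structure(big, cif))
  r <- suppressWarnings(read_structure(cif))
  expect_equal(length(chain_ids(r)), 72)
})

test_that("operator files round-trip", {
  ops <- list(rt_from_screw(c(1, 2, 3), c(4, 5, 6), 77.7, 12.3),
              rt_identity())
  f <- withr::local_tempfile(fileext = ".txt")
  write_operators(ops, f)
  back <- read_operators(f)
  expect_length(back, 2)
  expect_rt_equal(back[[1]], ops[[1]], tol = 1e-8)
  expect_rt_equal(back[[2]], ops[[2]], tol = 1e-8)
})
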