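# shared fixtures, built in code

# memoised default protomer (24 pseudo-residues; compact and fast)
default_protomer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_protomer(96, seed = 1)
    cache
  }
})

# memoised protein-sized protomer (396 pseudo-residues, the size of an
# FtsA monomer) for noise-sensitivity checks: angular superposition
# accuracy scales with subunit size, so recovery bounds are only
# meaningful at realistic size
protein_protomer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_protomer(4 * 396, seed = 2)
    cache
  }
})

# a two-conformer structure with a known hinge rotation of the "IC"
# block (residues 17-24) about an axis through the hinge point; chain B
# additionally moved by an arbitrary rigid motion
make_hinge_pair <- function(angle_deg = 13.8, seed = 7) {
  p <- default_protomer()
  a <- p$atoms
  a$chain <- "A"
  core_res <- 1:16
  mob_res <- 17:24
  b <- a
  b$chain <- "B"
  hinge_sel <- b$resno == 16 & b$elety == "CA"
  hinge_pt <- as.numeric(b[hinge_sel, c("x", "y", "z")])
  op <- rt_from_screw(c(0.3, -0.8, 0.52), hinge_pt, angle_deg, 0)
  mob <- b$resno %in% mob_res
  b[mob, c("x", "y", "z")] <-
    rt_apply(op, as.matrix(b[mob, c("x", "y", "z")]))
  # arbitrary global motion of conformer B
  glob <- protofil:::with_seed(seed, {
    rigid_transform(protofil:::random_rotation(), stats::rnorm(3, 0, 30))
  })
  b[, c("x", "y", "z")] <- rt_apply(glob, as.matrix(b[, c("x", "y", "z")]))
  list(structure = fil_structure(rbind(a, b), id = "hinge_pair"),
       domains = domain_definition(list(CORE = c(1, 16), IC = c(17, 24))),
       angle_deg = angle_deg)
}

# random rigid transform drawn from the current RNG stream
random_transform <- function(scale = 30) {
  rigid_transform(protofil:::random_rotation(),
                  stats::rnorm(3, 0, scale))
}

# tiny three-residue poly-Ala structure with side-chain CB positions
# set explicitly; used for distance and selection tests
tiny_structure <- function(cb_offset = c(5, 0, 0)) {
  mk <- function(chain, resno, base, resid = "ALA") {
    has_cb <- resid != "GLY"
    data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = c("N", "CA", "C", if (has_cb) "CB"),
      elesy = c("N", "C", "C", if (has_cb) "C"),
      x = base[1] + c(-1.2, 0, 1.2, if (has_cb) cb_offset[1]),
      y = base[2] + c(0.5, 0, 0.5, if (has_cb) cb_offset[2]),
      z = base[3] + c(0, 0, 0, if (has_cb) cb_offset[3]),
      o = 1, alt = "", polymer = TRUE)
  }
  fil_structure(rbind(mk("A", 1, c(0, 0, 0)),
                      mk("A", 2, c(3.8, 0, 0), resid = "GLY"),
                      mk("A", 3, c(7.6, 0, 0)),
                      mk("B", 1, c(0, 8, 0)),
                      mk("B", 2, c(3.8, 8, 0)),
                      mk("B", 3, c(7.6, 8, 0))),
                id = "tiny")
}

expect_rt_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
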