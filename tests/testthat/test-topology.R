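# interface detection, classification, C2 symmetry and filament graphs

test_that("distant or single chains give empty interface lists", {
  s <- tiny_structure()
  far <- s
  bsel <- far$atoms$chain == "B"
  far$atoms$y[bsel] <- far$atoms$y[bsel] + 100
  expect_length(find_interfaces(far), 0)
  single <- fil_structure(s$atoms[s$atoms$chain == "A", ], id = "one")
  expect_warning(out <- find_interfaces(single), "fewer than two")
  expect_length(out, 0)
})

test_that("generator double filaments are recovered exactly, and under noise", {
  df <- build_double_filament(default_protomer(), n = 4, rise = 9)
  truth <- df$truth$params$interfaces
  truth_keys <- sort(vapply(truth, function(x)
    paste(x$chains, collapse = "-"), character(1)))
  classes <- vapply(truth, function(x) x$class, character(1))
  expect_setequal(unique(classes),
                  c("longitudinal", "lateral_i_istar",
                    "lateral_i_istar_minus1"))
  for (sigma in c(0, 0.2, 0.3)) {
    st <- if (sigma > 0) perturb(df$structure, sigma, seed = 31) else
      df$structure
    found <- find_interfaces(st)
    keys <- sort(vapply(found, function(x)
      paste(x$chains, collapse = "-"), character(1)))
    expect_identical(keys, truth_keys)   # precision = recall = 1
  }
})

test_that("interface detection is invariant under rigid motion and relabelling", {
  df <- build_double_filament(default_protomer(), n = 2)
  base_keys <- sort(vapply(find_interfaces(df$structure), function(x)
    paste(x$chains, collapse = "-"), character(1)))
  set.seed(32)
  moved <- apply_transform(df$structure, random_transform())
  moved_keys <- sort(vapply(find_interfaces(moved), function(x)
    paste(x$chains, collapse = "-"), character(1)))
  expect_identical(moved_keys, base_keys)
})

test_that("interface count is monotone in the contact cutoff", {
  df <- build_double_filament(default_protomer(), n = 3, rise = 9)
  st <- df$structure
  counts <- vapply(c(3.5, 4.0, 4.5, 5.5, 6.5), function(cc)
    length(find_interfaces(st, contact_cutoff = cc, min_pairs = 1)),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("parallel dimers classify longitudinal, antiparallel lateral", {
  df <- build_double_filament(default_protomer(), n = 4, rise = 9)
  st <- df$structure
  ifaces <- find_interfaces(st)
  truth <- df$truth$params$interfaces
  tkey <- vapply(truth, function(x) paste(x$chains, collapse = "-"),
                 character(1))
  for (iface in ifaces) {
    k <- match(paste(iface$chains, collapse = "-"), tkey)
    cl <- classify_interface(st, iface, longitudinal_repeat = 9,
                             axis = c(0, 0, 1))
    expected <- truth[[k]]$class
    got <- cl$label
    if (expected == "longitudinal") {
      expect_match(got, "^longitudinal")
      expect_lt(cl$relative_twist_deg, 5)
    } else {
      expect_identical(got, expected)
      expect_gt(cl$relative_twist_deg, 175)
    }
  }
})

test_that("tight vs loose longitudinal contacts follow the domain ranges", {
  df <- build_double_filament(default_protomer(), n = 2, rise = 9)
  st <- df$structure
  ifaces <- find_interfaces(st)
  long <- ifaces[[which(vapply(ifaces, function(i)
    identical(i$chains, c("A", "B")), logical(1)))]]
  # map all contacting residues into IIA/IIB (tail) and IA (face):
  # every contact then counts as tight
  doms_tight <- domain_definition(list(IA = c(1, 12), IIA = c(13, 18),
                                       IIB = c(19, 24)))
  cl <- classify_interface(st, long, domains = doms_tight,
                           tight_min_pairs = 3)
  expect_identical(cl$label, "longitudinal_tight")
  # a partition whose IIA/IIB lie away from the contact: loose
  doms_loose <- domain_definition(list(IA = c(1, 20), IIA = c(21, 22),
                                       IIB = c(23, 24)))
  cl2 <- classify_interface(st, long, domains = doms_loose,
                            tight_min_pairs = 1e6)
  expect_identical(cl2$label, "longitudinal_loose")
})

test_that("exact C2 dimers pass; axial shifts and parallel dimers fail", {
  df <- build_double_filament(default_protomer(), n = 2)
  st <- df$structure
  lat <- Filter(function(x) grepl("lateral", x$class),
                df$truth$params$interfaces)[[1]]
  c2 <- detect_c2(st, lat$chains)
  expect_true(c2$has_c2)
  expect_equal(c2$angle_dev_deg, 0, tolerance = 1e-7)
  expect_equal(c2$rise_abs, 0, tolerance = 1e-7)
  expect_equal(c2$mapping_rmsd, 0, tolerance = 1e-7)

  # translate one chain 5 A along the would-be C2 axis (x).  The
  # chain-swap map must then move one chain by +5 and the other by -5
  # along the axis, which no rigid motion can do: the violation appears
  # as mapping RMSD (the best compromise splits the shift evenly)
  ax_dir <- c(1, 0, 0)
  shifted <- st
  sel <- shifted$atoms$chain == lat$chains[2]
  shifted$atoms[sel, c("x", "y", "z")] <-
    shifted$atoms[sel, c("x", "y", "z")] +
    rep(5 * ax_dir, each = sum(sel))
  c2s <- detect_c2(shifted, lat$chains)
  expect_false(c2s$has_c2)
  expect_gt(c2s$mapping_rmsd, 2)

  # translation-related (parallel) dimer: no rigid motion swaps two
  # identically oriented asymmetric chains -> large mapping RMSD, no C2
  p <- default_protomer()
  b <- p$atoms; b$chain <- "B"
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] +
    rep(c(0, 12, 0), each = nrow(b))
  par <- fil_structure(rbind(p$atoms, b), id = "par")
  c2p <- detect_c2(par, c("A", "B"))
  expect_false(c2p$has_c2)
  expect_gt(c2p$mapping_rmsd, 2)
})

test_that("polar contacts honour the cutoff monotonically", {
  s <- tiny_structure()
  # nearest inter-chain N/N pairs sit 8 A apart in y; build a closer one
  a <- s$atoms
  a$y[a$chain == "B" & a$resno == 1 & a$elety == "N"] <- 3.2 + 0.5
  s2 <- fil_structure(a, id = "polar")
  hits35 <- polar_contacts(s2, c("A", "B"), polar_cutoff = 3.5)
  expect_true(any(abs(hits35$dist - 3.2) < 0.2))
  hits30 <- polar_contacts(s2, c("A", "B"), polar_cutoff = 3.0)
  expect_lt(nrow(hits30), nrow(hits35))
})

test_that("filament graph resolves protofilaments, components and rings", {
  # constructed 4-chain tetramer: 2 longitudinal + lateral edges
  df <- build_double_filament(default_protomer(), n = 2)
  st <- df$structure
  ifaces <- find_interfaces(st)
  classes <- lapply(ifaces, classify_interface, s = st,
                    axis = c(0, 0, 1))
  g <- build_filament_graph(ifaces, classes)
  expect_equal(nrow(g$components), 1)
  expect_equal(g$components$size, 4)
  expect_equal(g$components$n_protofilaments, 2)
  expect_true(g$components$double_filament)
  lens <- vapply(g$protofilaments, function(p) length(p$chains),
                 numeric(1))
  expect_equal(sort(lens), c(2, 2))

  # a closed ring of 13 longitudinal edges
  ring <- build_helical_filament(default_protomer(), rise = 0,
                                 twist = 360 / 13, helical_radius = 25,
                                 n = 13)
  ri <- find_interfaces(ring$structure, min_pairs = 1)
  rc <- lapply(ri, classify_interface, s = ring$structure)
  keep <- vapply(rc, function(c) grepl("longitudinal", c$label),
                 logical(1))
  gr <- build_filament_graph(ri[keep], rc[keep])
  ring_pf <- Filter(function(p) p$closed, gr$protofilaments)
  expect_length(ring_pf, 1)
  expect_equal(length(ring_pf[[1]]$chains), 13)
})
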