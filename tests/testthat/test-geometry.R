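helix6 <- function() generate_structure_fixture("ideal_helix", n_res = 6)

sidechain_xyz <- function(model, resno) {
  a <- model$atoms
  sc <- a[a$resno == resno & !(a$elety %in% c("N", "CA", "C", "O", "OXT")), ]
  m <- as.matrix(sc[order(sc$elety), c("x", "y", "z")])
  rownames(m) <- sort(sc$elety)
  m
}

test_that("mutation truncates, renames and preserves the backbone", {
  h <- helix6()
  v <- mutate_residue(h, list(resno = 3), "VAL")
  g <- mutate_residue(v, list(resno = 3), "GLY")
  expect_equal(sort(g$atoms$elety[g$atoms$resno == 3]),
               sort(c("N", "CA", "C", "O")))
  expect_equal(unique(g$atoms$resid[g$atoms$resno == 3]), "GLY")
  # Ala -> Ala is the identity
  al <- mutate_residue(v, list(resno = 3), "ALA")
  expect_equal(mutate_residue(al, list(resno = 3), "ALA"), al)
  # backbone coordinates are bit-identical before and after any mutation
  bb <- function(m) {
    a <- m$atoms[m$atoms$elety %in% c("N", "CA", "C", "O"), ]
    as.matrix(a[order(a$resno, a$elety), c("x", "y", "z")])
  }
  expect_identical(bb(v), bb(h))
  expect_identical(bb(mutate_residue(h, list(resno = 2), "SER")), bb(h))
  # missing backbone is a geometry error
  broken <- h
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 3 &
                                   broken$atoms$elety == "O"), ]
  expect_error(mutate_residue(broken, list(resno = 3), "SER"),
               "backbone")
})

test_that("Val to Thr keeps CB and the original rotameric state", {
  h <- helix6()
  v <- mutate_residue(h, list(resno = 3), "VAL")
  rows_v <- pocketpca:::residue_rows(v, list(resno = 3))
  chi_v <- pocketpca:::measure_chi1(v, rows_v)
  t <- mutate_residue(v, list(resno = 3), "THR")
  rows_t <- pocketpca:::residue_rows(t, list(resno = 3))
  chi_t <- pocketpca:::measure_chi1(t, rows_t)
  expect_lt(abs(chi_t - chi_v), 1)
  cb <- function(m) as.numeric(m$atoms[m$atoms$resno == 3 &
                                         m$atoms$elety == "CB",
                                       c("x", "y", "z")])
  expect_identical(cb(t), cb(v))
  expect_setequal(t$atoms$elety[t$atoms$resno == 3],
                  c("N", "CA", "C", "O", "CB", "OG1", "CG2"))
  # built geometry is idealized: N-CA-CB angle near tetrahedral
  a <- t$atoms
  p <- function(el) as.numeric(a[a$resno == 3 & a$elety == el,
                                 c("x", "y", "z")])
  expect_equal(pocketpca:::angle_points(p("N"), p("CA"), p("CB")), 110.4,
               tolerance = 2)
  expect_equal(sqrt(sum((p("CB") - p("OG1"))^2)), 1.433, tolerance = 0.02)
})

test_that("chi1 scans hit the requested rotamers exactly", {
  h <- helix6()
  s <- mutate_residue(h, list(resno = 3), "SER")
  states <- scan_chi1(s, list(resno = 3), c(-60, 60, 180))
  expect_length(states, 3L)
  for (i in seq_along(states)) {
    expect_lt(abs(states[[i]]$chi1 - states[[i]]$chi1_requested) %% 360, 1)
  }
  # rebuilding at the current chi1 reproduces the side chain
  rows <- pocketpca:::residue_rows(s, list(resno = 3))
  cur <- pocketpca:::measure_chi1(s, rows)
  rebuilt <- scan_chi1(s, list(resno = 3), cur)[[1]]$model
  rmsd <- sqrt(mean((sidechain_xyz(s, 3) - sidechain_xyz(rebuilt, 3))^2))
  expect_lt(rmsd, 0.05)
  # chi1 undefined for Gly
  g <- mutate_residue(h, list(resno = 3), "GLY")
  expect_error(scan_chi1(g, list(resno = 3)), "undefined")
})

test_that("hydrogen-bond detection gates on distance and antecedent angle", {
  ok <- generate_structure_fixture("hbond_pair", distance = 2.9, angle = 150)
  hb <- find_hbonds(ok, list(resno = 1, elety = "N"),
                    list(resno = 10, elety = "O"))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 150, tolerance = 1e-6)
  # too far
  far <- generate_structure_fixture("hbond_pair", distance = 4.2,
                                    angle = 150)
  expect_equal(nrow(find_hbonds(far, list(resno = 1, elety = "N"),
                                list(resno = 10, elety = "O"))), 0L)
  # bad angle
  bent <- generate_structure_fixture("hbond_pair", distance = 2.9,
                                     angle = 95)
  expect_equal(nrow(find_hbonds(bent, list(resno = 1, elety = "N"),
                                list(resno = 10, elety = "O"))), 0L)
  expect_error(find_hbonds(ok, list(resno = 77), list(resno = 10)),
               "empty")
})

test_that("salt-bridge detection requires charged groups and is monotone", {
  h <- generate_structure_fixture("ideal_helix", n_res = 8)
  k <- mutate_residue(h, list(resno = 2), "LYS")
  ke <- mutate_residue(k, list(resno = 6), "GLU")
  sb <- find_salt_bridge(ke, list(resno = 2), list(resno = 6))
  expect_type(sb$present, "logical")
  expect_gt(sb$min_dist, 0)
  # present at d implies present at any larger cutoff
  if (!sb$present) {
    expect_true(find_salt_bridge(ke, list(resno = 2), list(resno = 6),
                                 d_max = sb$min_dist + 1)$present)
  }
  expect_true(find_salt_bridge(ke, list(resno = 2), list(resno = 6),
                               d_max = sb$min_dist)$present)
  expect_false(find_salt_bridge(ke, list(resno = 2), list(resno = 6),
                                d_max = sb$min_dist - 0.5)$present)
  # wrong residue types are a contract error
  expect_error(find_salt_bridge(ke, list(resno = 3), list(resno = 6)),
               "basic site")
  expect_error(find_salt_bridge(ke, list(resno = 2), list(resno = 3)),
               "acidic site")
})

test_that("hydrophobic staples need all three pairs within the cutoff", {
  tri <- generate_structure_fixture("staple_triangle", d12 = 4, d13 = 4,
                                    d23 = 4)
  sites <- list(list(resno = 1), list(resno = 2), list(resno = 3))
  st <- find_hydrophobic_staple(tri, sites)
  expect_true(st$present)
  expect_equal(st$pairs$min_dist, c(4, 4, 4), tolerance = 1e-9)
  wide <- generate_structure_fixture("staple_triangle", d12 = 4, d13 = 7,
                                     d23 = 7)
  expect_false(find_hydrophobic_staple(wide, sites)$present)
  # Gly has no side-chain carbons
  g <- tri
  g$atoms$resid[g$atoms$resno == 1] <- "GLY"
  expect_error(find_hydrophobic_staple(g, sites), "Gly")
})

test_that("helix backbone H-bond table distinguishes helical from extended and perturbed", {
  h <- generate_structure_fixture("ideal_helix", n_res = 12)
  res <- helix_backbone_hbonds(h, "A", c(1, 12))
  expect_equal(res$fraction, 1.0)
  expect_equal(nrow(res$table), 8L)
  ext <- generate_structure_fixture("ideal_helix", n_res = 12, phi = 180,
                                    psi = 180)
  expect_equal(helix_backbone_hbonds(ext, "A", c(1, 12))$fraction, 0)
  # displacing one residue breaks exactly the pairs that involve it
  pert <- h
  move <- pert$atoms$resno == 6
  pert$atoms$x[move] <- pert$atoms$x[move] + 2
  tab <- helix_backbone_hbonds(pert, "A", c(1, 12))$table
  affected <- tab$resno_i == 6 | tab$resno_i4 == 6
  # recompute by hand which pairs still satisfy the criterion
  for (r in seq_len(nrow(tab))) {
    if (!affected[r]) expect_true(tab$satisfied[r])
  }
  expect_false(all(tab$satisfied[affected]))
  # missing backbone atoms flag rows instead of failing
  gap <- h
  gap$atoms <- gap$atoms[!(gap$atoms$resno == 4 & gap$atoms$elety == "O"), ]
  res2 <- helix_backbone_hbonds(gap, "A", c(1, 12))
  expect_true(res2$table$missing[res2$table$resno_i == 4])
  expect_error(helix_backbone_hbonds(h, "A", c(1, 4)), "at least 5")
})

test_that("all detectors are invariant under rigid motion", {
  R <- random_rotation(99)
  tr <- c(-8.1, 14.2, 3.3)
  # H-bond geometry
  hp <- generate_structure_fixture("hbond_pair", distance = 3.1,
                                   angle = 140)
  hb1 <- find_hbonds(hp, list(resno = 1, elety = "N"),
                     list(resno = 10, elety = "O"))
  hb2 <- find_hbonds(transform_structure(hp, R, tr),
                     list(resno = 1, elety = "N"),
                     list(resno = 10, elety = "O"))
  expect_equal(hb2$distance, hb1$distance, tolerance = 1e-9)
  expect_equal(hb2$angle, hb1$angle, tolerance = 1e-9)
  # staple distances
  tri <- generate_structure_fixture("staple_triangle", d12 = 4, d13 = 4.4,
                                    d23 = 4.8)
  sites <- list(list(resno = 1), list(resno = 2), list(resno = 3))
  s1 <- find_hydrophobic_staple(tri, sites)
  s2 <- find_hydrophobic_staple(transform_structure(tri, R, tr), sites)
  expect_equal(s2$pairs$min_dist, s1$pairs$min_dist, tolerance = 1e-9)
  # helix H-bond fractions
  h <- generate_structure_fixture("ideal_helix", n_res = 10)
  f1 <- helix_backbone_hbonds(h, "A", c(1, 10))
  f2 <- helix_backbone_hbonds(transform_structure(h, R, tr), "A", c(1, 10))
  expect_equal(f2$fraction, f1$fraction)
  expect_equal(f2$table$distance, f1$table$distance, tolerance = 1e-9)
})
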