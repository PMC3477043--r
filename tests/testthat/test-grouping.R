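fit_oriented <- function() {
  recs <- load_bundled_dataset(include_isotypes = FALSE)
  enc <- onehot_encode(recs)
  model <- orient_axes(fit_pca(enc), recs)
  list(records = recs, enc = enc, model = model)
}

test_that("axis orientation is idempotent and sign-symmetric", {
  f <- fit_oriented()
  # orienting an already-oriented model changes nothing
  again <- orient_axes(f$model, f$records)
  expect_equal(again$vectors, f$model$vectors)
  expect_equal(again$flips, c(1L, 1L))
  # negating the eigenvectors is undone by orientation
  neg <- f$model
  neg$vectors[, 1:2] <- -neg$vectors[, 1:2]
  reneg <- orient_axes(neg, f$records)
  expect_equal(reneg$flips, c(-1L, -1L))
  expect_equal(reneg$vectors[, 1:2], f$model$vectors[, 1:2])
  # a feature matching no record is an orientation error
  expect_error(
    orient_axes(f$model, f$records,
                features = list(pc1 = list(list(column = 1, letters = "W")),
                                pc2 = list(list(column = 1, letters = "S")))),
    "matches no sequence")
})

test_that("after orientation the fungal groups sit at positive PC1", {
  f <- fit_oriented()
  proj <- project(f$model, f$enc)
  ab <- f$records$group %in% c("A", "B")
  expect_gt(mean(proj[ab, 1]), 0)
})

test_that("quadrant assignment follows the sign definition", {
  pts <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  attr(pts, "oriented") <- TRUE
  asg <- assign_quadrant(pts)
  expect_equal(asg$group, c("A", "B", "C", "D"))
  expect_false(any(asg$on_axis))
  # points on an axis take the non-negative side and are flagged
  ax <- rbind(c(0, 1), c(2, 0))
  attr(ax, "oriented") <- TRUE
  asg2 <- assign_quadrant(ax)
  expect_equal(asg2$group, c("A", "A"))
  expect_true(all(asg2$on_axis))
  # unoriented input is a contract error
  expect_error(assign_quadrant(pts[1:2, ]), "oriented")
})

test_that("quadrant assignment is invariant under positive rescaling", {
  set.seed(3)
  pts <- matrix(rnorm(40), ncol = 2)
  attr(pts, "oriented") <- TRUE
  base <- assign_quadrant(pts)$group
  sc <- pts %*% diag(c(3.7, 0.2))
  attr(sc, "oriented") <- TRUE
  expect_equal(assign_quadrant(sc)$group, base)
})

test_that("nearest-centroid assignment honours distances and tie-breaks", {
  training <- data.frame(pc1 = c(-1, -1, 1, 1), pc2 = c(0, 0, 0, 0),
                         group = c("B", "B", "A", "A"))
  # a point equal to a centroid takes that group
  p <- rbind(c(-1, 0), c(1, 0), c(0, 0))
  attr(p, "oriented") <- TRUE
  asg <- assign_nearest_centroid(p, training)
  expect_equal(asg$group, c("B", "A", "A"))  # midpoint tie -> alphabetical
  expect_error(assign_nearest_centroid(p, data.frame(pc1 = 1, pc2 = 1,
                                                     group = "")),
               "non-empty")
})

test_that("centroid refinement agrees with quadrants when clusters are quadrant-separated", {
  g <- generate_alignment(tubulin_like_spec(n = 150, noise = 0, seed = 2))
  enc <- onehot_encode(g$records)
  model <- orient_axes(fit_pca(enc), g$records,
                       features = synthetic_mode_features())
  proj <- project(model, enc)
  quad <- assign_quadrant(proj)
  ref <- refine_groups(proj)
  expect_equal(ref$group, quad$group)
  # and nearest-centroid trained on the quadrant partition reproduces it
  nc <- assign_nearest_centroid(proj, quad)
  expect_equal(nc$group, quad$group)
})

test_that("logo information content matches closed forms", {
  # fully conserved column: log2(20) bits
  lg <- logo_matrix(c("A", "A", "A", "A"))
  expect_equal(lg$ic, log2(20), tolerance = 1e-12)
  expect_equal(unname(lg$heights["A", 1]), log2(20))
  # uniform over all 20 amino acids: 0 bits
  lg20 <- logo_matrix(aa_alphabet()[1:20])
  expect_equal(lg20$ic, 0, tolerance = 1e-12)
  # 50/50 two-letter column: log2(20) - 1
  lg2 <- logo_matrix(c("A", "S", "A", "S"))
  expect_equal(lg2$ic, log2(20) - 1, tolerance = 1e-12)
  # small-sample correction subtracts 19 / (2 ln2 n)
  lgc <- logo_matrix(c("A", "A", "A", "A"), small_sample_correction = TRUE)
  expect_equal(lgc$ic, log2(20) - 19 / (2 * log(2) * 4), tolerance = 1e-12)
  # frequencies sum to one over counted symbols; gaps tracked separately
  lgg <- logo_matrix(c("A-", "AC", "A-"))
  expect_equal(unname(colSums(lgg$freq)), c(1, 1))
  expect_equal(lgg$gap_fraction, c(0, 2 / 3))
  # an all-gap column is reported missing with a warning
  expect_warning(lga <- logo_matrix(c("-A", "-C")), "only gaps")
  expect_true(is.na(lga$ic[1]))
})

test_that("dominant transitions recover the published group-defining moves", {
  lgA <- logo_matrix(c("TG", "TG", "TG"))
  expect_equal(nrow(dominant_transitions(lgA, lgA)), 0L)
  lgC <- logo_matrix(c("VD", "VD", "TD"))
  tr <- dominant_transitions(lgA, lgC)
  expect_equal(tr$column, c(2L, 1L))  # stronger transition first
  expect_equal(tr$from, c("G", "T"))
  expect_equal(tr$to, c("D", "V"))
  expect_error(dominant_transitions(lgA, logo_matrix("TGA")), "column counts")

  # bundled groups: A vs C includes the 23 and 26 columns, C vs D the 277
  d <- load_bundled_dataset()
  logos <- lapply(c(A = "A", C = "C", D = "D"), function(g) {
    logo_matrix(d[d$group == g, ])
  })
  ac <- dominant_transitions(logos$A, logos$C)
  expect_true(all(c(pbs_column(23), pbs_column(26)) %in% ac$column))
  expect_equal(ac$from[ac$column == pbs_column(23)], "T")
  expect_equal(ac$to[ac$column == pbs_column(23)], "V")
  expect_equal(ac$from[ac$column == pbs_column(26)], "G")
  expect_equal(ac$to[ac$column == pbs_column(26)], "D")
  cd <- dominant_transitions(logos$C, logos$D)
  expect_true(pbs_column(277) %in% cd$column)
  expect_equal(cd$from[cd$column == pbs_column(277)], "S")
  expect_equal(cd$to[cd$column == pbs_column(277)], "A")
})
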