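test_that("cube shape features match closed forms and scale correctly", {
  fx <- fixture_phantoms()
  sf <- shape_features(fx$cube$mask, extraction_dialect("B"))  # voxel_face
  expect_equal(unname(sf["SHAPE_VoxelVolume"]), 1000)
  expect_equal(unname(sf["SHAPE_SurfaceArea"]), 600)
  expect_equal(unname(sf["SHAPE_Sphericity"]), (36 * pi * 1e6)^(1 / 3) / 600,
               tolerance = 1e-12)
  # brute-force surface-voxel diameter oracle
  idx <- which(fx$cube$mask$data == 1L, arr.ind = TRUE)
  surf <- idx[apply(idx, 1, function(v) any(v == 2) || any(v == 11)), ]
  dmax <- sqrt(max(as.matrix(dist(surf))^2))
  expect_equal(unname(sf["SHAPE_Maximum3DDiameter"]), dmax, tolerance = 1e-9)
  expect_equal(dmax, sqrt(3 * 81), tolerance = 1e-12)

  # doubling spacing: V x8, A x4, sphericity unchanged
  big <- roi_mask(fx$cube$mask$data, c(2, 2, 2))
  sf2 <- shape_features(big, extraction_dialect("B"))
  expect_equal(unname(sf2["SHAPE_VoxelVolume"]), 8 * 1000)
  expect_equal(unname(sf2["SHAPE_SurfaceArea"]), 4 * 600)
  expect_equal(unname(sf2["SHAPE_Sphericity"]), unname(sf["SHAPE_Sphericity"]),
               tolerance = 1e-12)

  # on a ball mask the triangulated isosurface overshoots the analytic
  # sphere area (binary midpoint crossings) but stays well below the
  # staircase voxel-face area, whose ratio to the sphere tends to 3/2
  r <- 10.5
  g <- seq(-13, 13, by = 1)
  coords <- as.matrix(expand.grid(g, g, g))
  ball <- array(as.integer(rowSums(coords^2) <= r^2), c(27, 27, 27))
  bm <- roi_mask(ball, c(1, 1, 1))
  a_true <- 4 * pi * r^2
  a_mesh <- shape_features(bm, extraction_dialect("A"))["SHAPE_SurfaceArea"]
  a_face <- shape_features(bm, extraction_dialect("B"))["SHAPE_SurfaceArea"]
  expect_gt(a_mesh, a_true)
  expect_lt(a_mesh, 1.35 * a_true)
  expect_lt(a_mesh, a_face)
  expect_lt(abs(a_face / a_true - 1.5), 0.1)
})

test_that("histogram features: hand values, degeneracies, moment sampling", {
  v <- vol_of(array(c(1, 2, 3), c(3, 1, 1)))
  m <- full_mask(v$data)
  d <- discretize(v, m, 2)
  h <- histogram_features(v, m, d)
  expect_equal(unname(h["HISTO_Mean"]), 2)
  expect_equal(unname(h["HISTO_Median"]), 2)
  expect_equal(unname(h["HISTO_Range"]), 2)
  expect_equal(unname(h["HISTO_Variance"]), 2 / 3)   # population convention
  expect_equal(unname(h["HISTO_Energy"]), 1 + 4 + 9)

  fx <- fixture_phantoms()
  dc <- discretize(fx$constant$volume, fx$constant$mask, 64)
  hc <- histogram_features(fx$constant$volume, fx$constant$mask, dc)
  expect_equal(unname(hc["HISTO_Entropy"]), 0)
  expect_equal(unname(hc["HISTO_Uniformity"]), 1)
  expect_equal(unname(hc["HISTO_Variance"]), 0)
  expect_true(is.nan(hc["HISTO_Skewness"]))

  set.seed(21)
  x <- array(rnorm(1e4), c(100, 10, 10))
  vv <- vol_of(x); mm <- full_mask(x)
  hh <- histogram_features(vv, mm, discretize(vv, mm, 64))
  expect_lt(abs(hh["HISTO_Skewness"]), 0.1)
  expect_lt(abs(hh["HISTO_Kurtosis"]), 0.2)          # excess convention
  expect_equal(unname(hh["HISTO_P10"]), unname(quantile(x, 0.1, type = 7)))
})

test_that("GLCM features: constant ROI, checkerboard contrast, correlation bound", {
  fx <- fixture_phantoms()
  dc <- discretize(fx$constant$volume, fx$constant$mask, 8)
  f <- glcm_features(glcm(dc, "merge"))
  expect_equal(unname(f["GLCM_Contrast"]), 0)
  expect_equal(unname(f["GLCM_Dissimilarity"]), 0)
  expect_equal(unname(f["GLCM_Energy"]), 1)
  expect_equal(unname(f["GLCM_Entropy"]), 0)
  expect_equal(unname(f["GLCM_JointMaximum"]), 1)

  # checkerboard, single-direction matrix: all mass off-diagonal at |i-j|=1
  dchk <- discretize(fx$checkerboard$volume, fx$checkerboard$mask, 2)
  g <- glcm(dchk, "merge")
  P1 <- g$counts[, , 1] / sum(g$counts[, , 1])
  f1 <- oracle_glcm_features(P1)
  expect_equal(unname(f1["GLCM_Contrast"]), 1)       # (delta bin)^2 = 1 exactly
  expect_equal(sum(diag(P1)), 0)

  set.seed(22)
  for (rep in 1:5) {
    d <- random_disc(c(5, 5, 5), 5)
    f <- glcm_features(glcm(d, "merge"))
    expect_true(f["GLCM_Correlation"] >= -1 - 1e-12 &&
                  f["GLCM_Correlation"] <= 1 + 1e-12)
  }
})

test_that("GLRLM/GLZLM features: single-run and single-zone closed forms", {
  fx <- fixture_phantoms()
  d <- discretize(fx$run$volume, fx$run$mask, 5)
  # single direction along z (offset 3): one run of length 5
  m <- glrlm(d, "merge")
  f <- radagree:::rlm_feats(m$counts[, , 3], 5)
  expect_equal(unname(f["GLRLM_SRE"]), 1 / 25)
  expect_equal(unname(f["GLRLM_LRE"]), 25)
  expect_equal(unname(f["GLRLM_RP"]), 0.2)
  expect_equal(unname(f["GLRLM_LGRE"]), 1)   # constant ROI: all runs at level 1

  dc <- discretize(fx$constant$volume, fx$constant$mask, 8)
  z <- glzlm_features(glszm(dc))
  expect_equal(unname(z["GLZLM_SZE"]), 1 / 27^2)
  expect_equal(unname(z["GLZLM_LZE"]), 27^2)
  expect_equal(unname(z["GLZLM_ZP"]), 1 / 27)
  expect_equal(unname(z["GLZLM_GLV"]), 0)
})

test_that("NGTDM features: degeneracy caps and the 1x1x3 hand oracle", {
  fx <- fixture_phantoms()
  dc <- discretize(fx$constant$volume, fx$constant$mask, 8)
  f <- ngtdm_features(ngtdm(dc, "include"))
  expect_equal(unname(f["NGTDM_Coarseness"]), 1e6)
  expect_equal(unname(f["NGTDM_Busyness"]), 0)
  expect_equal(unname(f["NGTDM_Complexity"]), 0)
  expect_equal(unname(f["NGTDM_Strength"]), 0)

  b <- array(c(1L, 2L, 1L), c(1, 1, 3))
  d <- structure(list(bins = b, n_bins = 2L, roi_min = 0, roi_max = 2,
                      voxel_count = 3L, degenerate = FALSE, spacing = c(1, 1, 1)),
                 class = "discretized_roi")
  f2 <- ngtdm_features(ngtdm(d, "include"))
  # hand matrix: n = (2,1), s = (2,1), N_valid = 3
  o <- oracle_ngtdm_features(c(2, 1), c(2, 1), 3)
  expect_equal(f2, o, tolerance = 1e-12)
  expect_equal(unname(f2["NGTDM_Coarseness"]), 0.6, tolerance = 1e-12)

  # duplicating every voxel (n_i, s_i, N_valid all scaled by c): the
  # p-normalized features Busyness/Complexity/Contrast are invariant, while
  # Coarseness and Strength scale as 1/c through their sum-of-s_i terms
  o2 <- oracle_ngtdm_features(c(4, 2), c(4, 2), 6)
  inv <- c("NGTDM_Busyness", "NGTDM_Complexity", "NGTDM_Contrast")
  expect_equal(o[inv], o2[inv], tolerance = 1e-12)
  expect_equal(unname(o2["NGTDM_Coarseness"]), unname(o["NGTDM_Coarseness"]) / 2,
               tolerance = 1e-12)
  expect_equal(unname(o2["NGTDM_Strength"]), unname(o["NGTDM_Strength"]) / 2,
               tolerance = 1e-12)
})

test_that("extract assembles exactly 66 features with the stated invariants", {
  spec <- cohort_spec(n_patients = 1, seed = 23)
  rec <- render_patient(spec, 1)$record
  arm <- list(ct = resampling_spec("original"), mri = resampling_spec("original"))
  prep <- preprocess_pair(rec, arm)
  fv <- extract_features(prep$ct$volume, prep$ct$mask, prep$ct$disc,
                         extraction_dialect("A"))
  expect_identical(names(fv$values), feature_names()$feature)
  expect_identical(as.vector(table(fv$categories)[c("SHAPE", "HISTOGRAM", "GLCM",
                                                    "GLRLM", "GLZLM", "NGTDM")]),
                   c(4L, 16L, 18L, 11L, 12L, 5L))
  # determinism
  fv2 <- extract_features(prep$ct$volume, prep$ct$mask, prep$ct$disc,
                          extraction_dialect("A"))
  expect_identical(fv$values, fv2$values)

  # dialect A vs B on a constant-intensity sphere: shape differs only via
  # the surface algorithm; GLCM features are aggregation-invariant here
  # (every direction's co-occurrence matrix collapses to p(1,1) = 1), as are
  # GLZLM (no aggregation axis) and histogram features. GLRLM merge vs
  # average genuinely differ even on a constant ROI because chord lengths
  # vary across the 13 directions.
  g <- seq(-8, 8, by = 1)
  ball <- array(as.integer(rowSums(as.matrix(expand.grid(g, g, g))^2) <= 36),
                c(17, 17, 17))
  bv <- vol_of(array(50, c(17, 17, 17)))
  bm <- roi_mask(ball, c(1, 1, 1))
  bd <- discretize(bv, bm, 64)
  fa <- extract_features(bv, bm, bd, extraction_dialect("A"))
  fb <- extract_features(bv, bm, bd, extraction_dialect("B"))
  same <- grep("^(GLCM|GLZLM|HISTO)_", names(fa$values), value = TRUE)
  expect_equal(fa$values[same][!is.nan(fa$values[same])],
               fb$values[same][!is.nan(fb$values[same])], tolerance = 1e-12)
  expect_equal(unname(fa$values["SHAPE_VoxelVolume"]),
               unname(fb$values["SHAPE_VoxelVolume"]))
  expect_false(fa$values["SHAPE_SurfaceArea"] == fb$values["SHAPE_SurfaceArea"])
  expect_false(isTRUE(all.equal(unname(fa$values["GLRLM_GLNU"]),
                                unname(fb$values["GLRLM_GLNU"]))))
})

test_that("dialects share HISTOGRAM features; bin features are shift-invariant", {
  set.seed(24)
  x <- array(rnorm(4096, 100, 20), c(16, 16, 16))
  m <- array(as.integer(runif(4096) < 0.8), c(16, 16, 16))
  v <- vol_of(x); mk <- roi_mask(m, c(1, 1, 1))
  d <- discretize(v, mk, 16)
  fa <- extract_features(v, mk, d, extraction_dialect("A"))
  fb <- extract_features(v, mk, d, extraction_dialect("B"))
  hn <- grep("^HISTO_", names(fa$values), value = TRUE)
  expect_equal(fa$values[hn], fb$values[hn], tolerance = 1e-13)

  # adding a constant: all bin-based features unchanged
  v2 <- vol_of(x + 123.4)
  d2 <- discretize(v2, mk, 16)
  expect_identical(d$bins, d2$bins)
  fa2 <- extract_features(v2, mk, d2, extraction_dialect("A"))
  tex <- grep("^(GLCM|GLRLM|GLZLM|NGTDM)_", names(fa$values), value = TRUE)
  expect_equal(fa$values[tex], fa2$values[tex], tolerance = 1e-12)
})

test_that("merge-aggregated texture features are invariant under 90-degree rotation", {
  set.seed(25)
  d <- random_disc(c(6, 6, 6), 6)
  v <- vol_of(array(0, c(6, 6, 6)))
  rot_bins <- aperm(d$bins, c(2, 1, 3))[6:1, , , drop = FALSE]
  d2 <- d; d2$bins <- rot_bins
  fa <- c(glcm_features(glcm(d, "merge")), glrlm_features(glrlm(d, "merge")),
          glzlm_features(glszm(d)), ngtdm_features(ngtdm(d, "include")))
  fb <- c(glcm_features(glcm(d2, "merge")), glrlm_features(glrlm(d2, "merge")),
          glzlm_features(glszm(d2)), ngtdm_features(ngtdm(d2, "include")))
  expect_equal(fa, fb, tolerance = 1e-10)
})
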