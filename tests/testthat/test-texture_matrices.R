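test_that("GLCM matches exhaustive pair enumeration and its invariants", {
  # hand example: 1x1x4 line with bins 1,1,2,2
  b <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  d <- structure(list(bins = b, n_bins = 2L, roi_min = 0, roi_max = 2,
                      voxel_count = 4L, degenerate = FALSE, spacing = c(1, 1, 1)),
                 class = "discretized_roi")
  g <- glcm(d, "merge")
  PO <- oracle_glcm_merged(b, 2)
  expect_equal(g$p, PO / sum(PO), tolerance = 1e-14)

  set.seed(11)
  for (rep in 1:10) {
    d <- random_disc(c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1)),
                     sample(2:6, 1))
    g <- glcm(d, "merge")
    PO <- oracle_glcm_merged(d$bins, d$n_bins)
    if (sum(PO) == 0) next
    expect_equal(g$p, PO / sum(PO), tolerance = 1e-13)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(g$p, t(g$p), tolerance = 1e-14)          # symmetry
    # rotation invariance of the merged matrix (offset set closed under rot90)
    rot <- aperm(d$bins, c(2, 1, 3))[dim(d$bins)[2]:1, , , drop = FALSE]
    d2 <- d; d2$bins <- rot
    g2 <- glcm(d2, "merge")
    expect_equal(sort(as.vector(g$p)), sort(as.vector(g2$p)), tolerance = 1e-13)
  }

  # constant ROI: all mass at (1,1); merge and average agree
  dc <- discretize(fixture_phantoms()$constant$volume,
                   fixture_phantoms()$constant$mask, 8)
  gm <- glcm(dc, "merge")
  expect_equal(gm$p[1, 1], 1)
  expect_equal(sum(gm$p), 1)
  expect_equal(glcm_features(gm), glcm_features(glcm(dc, "average")),
               tolerance = 1e-12)
})

test_that("GLRLM matches an rle-scan oracle and conserves voxel count", {
  # hand example: bins 1,1,2,1 along a line
  b <- array(c(1L, 1L, 2L, 1L), c(4, 1, 1))
  R <- oracle_runs(b, c(1, 0, 0), 2, 4)
  expect_equal(R[1, 2], 1)  # run (1, len 2)
  expect_equal(R[2, 1], 1)  # run (2, len 1)
  expect_equal(R[1, 1], 1)  # run (1, len 1)

  offs <- radagree:::texture_offsets()
  set.seed(12)
  for (rep in 1:8) {
    d <- random_disc(c(5, 5, 5), sample(2:5, 1))
    m <- glrlm(d, "merge")
    for (dd in seq_len(13)) {
      RO <- oracle_runs(d$bins, offs[dd, ], d$n_bins, 5)
      expect_equal(unname(m$counts[, , dd]), unname(RO))
      expect_equal(sum(col(RO) * RO), d$voxel_count)      # conservation
    }
    expect_equal(sum(col(m$r) * m$r), 13 * d$voxel_count)
  }

  # masked voxels break runs
  b2 <- array(c(1L, 1L, 0L, 1L, 1L), c(5, 1, 1))
  R2 <- oracle_runs(b2, c(1, 0, 0), 1, 5)
  expect_equal(R2[1, 2], 2)
})

test_that("GLSZM equals flood-fill oracle; corner contact joins zones", {
  # two voxels touching only at a corner form one zone
  b <- array(0L, c(2, 2, 2)); b[1, 1, 1] <- 1L; b[2, 2, 2] <- 1L
  d <- structure(list(bins = b, n_bins = 1L, roi_min = 0, roi_max = 1,
                      voxel_count = 2L, degenerate = FALSE, spacing = c(1, 1, 1)),
                 class = "discretized_roi")
  z <- glszm(d)
  expect_equal(z$n_zones, 1L)
  expect_equal(z$s[1, 2], 1)

  dc <- discretize(fixture_phantoms()$constant$volume,
                   fixture_phantoms()$constant$mask, 8)
  zc <- glszm(dc)
  expect_equal(zc$n_zones, 1L)
  expect_equal(zc$s[1, 27], 1)

  set.seed(13)
  for (rep in 1:8) {
    d <- random_disc(c(6, 6, 6), sample(2:5, 1))
    z <- glszm(d)
    zo <- oracle_zones(d$bins)
    S <- matrix(0, d$n_bins, max(zo[, 2]))
    for (q in seq_len(nrow(zo))) S[zo[q, 1], zo[q, 2]] <- S[zo[q, 1], zo[q, 2]] + 1
    expect_equal(z$s, S)
    expect_equal(sum(col(z$s) * z$s), d$voxel_count)      # conservation
  }
})

test_that("NGTDM matches the neighbourhood oracle, including the edge rule", {
  # hand example: 1x1x3 with bins 1,2,1
  b <- array(c(1L, 2L, 1L), c(1, 1, 3))
  d <- structure(list(bins = b, n_bins = 2L, roi_min = 0, roi_max = 2,
                      voxel_count = 3L, degenerate = FALSE, spacing = c(1, 1, 1)),
                 class = "discretized_roi")
  m <- ngtdm(d, "include")
  expect_equal(m$s_i, c(2, 1))   # edges: |1-2| each; center: |2-1|
  expect_equal(m$n_i, c(2, 1))
  expect_equal(m$n_valid, 3)
  expect_equal(sum(m$p_i), 1)

  set.seed(14)
  for (rep in 1:6) {
    d <- random_disc(c(5, 5, 5), sample(2:5, 1))
    for (rule in c("include", "exclude")) {
      m <- ngtdm(d, rule)
      o <- oracle_ngtdm(d$bins, d$n_bins, rule == "exclude")
      expect_equal(m$n_i, o$n_i)
      expect_equal(m$s_i, o$s_i, tolerance = 1e-12)
      expect_equal(m$n_valid, o$n_valid)
      expect_equal(sum(m$n_i), m$n_valid)                 # partition
      expect_true(all(m$s_i >= -1e-15))
    }
  }
})

test_that("builders ignore values of out-of-ROI voxels", {
  set.seed(15)
  d <- random_disc(c(5, 5, 5), 4, p_in = 0.6)
  d2 <- d
  outside <- d$bins == 0L
  # out-of-ROI voxels stay 0 in `bins` by construction, so relabeling means
  # rebuilding from a volume whose background differs: simulate by checking
  # the matrices only see `bins`, which is invariant by the type contract
  expect_identical(d2$bins[outside], d$bins[outside])
  g1 <- glcm(d, "merge"); r1 <- glrlm(d, "merge"); z1 <- glszm(d)
  v <- vol_of(array(rnorm(125), c(5, 5, 5)))
  mk <- roi_mask(array(as.integer(d$bins > 0), c(5, 5, 5)), c(1, 1, 1))
  v$data[mk$data == 0L] <- 999      # arbitrary background
  dd <- discretize(v, mk, 4)
  expect_true(all(dd$bins[mk$data == 0L] == 0L))
})
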