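test_that("resampling follows the output-size rule and preserves constants", {
  set.seed(2)
  vol <- vol_of(array(rnorm(40 * 40 * 16), c(40, 40, 16)), c(0.7, 0.7, 2.5))
  msk <- full_mask(vol$data, c(0.7, 0.7, 2.5))
  rs <- resample(vol, msk, resampling_spec("external", c(1.4, 1.4, 1.4)))
  expect_identical(dim(rs$volume$data),
                   as.integer(ceiling(c(40, 40, 16) * c(0.7, 0.7, 2.5) / 1.4)))
  expect_equal(rs$volume$spacing, c(1.4, 1.4, 1.4))

  cv <- vol_of(array(3.7, c(10, 10, 10)))
  rc <- resample(cv, full_mask(cv$data),
                 resampling_spec("external", c(0.8, 0.8, 0.8)))
  expect_lt(max(abs(rc$volume$data - 3.7)), 1e-12)  # B-spline partition of unity
})

test_that("strategy=original returns inputs unchanged, bit-exact", {
  set.seed(3)
  vol <- vol_of(array(rnorm(1000), c(10, 10, 10)))
  msk <- full_mask(vol$data)
  rs <- resample(vol, msk, resampling_spec("original", c(1.4, 1.4, 1.4)))
  expect_identical(rs$volume, vol)
  expect_identical(rs$mask, msk)
})

test_that("resampling to own spacing reproduces in-grid values (interpolating spline)", {
  set.seed(4)
  vol <- vol_of(array(rnorm(12 * 11 * 9), c(12, 11, 9)), c(0.7, 0.7, 2.5))
  rs <- resample(vol, full_mask(vol$data, c(0.7, 0.7, 2.5)),
                 resampling_spec("external", c(0.7, 0.7, 2.5)))
  expect_lt(max(abs(rs$volume$data - vol$data)), 1e-9)
})

test_that("mask resampling stays binary and empty-ROI is an error", {
  set.seed(5)
  m <- array(0L, c(20, 20, 10)); m[9:12, 9:12, 4:6] <- 1L
  vol <- vol_of(array(rnorm(4000), c(20, 20, 10)), c(1, 1, 2))
  msk <- roi_mask(m, c(1, 1, 2))
  rs <- resample(vol, msk, resampling_spec("external", c(1.5, 1.5, 1.5)))
  expect_true(all(rs$mask$data %in% c(0L, 1L)))
  expect_gt(sum(rs$mask$data), 0)

  # a lone voxel that no coarse-grid sample lands on vanishes
  tiny <- array(0L, c(20, 20, 10)); tiny[2, 2, 2] <- 1L
  expect_error(resample(vol, roi_mask(tiny, c(1, 1, 2)),
                        resampling_spec("external", c(3, 3, 3))),
               "ROI vanished")
})

test_that("center anchoring shifts the grid, corner anchoring preserves origin", {
  set.seed(6)
  vol <- vol_of(array(rnorm(8000), c(20, 20, 20)), c(1, 1, 1))
  msk <- full_mask(vol$data)
  a <- resample(vol, msk, resampling_spec("internal", c(1.5, 1.5, 1.5),
                                          grid_anchor = "corner"))
  b <- resample(vol, msk, resampling_spec("internal", c(1.5, 1.5, 1.5),
                                          grid_anchor = "center"))
  expect_equal(a$volume$origin, vol$origin)
  expect_false(isTRUE(all.equal(a$volume$origin, b$volume$origin)))
  expect_false(identical(a$volume$data, b$volume$data))
})

test_that("discretization obeys the bin formula, ordering and occupancy", {
  v <- vol_of(array(c(10, 12, 20, 0), c(4, 1, 1)))
  m <- roi_mask(array(c(1L, 1L, 1L, 0L), c(4, 1, 1)), c(1, 1, 1))
  d <- discretize(v, m, 5)
  expect_identical(d$bins[1:3, 1, 1], c(1L, 2L, 5L))
  expect_identical(d$bins[4, 1, 1], 0L)
  expect_identical(d$voxel_count, 3L)
  expect_false(d$degenerate)

  # constant ROI: all bin 1, degenerate
  dc <- discretize(fixture_phantoms()$constant$volume,
                   fixture_phantoms()$constant$mask, 64)
  expect_true(all(dc$bins[dc$bins > 0] == 1L))
  expect_true(dc$degenerate)

  # order preservation on random values
  set.seed(7)
  vv <- vol_of(array(rnorm(4096), c(16, 16, 16)))
  dd <- discretize(vv, full_mask(vv$data), 16)
  o <- order(vv$data)
  expect_false(is.unsorted(dd$bins[o]))

  # 1e5 uniform values occupy all 64 bins; extremes pinned to 1 and n_bins
  set.seed(8)
  vu <- vol_of(array(runif(1e5), c(100, 100, 10)))
  du <- discretize(vu, full_mask(vu$data), 64)
  expect_identical(sort(unique(as.vector(du$bins[du$bins > 0]))), 1:64)
  expect_identical(du$bins[which.min(vu$data)], 1L)
  expect_identical(du$bins[which.max(vu$data)], 64L)

  expect_error(discretize(vu, full_mask(vu$data), 1), "n_bins")
})

test_that("histogram matching removes shifts, is monotone and rank-preserving", {
  set.seed(9)
  ref <- vol_of(array(rnorm(8000, 100, 25), c(20, 20, 20)), modality = "MRI")
  spec <- normalization_spec(ref, exclude_background = FALSE)

  # matching a volume to itself is the identity at quantile knots
  idm <- histogram_match(ref, spec)
  expect_lt(max(abs(idm$data - ref$data)), 1e-9)

  # shift-removal against a sort-based quantile oracle
  src <- image_volume(ref$data + 100, ref$spacing, ref$origin, "MRI")
  out <- histogram_match(src, spec)
  probs <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(quantile(sort(as.vector(out$data)), probs) -
                      quantile(sort(as.vector(ref$data)), probs))), 1e-9)

  # monotone: mapped values ordered like the sources
  expect_false(is.unsorted(out$data[order(src$data)]))

  expect_error(histogram_match(src, normalization_spec(
    vol_of(array(5, c(4, 4, 4)), modality = "MRI"), exclude_background = FALSE)),
    "zero intensity spread")
  expect_error(normalization_spec(ref, match_points = 200), "match_points")
})

test_that("preprocess_pair applies resample -> normalize -> discretize and is deterministic", {
  spec <- cohort_spec(n_patients = 1, seed = 31)
  rec <- render_patient(spec, 1)$record
  norm <- normalization_spec(reference_volume(spec))
  arm_orig <- list(ct = resampling_spec("original"), mri = resampling_spec("original"))
  arm_ext <- list(ct = resampling_spec("external", c(1, 1, 1)),
                  mri = resampling_spec("external", c(1.4, 1.4, 1.4)))

  p0 <- preprocess_pair(rec, arm_orig, norm = NULL)
  expect_identical(p0$ct$volume$data, rec$ct$volume$data)
  expect_identical(dim(p0$ct$disc$bins), dim(rec$ct$volume$data))

  p1 <- preprocess_pair(rec, arm_ext, norm)
  expect_equal(p1$mri$volume$spacing, c(1.4, 1.4, 1.4))
  expect_equal(p1$ct$volume$spacing, c(1, 1, 1))
  expect_true(all(p1$mri$disc$bins[p1$mri$disc$bins > 0] %in% 1:64))

  p2 <- preprocess_pair(rec, arm_ext, norm)
  expect_identical(p1$mri$volume$data, p2$mri$volume$data)
  expect_identical(p1$ct$disc$bins, p2$ct$disc$bins)
})
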