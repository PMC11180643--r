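# Preprocessing: voxel resampling, MRI histogram-matching normalization and
# fixed-bin-number discretization, applied in that order.

#' Resampling specification
#'
#' The three resampling arms: `"original"` (no resampling), `"internal"`
#' (resampling performed inside the extraction call, using the extraction
#' dialect's grid anchoring) and `"external"` (a shared prior pipeline stage,
#' always corner-anchored). Target spacings default to the isotropic working
#' spacings used for CT (1 mm) and MRI (1.4 mm).
#'
#' @param strategy One of "original", "internal", "external".
#' @param target_spacing Length-3 mm target; ignored for "original".
#' @param image_interpolator "bspline3" (cubic B-spline with prefiltering),
#'   "linear" or "nearest".
#' @param grid_anchor "corner" (output voxel 0 coincides with input voxel 0)
#'   or "center" (grid centers aligned). Dialect B center-anchors during
#'   internal resampling; this is one concrete way two programs' resampling
#'   algorithms genuinely differ.
#' @return An object of class `resampling_spec`.
#' @export
resampling_spec <- function(strategy = c("original", "internal", "external"),
                            target_spacing = c(1, 1, 1),
                            image_interpolator = c("bspline3", "linear", "nearest"),
                            grid_anchor = c("corner", "center")) {
  strategy <- match.arg(strategy)
  image_interpolator <- match.arg(image_interpolator)
  grid_anchor <- match.arg(grid_anchor)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target_spacing must be 3 positive values")
  structure(list(strategy = strategy, target_spacing = as.double(target_spacing),
                 image_interpolator = image_interpolator,
                 mask_interpolator = "nearest", grid_anchor = grid_anchor),
            class = "resampling_spec")
}

resample_offsets <- function(in_dim, in_spacing, out_dim, out_spacing, anchor) {
  # continuous input-grid index of output voxel i is offset + i * step
  step <- out_spacing / in_spacing
  if (anchor == "corner") {
    offset_mm <- c(0, 0, 0)
  } else { # center: align the physical centers of the two grids
    offset_mm <- ((in_dim - 1) * in_spacing - (out_dim - 1) * out_spacing) / 2
  }
  list(offset = offset_mm / in_spacing, step = step, offset_mm = offset_mm)
}

#' Resample a volume and its mask to a target spacing
#'
#' Output grid: `size_d = ceiling(in_size_d * in_spacing_d / target_d)`,
#' origin preserved (corner anchor) or shifted to align grid centers (center
#' anchor). The image is sampled at output voxel centers with the requested
#' interpolator (cubic B-spline by default, with IIR prefiltering so values
#' at input knots are reproduced); the mask with nearest neighbour.
#' Out-of-grid samples take the nearest edge value.
#'
#' @param vol An [image_volume()].
#' @param mask The aligned [roi_mask()].
#' @param spec A [resampling_spec()].
#' @return `list(volume =, mask =)` on the new grid (inputs unchanged for
#'   strategy "original").
#' @export
resample <- function(vol, mask, spec) {
  stopifnot(inherits(spec, "resampling_spec"))
  check_same_grid(mask, vol)
  if (spec$strategy == "original") return(list(volume = vol, mask = mask))
  in_dim <- dim(vol$data)
  tsp <- spec$target_spacing
  out_dim <- as.integer(ceiling(in_dim * vol$spacing / tsp))
  g <- resample_offsets(in_dim, vol$spacing, out_dim, tsp, spec$grid_anchor)

  vdata <- switch(spec$image_interpolator,
    bspline3 = {
      coef <- .cpp_bspline_prefilter(as.double(vol$data), in_dim)
      .cpp_bspline_sample(coef, in_dim, out_dim, g$offset, g$step)
    },
    linear = trilinear_sample(vol$data, out_dim, g$offset, g$step),
    nearest = nearest_sample(vol$data, out_dim, g$offset, g$step)
  )
  mdata <- .cpp_nn_sample(mask$data, in_dim, out_dim, g$offset, g$step)
  if (sum(mdata) == 0L) stop("ROI vanished under resampling")
  new_origin <- vol$origin + g$offset_mm
  list(volume = image_volume(array(vdata, out_dim), tsp, new_origin, vol$modality),
       mask = roi_mask(array(mdata, out_dim), tsp, new_origin))
}

nearest_sample <- function(arr, out_dim, offset, step) {
  d <- dim(arr)
  ix <- pmin(pmax(round(offset[1] + (seq_len(out_dim[1]) - 1) * step[1]), 0), d[1] - 1) + 1
  iy <- pmin(pmax(round(offset[2] + (seq_len(out_dim[2]) - 1) * step[2]), 0), d[2] - 1) + 1
  iz <- pmin(pmax(round(offset[3] + (seq_len(out_dim[3]) - 1) * step[3]), 0), d[3] - 1) + 1
  as.vector(arr[ix, iy, iz, drop = FALSE])
}

trilinear_sample <- function(arr, out_dim, offset, step) {
  d <- dim(arr)
  tx <- pmin(pmax(offset[1] + (seq_len(out_dim[1]) - 1) * step[1], 0), d[1] - 1)
  ty <- pmin(pmax(offset[2] + (seq_len(out_dim[2]) - 1) * step[2], 0), d[2] - 1)
  tz <- pmin(pmax(offset[3] + (seq_len(out_dim[3]) - 1) * step[3], 0), d[3] - 1)
  interp1 <- function(t, n) {
    i0 <- pmin(floor(t), n - 2); w <- t - i0
    list(i0 = i0 + 1, w = w)
  }
  if (d[1] == 1) tx <- tx * 0
  if (d[2] == 1) ty <- ty * 0
  if (d[3] == 1) tz <- tz * 0
  X <- interp1(tx, max(d[1], 2)); Y <- interp1(ty, max(d[2], 2)); Z <- interp1(tz, max(d[3], 2))
  ix0 <- rep(X$i0, times = out_dim[2] * out_dim[3]); wx <- rep(X$w, times = out_dim[2] * out_dim[3])
  iy0 <- rep(rep(Y$i0, each = out_dim[1]), times = out_dim[3])
  wy <- rep(rep(Y$w, each = out_dim[1]), times = out_dim[3])
  iz0 <- rep(Z$i0, each = out_dim[1] * out_dim[2]); wz <- rep(Z$w, each = out_dim[1] * out_dim[2])
  cl <- function(i, n) pmin(i, n)
  at <- function(i, j, k) arr[cbind(cl(i, d[1]), cl(j, d[2]), cl(k, d[3]))]
  v <- (1 - wx) * (1 - wy) * (1 - wz) * at(ix0, iy0, iz0) +
       wx * (1 - wy) * (1 - wz) * at(ix0 + 1, iy0, iz0) +
       (1 - wx) * wy * (1 - wz) * at(ix0, iy0 + 1, iz0) +
       wx * wy * (1 - wz) * at(ix0 + 1, iy0 + 1, iz0) +
       (1 - wx) * (1 - wy) * wz * at(ix0, iy0, iz0 + 1) +
       wx * (1 - wy) * wz * at(ix0 + 1, iy0, iz0 + 1) +
       (1 - wx) * wy * wz * at(ix0, iy0 + 1, iz0 + 1) +
       wx * wy * wz * at(ix0 + 1, iy0 + 1, iz0 + 1)
  v
}

#' Normalization specification for histogram matching
#'
#' MRI intensities are normalized by matching quantiles to a reference image
#' from a healthy subject. `match_points` quantile knots are paired between
#' source and reference (computed over voxels above the background threshold,
#' the volume mean, when `exclude_background`), and the monotone piecewise
#' linear map between knots is applied voxelwise.
#'
#' @param reference The reference [image_volume()].
#' @param enabled Default TRUE (normalization is an MRI-only stage).
#' @param histogram_levels Histogram resolution carried for interface
#'   compatibility; the mapping itself is quantile-knot based.
#' @param match_points Number of quantile knots (default 64).
#' @param exclude_background Exclude voxels below the volume mean from the
#'   quantile computation (default TRUE).
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(reference, enabled = TRUE, histogram_levels = 128L,
                               match_points = 64L, exclude_background = TRUE) {
  if (enabled) stopifnot(inherits(reference, "image_volume"))
  if (!(match_points >= 2 && match_points < histogram_levels))
    stop("need 2 <= match_points < histogram_levels")
  structure(list(reference = if (enabled) reference else NULL, enabled = enabled,
                 histogram_levels = as.integer(histogram_levels),
                 match_points = as.integer(match_points),
                 exclude_background = isTRUE(exclude_background)),
            class = "normalization_spec")
}

match_values <- function(x, exclude_background) {
  if (exclude_background) {
    fg <- x[x > mean(x)]
    if (length(fg) >= 2) return(fg)
  }
  x
}

#' Histogram-match a volume to a reference
#'
#' @param vol Source [image_volume()].
#' @param spec A [normalization_spec()] with `enabled = TRUE`.
#' @return The matched [image_volume()] (same grid).
#' @export
histogram_match <- function(vol, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  if (!spec$enabled) stop("normalization disabled in spec")
  rv <- match_values(as.vector(spec$reference$data), spec$exclude_background)
  if (max(rv) - min(rv) <= 0) stop("reference with zero intensity spread")
  sv <- match_values(as.vector(vol$data), spec$exclude_background)
  probs <- seq(0, 1, length.out = spec$match_points)
  qs <- unname(stats::quantile(sv, probs, type = 7))
  qr <- unname(stats::quantile(rv, probs, type = 7))
  # collapse tied source knots (heavy ties), keeping the map monotone
  keep <- tapply(qr, factor(qs, levels = unique(qs)), mean)
  xs <- as.numeric(names(keep)); ys <- as.numeric(keep)
  if (length(xs) < 2) {
    mapped <- rep(mean(qr), length(vol$data))
  } else {
    mapped <- stats::approx(xs, ys, xout = as.vector(vol$data), rule = 2)$y
  }
  image_volume(array(mapped, dim(vol$data)), vol$spacing, vol$origin, vol$modality)
}

#' Fixed-bin-number discretization of ROI intensities
#'
#' Maps in-ROI intensities to integer bins 1..n_bins with
#' `bin(x) = min(floor(n_bins * (x - roi_min) / (roi_max - roi_min)) + 1,
#' n_bins)`; the ROI minimum maps to bin 1 and the maximum to bin `n_bins`.
#' A constant ROI maps everything to bin 1 and is flagged degenerate.
#'
#' @param vol An [image_volume()].
#' @param mask The aligned nonempty [roi_mask()].
#' @param n_bins Number of gray-level bins (default 64; >= 2).
#' @return A `discretized_roi`: list with `bins` (3-D integer array, 0 outside
#'   the ROI), `n_bins`, `roi_min`, `roi_max`, `voxel_count`, `degenerate`,
#'   `spacing`.
#' @export
discretize <- function(vol, mask, n_bins = 64L) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(mask, vol)
  if (n_bins < 2) stop("n_bins must be >= 2")
  n_bins <- as.integer(n_bins)
  inroi <- mask$data != 0L
  if (!any(inroi)) stop("empty ROI")
  x <- vol$data[inroi]
  rmin <- min(x); rmax <- max(x)
  bins <- array(0L, dim(vol$data))
  degenerate <- rmax <= rmin
  if (degenerate) {
    bins[inroi] <- 1L
  } else {
    b <- floor(n_bins * (x - rmin) / (rmax - rmin)) + 1
    bins[inroi] <- as.integer(pmin(b, n_bins))
  }
  structure(list(bins = bins, n_bins = n_bins, roi_min = rmin, roi_max = rmax,
                 voxel_count = sum(inroi), degenerate = degenerate,
                 spacing = vol$spacing),
            class = "discretized_roi")
}

#' Preprocess one patient record under a resampling arm
#'
#' Applies, per modality and in order: resample, histogram matching (MRI only,
#' when enabled), and fixed-bin-number discretization. All intermediates are
#' returned for inspection. When the reference image is supplied it is
#' resampled to the MRI working spacing before matching (for non-original
#' arms), so source and reference histograms live on comparable grids.
#'
#' @param record A [patient_record()].
#' @param arm `list(ct =, mri =)` of [resampling_spec()]s.
#' @param norm A [normalization_spec()] (or NULL to skip normalization).
#' @param n_bins Discretization bins (default 64).
#' @return `list(ct = list(volume, mask, disc), mri = list(volume, mask, disc))`.
#' @export
preprocess_pair <- function(record, arm, norm = NULL, n_bins = 64L) {
  stopifnot(inherits(record, "patient_record"))
  out <- list()
  for (mod in c("ct", "mri")) {
    side <- record[[mod]]
    rs <- resample(side$volume, side$mask, arm[[mod]])
    if (mod == "mri" && !is.null(norm) && isTRUE(norm$enabled)) {
      ref <- norm$reference
      if (arm$mri$strategy != "original") {
        refmask <- roi_mask(array(1L, dim(ref$data)), ref$spacing, ref$origin)
        ref <- resample(ref, refmask, arm$mri)$volume
      }
      spec2 <- normalization_spec(ref, TRUE, norm$histogram_levels,
                                  norm$match_points, norm$exclude_background)
      rs$volume <- histogram_match(rs$volume, spec2)
    }
    out[[mod]] <- list(volume = rs$volume, mask = rs$mask,
                       disc = discretize(rs$volume, rs$mask, n_bins))
  }
  out
}
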