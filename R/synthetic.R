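# Synthetic paired CT/MRI phantom cohorts: shared continuous tumor geometry
# sampled on modality-specific grids, modality-specific intensity and noise
# models, and a tunable cross-modality texture correlation rho, so the
# agreement analysis has a known ground truth to recover.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Documented child-seed hash: deterministic, patient- and stream-specific,
# kept below 2^31.
child_seed <- function(seed, index, stream) {
  (as.double(seed) * 1000003 + index * 10007 + stream * 101) %% 2147483629
}

#' Cohort generation specification
#'
#' Defaults state the emulated study conditions: 35 patients, CT voxel
#' spacing 0.7 x 0.7 x 2 mm with low noise, MRI 1.4 x 1.4 x 2.5 mm with
#' higher noise and a multiplicative bias field, shared tumor geometry per
#' patient, and cross-modality texture coupling rho. Grids default to a
#' reduced 64^3-scale extent so the full experimental grid runs at desk
#' scale; `full_size = TRUE` restores clinical extents and the 20-150 mm
#' tumor diameter range (desk-scale default 20-32 mm, bounded by the reduced
#' field of view).
#'
#' @param n_patients Number of patients (default 35).
#' @param seed Integer master seed.
#' @param tumor_diameter_range mm interval; NULL picks the scale default.
#' @param ct_spacing,mri_spacing Acquisition spacings, mm.
#' @param grid_ct,grid_mri Grid extents (voxels); NULL picks the scale default.
#' @param texture_correlation rho in [0, 1]: correlation between the CT and
#'   MRI intratumoral texture fields.
#' @param ct_noise_sd,mri_noise_sd Additive Gaussian noise SD (intensity units).
#' @param mri_bias_amplitude Fractional amplitude of the smooth multiplicative
#'   MRI bias field.
#' @param texture_length_scale Correlation length of the Gaussian random
#'   texture field, mm.
#' @param texture_amplitude_ct Texture SD in CT units (HU).
#' @param texture_amplitude_mri Texture SD in MRI units; NULL derives it via
#'   the affine CT-to-MRI intensity rescale (slope x CT amplitude).
#' @param mri_slope,mri_intercept Affine map from the CT tissue map to MRI
#'   arbitrary units.
#' @param heterogeneity_sdlog,length_scale_sdlog Lognormal SDs of the
#'   per-patient texture-contrast multiplier (shared between modalities) and
#'   length-scale jitter; these give the cohort between-patient feature
#'   variance.
#' @param full_size Use clinical grid extents (default FALSE).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 35L, seed = 1L,
                        tumor_diameter_range = NULL,
                        ct_spacing = c(0.7, 0.7, 2.0),
                        mri_spacing = c(1.4, 1.4, 2.5),
                        grid_ct = NULL, grid_mri = NULL,
                        texture_correlation = 0.3,
                        ct_noise_sd = 5, mri_noise_sd = 20,
                        mri_bias_amplitude = 0.2,
                        texture_length_scale = 6,
                        texture_amplitude_ct = 40,
                        texture_amplitude_mri = NULL,
                        mri_slope = 0.45, mri_intercept = 390,
                        heterogeneity_sdlog = 0.35,
                        length_scale_sdlog = 0.15,
                        full_size = FALSE) {
  if (is.null(grid_ct)) grid_ct <- if (full_size) c(320L, 320L, 96L) else c(64L, 64L, 64L)
  if (is.null(grid_mri)) grid_mri <- if (full_size) c(160L, 160L, 77L) else c(32L, 32L, 52L)
  if (is.null(tumor_diameter_range))
    tumor_diameter_range <- if (full_size) c(20, 150) else c(20, 32)
  if (is.null(texture_amplitude_mri))
    texture_amplitude_mri <- mri_slope * texture_amplitude_ct
  spec <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    tumor_diameter_range = as.double(tumor_diameter_range),
    ct_spacing = as.double(ct_spacing), mri_spacing = as.double(mri_spacing),
    grid_ct = as.integer(grid_ct), grid_mri = as.integer(grid_mri),
    texture_correlation = texture_correlation,
    ct_noise_sd = ct_noise_sd, mri_noise_sd = mri_noise_sd,
    mri_bias_amplitude = mri_bias_amplitude,
    texture_length_scale = texture_length_scale,
    texture_amplitude_ct = texture_amplitude_ct,
    texture_amplitude_mri = texture_amplitude_mri,
    mri_slope = mri_slope, mri_intercept = mri_intercept,
    heterogeneity_sdlog = heterogeneity_sdlog,
    length_scale_sdlog = length_scale_sdlog,
    full_size = isTRUE(full_size)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 1) stop("invalid n_patients")
  rho <- spec$texture_correlation
  if (!is.finite(rho) || rho < 0 || rho > 1)
    stop("invalid texture_correlation (need 0 <= rho <= 1)")
  if (spec$ct_noise_sd < 0 || spec$mri_noise_sd < 0)
    stop("invalid noise sd (ct_noise_sd/mri_noise_sd must be >= 0)")
  if (any(spec$ct_spacing <= 0) || any(spec$mri_spacing <= 0))
    stop("invalid spacing (ct_spacing/mri_spacing must be positive)")
  dr <- spec$tumor_diameter_range
  if (length(dr) != 2 || dr[1] <= 0 || dr[2] < dr[1])
    stop("invalid tumor_diameter_range")
  fov <- pmin(spec$grid_ct * spec$ct_spacing, spec$grid_mri * spec$mri_spacing)
  if (dr[2] * 1.15 + 4 > min(fov))
    stop("invalid tumor_diameter_range: tumors would exceed the field of view (",
         format(min(fov)), " mm)")
  if (spec$texture_length_scale <= 0) stop("invalid texture_length_scale")
  if (spec$mri_bias_amplitude < 0 || spec$mri_bias_amplitude >= 1)
    stop("invalid mri_bias_amplitude")
  invisible(spec)
}

#' Randomized continuous tumor shape
#'
#' An ellipsoid with lognormal semi-axis ratios under a random rotation,
#' perturbed by smooth low-frequency directional noise: the implicit
#' function is phi(x) = 1 - r / r_p(u), where r_p(u) is the perturbed
#' ellipsoid radius along direction u. phi >= 0 inside; phi < 0 everywhere
#' outside radius max(semi-axes) x (1 + amplitude), so the shape is bounded.
#'
#' @param seed Shape seed (bit-reproducible).
#' @param diameter Target maximum diameter, mm (the largest semi-axis is
#'   diameter/2 before perturbation).
#' @param perturb_amplitude Radial perturbation amplitude as a fraction of
#'   the ellipsoid radius (0 gives an exact ellipsoid).
#' @param n_modes Number of directional perturbation modes.
#' @return A list with `fun(pts)` (implicit function on n x 3 mm
#'   coordinates, tumor-centered), `semi_axes`, `max_radius`, `diameter`.
#' @export
tumor_shape <- function(seed, diameter, perturb_amplitude = 0.15, n_modes = 6L) {
  stopifnot(diameter > 0, perturb_amplitude >= 0, perturb_amplitude < 0.5)
  par <- with_seed(seed, {
    ratios <- pmin(pmax(exp(stats::rnorm(2, -0.25, 0.15)), 0.45), 1)
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    list(axes = c(diameter / 2, diameter / 2 * ratios),
         rot = rot,
         freqs = matrix(stats::rnorm(3 * n_modes, sd = 1.5), n_modes, 3),
         phases = stats::runif(n_modes, 0, 2 * pi),
         coefs = { cf <- stats::rnorm(n_modes); cf / sqrt(sum(cf^2)) })
  })
  amp <- perturb_amplitude
  fun <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    local <- pts %*% par$rot
    r <- sqrt(rowSums(local^2))
    safe <- pmax(r, 1e-9)
    u <- local / safe
    re <- 1 / sqrt((u[, 1] / par$axes[1])^2 + (u[, 2] / par$axes[2])^2 +
                     (u[, 3] / par$axes[3])^2)
    g <- rep(0, nrow(pts))
    if (amp > 0) {
      for (m in seq_len(nrow(par$freqs)))
        g <- g + par$coefs[m] * sin(u %*% par$freqs[m, ] + par$phases[m])
      g <- pmin(pmax(g, -1), 1)
    }
    phi <- 1 - r / (re * (1 + amp * g))
    phi[r < 1e-9] <- 1
    as.vector(phi)
  }
  list(fun = fun, semi_axes = par$axes,
       max_radius = max(par$axes) * (1 + amp), diameter = diameter)
}

#' Volume of a continuous shape by dense sampling
#'
#' @param shape A [tumor_shape()].
#' @param step Sampling step, mm.
#' @return Volume in mm^3.
#' @export
shape_volume <- function(shape, step = 1) {
  R <- shape$max_radius + step
  g <- seq(-R, R, by = step)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  sum(shape$fun(pts) >= 0) * step^3
}

# Gaussian random field: white noise on a world-space lattice smoothed to the
# requested correlation length, standardized to zero mean / unit SD.
gaussian_field <- function(seed, lo, hi, length_scale, step = NULL) {
  if (is.null(step)) step <- max(1, length_scale / 2)
  n <- pmax(as.integer(ceiling((hi - lo) / step)) + 1L, 4L)
  vals <- with_seed(seed, array(stats::rnorm(prod(n)), dim = n))
  sigma <- length_scale / step
  vals <- smooth_sep(vals, sigma)
  vals <- (vals - mean(vals)) / stats::sd(vals)
  list(lo = lo, step = step, dim = n, values = vals)
}

smooth_sep <- function(arr, sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(-h:h, sd = sigma)
  d <- dim(arr)
  conv_mat <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - h):(i + h)
      ok <- j >= 1 & j <= n
      M[i, j[ok]] <- kern[ok]
      M[i, ] <- M[i, ] / sum(M[i, ])
    }
    M
  }
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- conv_mat(da[1]) %*% matrix(a, nrow = da[1])
    arr <- aperm(array(m, da), order(perm))
  }
  arr
}

field_eval <- function(field, pts) {
  pts <- matrix(pts, ncol = 3)
  n <- field$dim
  out <- rep(0, nrow(pts))
  t1 <- pmin(pmax((pts[, 1] - field$lo[1]) / field$step, 0), n[1] - 1)
  t2 <- pmin(pmax((pts[, 2] - field$lo[2]) / field$step, 0), n[2] - 1)
  t3 <- pmin(pmax((pts[, 3] - field$lo[3]) / field$step, 0), n[3] - 1)
  i0 <- pmin(floor(t1), n[1] - 2); w1 <- t1 - i0
  j0 <- pmin(floor(t2), n[2] - 2); w2 <- t2 - j0
  k0 <- pmin(floor(t3), n[3] - 2); w3 <- t3 - k0
  v <- field$values
  at <- function(a, b, c) v[cbind(i0 + 1 + a, j0 + 1 + b, k0 + 1 + c)]
  (1 - w1) * (1 - w2) * (1 - w3) * at(0, 0, 0) +
    w1 * (1 - w2) * (1 - w3) * at(1, 0, 0) +
    (1 - w1) * w2 * (1 - w3) * at(0, 1, 0) +
    w1 * w2 * (1 - w3) * at(1, 1, 0) +
    (1 - w1) * (1 - w2) * w3 * at(0, 0, 1) +
    w1 * (1 - w2) * w3 * at(1, 0, 1) +
    (1 - w1) * w2 * w3 * at(0, 1, 1) +
    w1 * w2 * w3 * at(1, 1, 1)
}

# CT-valued tissue map on a grid: lung background, a mediastinal soft-tissue
# slab, tumor interior.
tissue_map <- function(pts, dims, fov, shape, center) {
  base <- rep(-800, nrow(pts))
  base[pts[, 1] < 0.25 * fov[1]] <- 40
  inside <- shape$fun(sweep(pts, 2, center)) >= 0
  base[inside] <- 60
  list(base = base, inside = inside)
}

#' Render one synthetic patient
#'
#' CT volume = tissue map (lung -800 / soft tissue 40 / tumor interior 60 HU)
#' + intratumoral texture (amplitude x per-patient heterogeneity multiplier)
#' + Gaussian noise. MRI volume = affine-rescaled tissue map x smooth
#' multiplicative bias field + intratumoral texture + noise, where the MRI
#' texture field is `rho * T_shared + sqrt(1 - rho^2) * T_independent` and
#' T_shared is the CT texture field evaluated on the MRI grid. Both masks
#' sample the same continuous tumor shape.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index 1-based patient index (drives child seeds).
#' @return A `phantom`: `record` ([patient_record()]) and `truth` (diameter,
#'   volume by dense sampling, rho, heterogeneity multiplier, seeds).
#' @export
render_patient <- function(spec, patient_index) {
  validate_cohort_spec(spec)
  i <- patient_index
  s_shape <- child_seed(spec$seed, i, 1)
  s_tex_ct <- child_seed(spec$seed, i, 2)
  s_tex_mri <- child_seed(spec$seed, i, 3)
  s_noise_ct <- child_seed(spec$seed, i, 4)
  s_noise_mri <- child_seed(spec$seed, i, 5)
  s_misc <- child_seed(spec$seed, i, 6)

  draws <- with_seed(s_misc, {
    list(diameter = stats::runif(1, spec$tumor_diameter_range[1],
                                 spec$tumor_diameter_range[2]),
         h = exp(stats::rnorm(1, 0, spec$heterogeneity_sdlog)),
         lsc = spec$texture_length_scale *
           exp(stats::rnorm(1, 0, spec$length_scale_sdlog)),
         center_u = stats::runif(3),
         bias_phase = stats::runif(3, 0, 2 * pi))
  })
  shape <- tumor_shape(s_shape, draws$diameter)

  ct_ext <- (spec$grid_ct - 1) * spec$ct_spacing
  mri_ext <- (spec$grid_mri - 1) * spec$mri_spacing
  lo <- rep(shape$max_radius + 2, 3)
  hi <- pmin(ct_ext, mri_ext) - shape$max_radius - 2
  if (any(hi < lo)) stop("tumor exceeding grid (diameter ",
                         format(draws$diameter), " mm)")
  center <- lo + draws$center_u * (hi - lo)

  flo <- center - (shape$max_radius + 2 * draws$lsc)
  fhi <- center + (shape$max_radius + 2 * draws$lsc)
  f_ct <- gaussian_field(s_tex_ct, flo, fhi, draws$lsc)
  f_ind <- gaussian_field(s_tex_mri, flo, fhi, draws$lsc)
  rho <- spec$texture_correlation

  make_side <- function(dims, spacing, modality) {
    pts <- voxel_centers_mm(dims, spacing, c(0, 0, 0))
    fov <- dims * spacing
    tm <- tissue_map(pts, dims, fov, shape, center)
    if (modality == "CT") {
      tex <- field_eval(f_ct, pts[tm$inside, , drop = FALSE])
      vals <- tm$base
      vals[tm$inside] <- vals[tm$inside] +
        spec$texture_amplitude_ct * draws$h * tex
      if (spec$ct_noise_sd > 0)
        vals <- vals + with_seed(s_noise_ct,
                                 stats::rnorm(length(vals), 0, spec$ct_noise_sd))
    } else {
      t_sh <- field_eval(f_ct, pts[tm$inside, , drop = FALSE])
      t_in <- field_eval(f_ind, pts[tm$inside, , drop = FALSE])
      tex <- rho * t_sh + sqrt(1 - rho^2) * t_in
      bias <- 1 + spec$mri_bias_amplitude *
        cos(pi * pts[, 1] / fov[1] + draws$bias_phase[1]) *
        cos(pi * pts[, 2] / fov[2] + draws$bias_phase[2]) *
        cos(pi * pts[, 3] / fov[3] + draws$bias_phase[3])
      vals <- (spec$mri_slope * tm$base + spec$mri_intercept) * bias
      vals[tm$inside] <- vals[tm$inside] +
        spec$texture_amplitude_mri * draws$h * tex
      if (spec$mri_noise_sd > 0)
        vals <- vals + with_seed(s_noise_mri,
                                 stats::rnorm(length(vals), 0, spec$mri_noise_sd))
    }
    if (sum(tm$inside) == 0) stop("tumor mask empty on ", modality, " grid")
    list(volume = image_volume(array(vals, dims), spacing, c(0, 0, 0), modality),
         mask = roi_mask(array(as.integer(tm$inside), dims), spacing, c(0, 0, 0)))
  }

  ct <- make_side(spec$grid_ct, spec$ct_spacing, "CT")
  mri <- make_side(spec$grid_mri, spec$mri_spacing, "MRI")
  pid <- sprintf("P%03d", i)
  vol_step <- min(max(draws$diameter / 40, 0.5), 2)
  structure(list(
    record = patient_record(pid, ct, mri),
    truth = data.frame(patient_id = pid, diameter = draws$diameter,
                       true_volume = shape_volume(shape, vol_step),
                       rho = rho, heterogeneity = draws$h,
                       length_scale = draws$lsc,
                       seed_shape = s_shape, stringsAsFactors = FALSE)),
    class = "phantom")
}

#' Generate a cohort of paired phantoms
#'
#' Child seeds are derived deterministically from `spec$seed`, so the same
#' spec always yields the same cohort. When `dir` is given, volumes and
#' masks are written as NIfTI (`<pid>_<modality>.nii.gz`,
#' `<pid>_<modality>_mask.nii.gz`) plus `truth.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @return `list(records = list of patient_record, truth = data.frame,
#'   dir = dir or NULL)` invisibly when writing, visibly otherwise.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  validate_cohort_spec(spec)
  phantoms <- lapply(seq_len(spec$n_patients), function(i) render_patient(spec, i))
  records <- lapply(phantoms, `[[`, "record")
  truth <- do.call(rbind, lapply(phantoms, `[[`, "truth"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in records) {
      for (mod in c("ct", "mri")) {
        write_volume(r[[mod]]$volume,
                     file.path(dir, sprintf("%s_%s.nii.gz", r$patient_id, mod)))
        write_volume(r[[mod]]$mask,
                     file.path(dir, sprintf("%s_%s_mask.nii.gz", r$patient_id, mod)))
      }
    }
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out <- list(records = records, truth = truth, dir = dir)
  if (is.null(dir)) out else invisible(out)
}

#' Healthy-subject MRI reference volume
#'
#' A tumor-free MRI-like volume (same intensity model as [render_patient()]
#' without the tumor) used as the histogram-matching reference. This is a
#' synthetic surrogate for the study's healthy-subject reference image.
#'
#' @param spec A [cohort_spec()].
#' @return An MRI [image_volume()].
#' @export
reference_volume <- function(spec) {
  dims <- spec$grid_mri; spacing <- spec$mri_spacing
  pts <- voxel_centers_mm(dims, spacing, c(0, 0, 0))
  fov <- dims * spacing
  base <- rep(-800, nrow(pts))
  base[pts[, 1] < 0.25 * fov[1]] <- 40
  s_ref <- child_seed(spec$seed, 0, 7)
  phase <- with_seed(s_ref, stats::runif(3, 0, 2 * pi))
  bias <- 1 + spec$mri_bias_amplitude *
    cos(pi * pts[, 1] / fov[1] + phase[1]) *
    cos(pi * pts[, 2] / fov[2] + phase[2]) *
    cos(pi * pts[, 3] / fov[3] + phase[3])
  vals <- (spec$mri_slope * base + spec$mri_intercept) * bias
  if (spec$mri_noise_sd > 0)
    vals <- vals + with_seed(s_ref + 1,
                             stats::rnorm(length(vals), 0, spec$mri_noise_sd))
  image_volume(array(vals, dims), spacing, c(0, 0, 0), "MRI")
}

#' Fixed tiny phantoms for oracle tests
#'
#' Deterministic hand-checkable fixtures: a 10x10x10 solid cube (ramp
#' intensities) in a 12^3 grid, a 1x1x5 constant run phantom, a 3x3x3
#' constant block, and a 4x4x4 two-level parity checkerboard. Repeated calls
#' return identical objects.
#'
#' @return Named list; each element is `list(volume =, mask =)`.
#' @export
fixture_phantoms <- function() {
  cube_m <- array(0L, c(12, 12, 12))
  cube_m[2:11, 2:11, 2:11] <- 1L
  cube_v <- array(as.double(slice.index(cube_m, 1)), c(12, 12, 12))

  run_v <- array(7, c(1, 1, 5))
  run_m <- array(1L, c(1, 1, 5))

  const_v <- array(5, c(3, 3, 3))
  const_m <- array(1L, c(3, 3, 3))

  idx <- array(seq_len(64) - 1, c(4, 4, 4))
  par3 <- (slice.index(idx, 1) + slice.index(idx, 2) + slice.index(idx, 3)) %% 2
  chk_v <- array(10 * par3, c(4, 4, 4))
  chk_m <- array(1L, c(4, 4, 4))

  list(
    cube = list(volume = image_volume(cube_v, c(1, 1, 1), modality = "CT"),
                mask = roi_mask(cube_m, c(1, 1, 1))),
    run = list(volume = image_volume(run_v, c(1, 1, 1), modality = "CT"),
               mask = roi_mask(run_m, c(1, 1, 1))),
    constant = list(volume = image_volume(const_v, c(1, 1, 1), modality = "CT"),
                    mask = roi_mask(const_m, c(1, 1, 1))),
    checkerboard = list(volume = image_volume(chk_v, c(1, 1, 1), modality = "CT"),
                        mask = roi_mask(chk_m, c(1, 1, 1)))
  )
}
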