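# The 66 radiomic features: 4 shape, 16 histogram, 18 GLCM, 11 GLRLM,
# 12 GLZLM, 5 NGTDM, computed under a named extraction dialect. Formulas
# follow the IBSI reference definitions; entropies are log2; Kurtosis is
# excess (Fisher); Variance/MAD use population (1/N) normalization.

FEATURE_NAMES <- c(
  "SHAPE_VoxelVolume", "SHAPE_SurfaceArea", "SHAPE_Sphericity",
  "SHAPE_Maximum3DDiameter",
  "HISTO_Skewness", "HISTO_Kurtosis", "HISTO_Entropy", "HISTO_Energy",
  "HISTO_Uniformity", "HISTO_Mean", "HISTO_Median", "HISTO_Minimum",
  "HISTO_P10", "HISTO_P90", "HISTO_Maximum", "HISTO_InterquartileRange",
  "HISTO_Range", "HISTO_MAD", "HISTO_rMAD", "HISTO_Variance",
  "GLCM_Contrast", "GLCM_Correlation", "GLCM_Dissimilarity", "GLCM_Energy",
  "GLCM_Entropy", "GLCM_InverseDifference", "GLCM_Autocorrelation",
  "GLCM_JointAverage", "GLCM_ClusterProminence", "GLCM_ClusterTendency",
  "GLCM_ClusterShade", "GLCM_DifferenceVariance", "GLCM_DifferenceEntropy",
  "GLCM_InverseVariance", "GLCM_SumEntropy", "GLCM_JointVariance",
  "GLCM_JointMaximum", "GLCM_NID",
  "GLRLM_SRE", "GLRLM_LRE", "GLRLM_GLNU", "GLRLM_RLNU", "GLRLM_RP",
  "GLRLM_LGRE", "GLRLM_HGRE", "GLRLM_SRLGE", "GLRLM_SRHGE", "GLRLM_LRLGE",
  "GLRLM_LRHGE",
  "GLZLM_SZE", "GLZLM_LZE", "GLZLM_GLNU", "GLZLM_ZLNU", "GLZLM_ZP",
  "GLZLM_GLV", "GLZLM_LGZE", "GLZLM_HGZE", "GLZLM_SZLGE", "GLZLM_SZHGE",
  "GLZLM_LZLGE", "GLZLM_LZHGE",
  "NGTDM_Coarseness", "NGTDM_Complexity", "NGTDM_Busyness", "NGTDM_Strength",
  "NGTDM_Contrast"
)

FEATURE_CATEGORIES <- stats::setNames(
  sub("_.*", "", FEATURE_NAMES), FEATURE_NAMES
)
FEATURE_CATEGORIES[FEATURE_CATEGORIES == "HISTO"] <- "HISTOGRAM"

NGTDM_COARSENESS_CAP <- 1e6

#' Feature name table
#'
#' The ordered list of the 66 feature names with their categories
#' (SHAPE 4, HISTOGRAM 16, GLCM 18, GLRLM 11, GLZLM 12, NGTDM 5).
#'
#' @return data.frame with columns `feature`, `category`.
#' @export
feature_names <- function() {
  data.frame(feature = FEATURE_NAMES,
             category = unname(FEATURE_CATEGORIES[FEATURE_NAMES]),
             stringsAsFactors = FALSE)
}

#' Extraction dialect
#'
#' A named bundle of implementation choices on which radiomics programs
#' historically differ: texture-matrix aggregation over directions, surface
#' algorithm, resampling grid anchoring and the NGTDM edge-voxel rule.
#' Built-in dialect "A" = (merge, merge, mesh, corner, include); built-in
#' "B" = (average, average, voxel_face, center, exclude). Dialects are a
#' controlled surrogate for distinct software implementations; they are not
#' claimed reproductions of any particular program.
#'
#' @param name "A", "B", or "custom" (then set the other arguments).
#' @param glcm_aggregation,glrlm_aggregation "merge" or "average".
#' @param surface_algorithm "mesh" (marching-tetrahedra 0.5-isosurface) or
#'   "voxel_face" (exposed voxel face area).
#' @param grid_anchor "corner" or "center" (used for internal resampling).
#' @param ngtdm_edge_rule "include" or "exclude".
#' @return An object of class `extraction_dialect`.
#' @export
extraction_dialect <- function(name = c("A", "B", "custom"),
                               glcm_aggregation = "merge",
                               glrlm_aggregation = "merge",
                               surface_algorithm = "mesh",
                               grid_anchor = "corner",
                               ngtdm_edge_rule = "include") {
  name <- match.arg(name)
  if (name == "A") {
    glcm_aggregation <- "merge"; glrlm_aggregation <- "merge"
    surface_algorithm <- "mesh"; grid_anchor <- "corner"
    ngtdm_edge_rule <- "include"
  } else if (name == "B") {
    glcm_aggregation <- "average"; glrlm_aggregation <- "average"
    surface_algorithm <- "voxel_face"; grid_anchor <- "center"
    ngtdm_edge_rule <- "exclude"
  }
  stopifnot(glcm_aggregation %in% c("merge", "average"),
            glrlm_aggregation %in% c("merge", "average"),
            surface_algorithm %in% c("mesh", "voxel_face"),
            grid_anchor %in% c("corner", "center"),
            ngtdm_edge_rule %in% c("include", "exclude"))
  structure(list(name = name, glcm_aggregation = glcm_aggregation,
                 glrlm_aggregation = glrlm_aggregation,
                 surface_algorithm = surface_algorithm,
                 grid_anchor = grid_anchor,
                 ngtdm_edge_rule = ngtdm_edge_rule),
            class = "extraction_dialect")
}

#' Shape features
#'
#' VoxelVolume = voxel count x voxel volume (mm^3); SurfaceArea (mm^2) by the
#' dialect's algorithm; Sphericity = (36 pi V^2)^(1/3) / A; Maximum3DDiameter
#' = largest Euclidean distance between centres of surface voxels (mm).
#'
#' @param mask Nonempty [roi_mask()].
#' @param dialect An [extraction_dialect()].
#' @return Named numeric of length 4.
#' @export
shape_features <- function(mask, dialect = extraction_dialect("A")) {
  stopifnot(inherits(mask, "roi_mask"))
  n <- mask_count(mask)
  if (n < 1) stop("empty mask")
  sp <- mask$spacing
  V <- n * prod(sp)
  A <- if (dialect$surface_algorithm == "mesh") {
    .cpp_mesh_area(mask$data, dim(mask$data), sp)
  } else {
    .cpp_voxel_face_area(mask$data, dim(mask$data), sp)
  }
  c(SHAPE_VoxelVolume = V,
    SHAPE_SurfaceArea = A,
    SHAPE_Sphericity = (36 * pi * V^2)^(1 / 3) / A,
    SHAPE_Maximum3DDiameter = .cpp_max_diameter(mask$data, dim(mask$data), sp))
}

plog2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Histogram (first-order) features
#'
#' Order statistics, moments and dispersion from raw in-ROI intensities
#' (population 1/N convention; percentiles linear-interpolation type 7;
#' Kurtosis excess); Entropy/Uniformity from the discretized 64-bin
#' histogram (log2); Energy = sum of squared raw intensities; rMAD is the
#' mean absolute deviation restricted to the 10th-90th percentile band.
#'
#' @param vol An [image_volume()].
#' @param mask Aligned nonempty [roi_mask()].
#' @param d The matching `discretized_roi`.
#' @return Named numeric of length 16.
#' @export
histogram_features <- function(vol, mask, d) {
  x <- vol$data[mask$data != 0L]
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), type = 7, names = FALSE)
  xr <- x[x >= q[1] & x <= q[4]]
  hb <- tabulate(d$bins[d$bins > 0], nbins = d$n_bins)
  p <- hb / sum(hb)
  c(HISTO_Skewness = if (v > 0) (sum((x - mu)^3) / n) / v^1.5 else NaN,
    HISTO_Kurtosis = if (v > 0) (sum((x - mu)^4) / n) / v^2 - 3 else NaN,
    HISTO_Entropy = plog2(p),
    HISTO_Energy = sum(x^2),
    HISTO_Uniformity = sum(p^2),
    HISTO_Mean = mu,
    HISTO_Median = stats::median(x),
    HISTO_Minimum = min(x),
    HISTO_P10 = q[1],
    HISTO_P90 = q[4],
    HISTO_Maximum = max(x),
    HISTO_InterquartileRange = q[3] - q[2],
    HISTO_Range = max(x) - min(x),
    HISTO_MAD = mean(abs(x - mu)),
    HISTO_rMAD = mean(abs(xr - mean(xr))),
    HISTO_Variance = v)
}

glcm_feats_from_p <- function(P) {
  nb <- nrow(P)
  I <- row(P); J <- col(P)
  px <- rowSums(P)
  i <- seq_len(nb)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  adiff <- abs(I - J)
  pd <- vapply(0:(nb - 1), function(k) sum(P[adiff == k]), 0.0)
  mud <- sum((0:(nb - 1)) * pd)
  ssum <- I + J
  ps <- vapply(2:(2 * nb), function(k) sum(P[ssum == k]), 0.0)
  cterm <- I + J - 2 * mu
  c(GLCM_Contrast = sum((I - J)^2 * P),
    GLCM_Correlation = if (sig2 > 0) (sum(I * J * P) - mu^2) / sig2 else NaN,
    GLCM_Dissimilarity = sum(adiff * P),
    GLCM_Energy = sum(P^2),
    GLCM_Entropy = plog2(P),
    GLCM_InverseDifference = sum(P / (1 + adiff)),
    GLCM_Autocorrelation = sum(I * J * P),
    GLCM_JointAverage = mu,
    GLCM_ClusterProminence = sum(cterm^4 * P),
    GLCM_ClusterTendency = sum(cterm^2 * P),
    GLCM_ClusterShade = sum(cterm^3 * P),
    GLCM_DifferenceVariance = sum(((0:(nb - 1)) - mud)^2 * pd),
    GLCM_DifferenceEntropy = plog2(pd),
    GLCM_InverseVariance = sum(P[adiff > 0] / (adiff[adiff > 0])^2),
    GLCM_SumEntropy = plog2(ps),
    GLCM_JointVariance = sig2,
    GLCM_JointMaximum = max(P),
    GLCM_NID = sum(P / (1 + adiff / nb)))
}

#' GLCM features
#'
#' The 18 co-occurrence features. Under "merge" aggregation they are computed
#' from the single direction-merged probability matrix; under "average" each
#' direction's matrix yields a feature vector and the vectors are averaged
#' (directions without any valid pair are skipped).
#'
#' @param m A `glc_matrix` from [glcm()].
#' @return Named numeric of length 18 (all NaN when the matrix is degenerate).
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glc_matrix"))
  nms <- grep("^GLCM_", FEATURE_NAMES, value = TRUE)
  if (m$degenerate) return(stats::setNames(rep(NaN, 18), nms))
  if (m$aggregation == "merge") {
    out <- glcm_feats_from_p(m$p)
  } else {
    per <- lapply(seq_len(13), function(dd) {
      Pd <- m$p[, , dd]
      if (any(is.na(Pd))) return(NULL)
      glcm_feats_from_p(Pd)
    })
    per <- per[!vapply(per, is.null, TRUE)]
    out <- Reduce(`+`, per) / length(per)
  }
  out[nms]
}

rlm_feats <- function(R, n_vox_eff) {
  i <- row(R); j <- col(R)
  Ns <- sum(R)
  gl <- rowSums(R)   # per gray level
  rl <- colSums(R)   # per run length
  c(GLRLM_SRE = sum(R / j^2) / Ns,
    GLRLM_LRE = sum(R * j^2) / Ns,
    GLRLM_GLNU = sum(gl^2) / Ns,
    GLRLM_RLNU = sum(rl^2) / Ns,
    GLRLM_RP = Ns / n_vox_eff,
    GLRLM_LGRE = sum(R / i^2) / Ns,
    GLRLM_HGRE = sum(R * i^2) / Ns,
    GLRLM_SRLGE = sum(R / (i^2 * j^2)) / Ns,
    GLRLM_SRHGE = sum(R * i^2 / j^2) / Ns,
    GLRLM_LRLGE = sum(R * j^2 / i^2) / Ns,
    GLRLM_LRHGE = sum(R * i^2 * j^2) / Ns)
}

#' GLRLM features
#'
#' The 11 run-length features. Run Percentage divides the number of runs by
#' the effective voxel count (ROI voxels x number of merged directions, so a
#' single-direction matrix gives the textbook runs/voxels ratio).
#'
#' @param m A `glrl_matrix` from [glrlm()].
#' @return Named numeric of length 11.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrl_matrix"))
  if (m$aggregation == "merge") {
    rlm_feats(m$r, 13 * m$n_voxels)
  } else {
    per <- lapply(seq_len(13), function(dd) rlm_feats(m$r[, , dd], m$n_voxels))
    Reduce(`+`, per) / 13
  }
}

#' GLZLM (size zone) features
#'
#' The 12 size-zone features; Zone Percentage = zones / ROI voxel count and
#' Gray Level Variance is the variance of zone gray levels weighted by zone
#' counts.
#'
#' @param m A `glsz_matrix` from [glszm()].
#' @return Named numeric of length 12.
#' @export
glzlm_features <- function(m) {
  stopifnot(inherits(m, "glsz_matrix"))
  S <- m$s
  i <- row(S); j <- col(S)
  Nz <- sum(S)
  gl <- rowSums(S)
  zs <- colSums(S)
  mu <- sum(row(S) * S) / Nz
  c(GLZLM_SZE = sum(S / j^2) / Nz,
    GLZLM_LZE = sum(S * j^2) / Nz,
    GLZLM_GLNU = sum(gl^2) / Nz,
    GLZLM_ZLNU = sum(zs^2) / Nz,
    GLZLM_ZP = Nz / m$n_voxels,
    GLZLM_GLV = sum((i - mu)^2 * S) / Nz,
    GLZLM_LGZE = sum(S / i^2) / Nz,
    GLZLM_HGZE = sum(S * i^2) / Nz,
    GLZLM_SZLGE = sum(S / (i^2 * j^2)) / Nz,
    GLZLM_SZHGE = sum(S * i^2 / j^2) / Nz,
    GLZLM_LZLGE = sum(S * j^2 / i^2) / Nz,
    GLZLM_LZHGE = sum(S * i^2 * j^2) / Nz)
}

#' NGTDM features
#'
#' Coarseness, Complexity, Busyness, Strength, Contrast. Degenerate cases are
#' capped rather than raised: Coarseness = 1e6 when sum(p_i s_i) = 0;
#' Busyness = 0 when its denominator vanishes; Strength and Contrast fall to
#' 0 for a flat or single-level ROI.
#'
#' @param m An `ngtd_matrix` from [ngtdm()].
#' @return Named numeric of length 5.
#' @export
ngtdm_features <- function(m) {
  stopifnot(inherits(m, "ngtd_matrix"))
  nms <- grep("^NGTDM_", FEATURE_NAMES, value = TRUE)
  if (m$degenerate) return(stats::setNames(rep(NaN, 5), nms))
  p <- m$p_i; s <- m$s_i
  lev <- which(p > 0)
  Ngp <- length(lev)
  Nv <- m$n_valid
  ps <- sum(p * s)
  coarseness <- if (ps > 0) min(1 / ps, NGTDM_COARSENESS_CAP) else NGTDM_COARSENESS_CAP
  # pairwise sums over occupied levels
  iL <- rep(lev, times = Ngp); jL <- rep(lev, each = Ngp)
  piL <- p[iL]; pjL <- p[jL]
  contrast <- if (Ngp > 1) {
    (sum(piL * pjL * (iL - jL)^2) / (Ngp * (Ngp - 1))) * (sum(s) / Nv)
  } else 0
  busy_den <- sum(abs(iL * piL - jL * pjL))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  complexity <- if (Ngp > 1) {
    sum(abs(iL - jL) * (piL * s[iL] + pjL * s[jL]) / (piL + pjL)) / Nv
  } else 0
  strength <- if (sum(s) > 0) sum((piL + pjL) * (iL - jL)^2) / sum(s) else 0
  stats::setNames(c(coarseness, complexity, busyness, strength, contrast), nms)
}

#' Feature vector constructor (internal)
#'
#' Checks the 66-name invariant and category counts.
#' @keywords internal
feature_vector <- function(values, degenerate, dialect_name) {
  stopifnot(identical(names(values), FEATURE_NAMES))
  counts <- table(unname(FEATURE_CATEGORIES[FEATURE_NAMES]))
  stopifnot(counts[["SHAPE"]] == 4, counts[["HISTOGRAM"]] == 16,
            counts[["GLCM"]] == 18, counts[["GLRLM"]] == 11,
            counts[["GLZLM"]] == 12, counts[["NGTDM"]] == 5)
  structure(list(values = values,
                 categories = FEATURE_CATEGORIES[FEATURE_NAMES],
                 degenerate = degenerate, dialect = dialect_name),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: 66 features, dialect %s, %d degenerate>\n",
              x$dialect, length(x$degenerate)))
  invisible(x)
}

#' Extract the 66 features from one preprocessed modality
#'
#' Assembles shape, histogram and the four texture families into a single
#' ordered feature vector. Features undefined on the input (constant ROI,
#' single voxel, zero variance) are carried as NaN plus a degenerate flag,
#' never dropped, so cohort tables stay rectangular.
#'
#' @param volume Preprocessed [image_volume()].
#' @param mask Aligned [roi_mask()].
#' @param disc `discretized_roi` from [discretize()].
#' @param dialect An [extraction_dialect()].
#' @return A `feature_vector`.
#' @export
extract_features <- function(volume, mask, disc, dialect = extraction_dialect("A")) {
  vals <- c(
    shape_features(mask, dialect),
    histogram_features(volume, mask, disc),
    glcm_features(glcm(disc, dialect$glcm_aggregation)),
    glrlm_features(glrlm(disc, dialect$glrlm_aggregation)),
    glzlm_features(glszm(disc)),
    ngtdm_features(ngtdm(disc, dialect$ngtdm_edge_rule))
  )
  vals <- vals[FEATURE_NAMES]
  names(vals) <- FEATURE_NAMES
  feature_vector(vals, degenerate = FEATURE_NAMES[!is.finite(vals)],
                 dialect_name = dialect$name)
}

#' Extract features for both modalities of a preprocessed record
#'
#' @param prep Output of [preprocess_pair()].
#' @param dialect An [extraction_dialect()].
#' @return `list(ct =, mri =)` of `feature_vector`s.
#' @export
extract_record <- function(prep, dialect = extraction_dialect("A")) {
  lapply(prep, function(side)
    extract_features(side$volume, side$mask, side$disc, dialect))
}
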