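# 3-D texture matrices built from a discretized ROI: GLCM, GLRLM, GLSZM,
# NGTDM. All four use the 13 unique Chebyshev-distance-1 offsets (GLCM/GLRLM
# directions) or the full 26-neighbourhood (GLSZM zones, NGTDM neighbours),
# and masked voxels always break adjacency: runs, pairs and zones never cross
# the ROI boundary.

stopifnot_nonempty <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  if (d$voxel_count < 1) stop("empty discretized ROI")
  invisible(d)
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of in-ROI voxels at each of the 13 unique 3-D offsets
#' with Chebyshev distance 1, symmetrized by adding the transpose. Under
#' `"merge"` aggregation the 13 count matrices are summed and normalized
#' once; under `"average"` each direction is normalized separately and
#' downstream features average over directions.
#'
#' @param d A `discretized_roi`.
#' @param aggregation "merge" or "average" (an extraction-dialect axis).
#' @return A `glc_matrix`: `counts` (n_bins x n_bins x 13), `p` (merged joint
#'   probability matrix, or per-direction array for "average"), `aggregation`,
#'   `degenerate` (TRUE when no valid voxel pair exists).
#' @export
glcm <- function(d, aggregation = c("merge", "average")) {
  aggregation <- match.arg(aggregation)
  stopifnot_nonempty(d)
  nb <- d$n_bins
  counts <- array(.cpp_glcm_counts(as.integer(d$bins), dim(d$bins), nb),
                  dim = c(nb, nb, 13))
  total <- sum(counts)
  degenerate <- total == 0
  if (aggregation == "merge") {
    P <- apply(counts, c(1, 2), sum)
    if (!degenerate) P <- P / sum(P)
    p <- P
  } else {
    p <- counts
    for (dd in seq_len(13)) {
      s <- sum(counts[, , dd])
      p[, , dd] <- if (s > 0) counts[, , dd] / s else NA_real_
    }
  }
  structure(list(counts = counts, p = p, aggregation = aggregation,
                 n_bins = nb, degenerate = degenerate),
            class = "glc_matrix")
}

#' Gray-level run length matrix
#'
#' Maximal runs of equal bin value along each of the 13 directions;
#' out-of-ROI voxels break runs. `"merge"` sums run counts over directions
#' (the effective voxel count becomes 13x for Run Percentage); `"average"`
#' keeps per-direction matrices and features average over directions.
#'
#' @inheritParams glcm
#' @return A `glrl_matrix`: `counts` (n_bins x maxlen x 13), `r` (merged or
#'   per-direction), `n_voxels`, `n_directions`, `aggregation`.
#' @export
glrlm <- function(d, aggregation = c("merge", "average")) {
  aggregation <- match.arg(aggregation)
  stopifnot_nonempty(d)
  nb <- d$n_bins
  maxlen <- max(dim(d$bins))
  counts <- array(.cpp_glrlm_counts(as.integer(d$bins), dim(d$bins), nb),
                  dim = c(nb, maxlen, 13))
  r <- if (aggregation == "merge") apply(counts, c(1, 2), sum) else counts
  structure(list(counts = counts, r = r, aggregation = aggregation,
                 n_voxels = d$voxel_count,
                 n_directions = if (aggregation == "merge") 13L else 1L,
                 n_bins = nb, degenerate = FALSE),
            class = "glrl_matrix")
}

#' Gray-level size zone matrix
#'
#' Zones are maximal 26-connected components of equal bin value within the
#' ROI (corner contact joins a zone).
#'
#' @param d A `discretized_roi`.
#' @return A `glsz_matrix`: `s` (n_bins x max zone size count matrix),
#'   `n_voxels`, `n_zones`.
#' @export
glszm <- function(d) {
  stopifnot_nonempty(d)
  zones <- .cpp_glszm_zones(as.integer(d$bins), dim(d$bins))
  maxsize <- max(zones[, 2])
  s <- matrix(0, d$n_bins, maxsize)
  for (z in seq_len(nrow(zones))) {
    s[zones[z, 1], zones[z, 2]] <- s[zones[z, 1], zones[z, 2]] + 1
  }
  structure(list(s = s, n_voxels = d$voxel_count, n_zones = nrow(zones),
                 n_bins = d$n_bins, degenerate = FALSE),
            class = "glsz_matrix")
}

#' Neighbouring gray-tone difference matrix
#'
#' For each valid in-ROI voxel of gray level i, accumulates
#' `s_i += |i - mean(gray levels of its in-ROI 26-neighbours)|` and counts
#' `n_i`. With `edge_rule = "include"` (default) every voxel with at least
#' one in-ROI neighbour is valid; `"exclude"` (dialect B) restricts validity
#' to voxels whose entire 26-neighbourhood lies inside the ROI.
#'
#' @param d A `discretized_roi`.
#' @param edge_rule "include" or "exclude".
#' @return An `ngtd_matrix`: `n_i`, `s_i`, `p_i`, `n_valid`.
#' @export
ngtdm <- function(d, edge_rule = c("include", "exclude")) {
  edge_rule <- match.arg(edge_rule)
  stopifnot_nonempty(d)
  res <- .cpp_ngtdm(as.integer(d$bins), dim(d$bins), d$n_bins,
                    edge_rule == "exclude")
  nv <- res$n_valid
  structure(list(n_i = res$n_i, s_i = res$s_i,
                 p_i = if (nv > 0) res$n_i / nv else res$n_i * NA_real_,
                 n_valid = nv, n_bins = d$n_bins, degenerate = nv == 0),
            class = "ngtd_matrix")
}

#' The 13 unique Chebyshev-distance-1 offsets
#' @return 13 x 3 integer matrix.
#' @keywords internal
texture_offsets <- function() .cpp_offsets13()
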