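# Independent brute-force oracles used throughout the suite. These are
# deliberately literal (nested loops, rle scans, queue flood fill, explicit
# sums of squares) and share no code with the implementation they check.

all_offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

oracle_glcm_merged <- function(bins, nbins) {
  d <- dim(bins)
  P <- matrix(0, nbins, nbins)
  off <- all_offsets26()
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    a <- bins[i, j, k]; if (a == 0) next
    for (o in seq_len(nrow(off))) {
      i2 <- i + off[o, 1]; j2 <- j + off[o, 2]; k2 <- k + off[o, 3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      b <- bins[i2, j2, k2]; if (b == 0) next
      P[a, b] <- P[a, b] + 1
    }
  }
  P
}

# maximal runs along one direction via rle over full grid lines
oracle_runs <- function(bins, dvec, nbins, maxlen) {
  d <- dim(bins)
  R <- matrix(0, nbins, maxlen)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    ip <- i - dvec[1]; jp <- j - dvec[2]; kp <- k - dvec[3]
    if (ip >= 1 && ip <= d[1] && jp >= 1 && jp <= d[2] && kp >= 1 && kp <= d[3])
      next # not a line start
    line <- integer(0); ii <- i; jj <- j; kk <- k
    while (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3]) {
      line <- c(line, bins[ii, jj, kk])
      ii <- ii + dvec[1]; jj <- jj + dvec[2]; kk <- kk + dvec[3]
    }
    r <- rle(line)
    for (q in seq_along(r$values))
      if (r$values[q] != 0)
        R[r$values[q], r$lengths[q]] <- R[r$values[q], r$lengths[q]] + 1
  }
  R
}

# 26-connected zone decomposition by queue-based flood fill
oracle_zones <- function(bins) {
  d <- dim(bins)
  seen <- array(FALSE, d)
  off <- all_offsets26()
  zones <- NULL
  for (s in seq_along(bins)) {
    if (seen[s] || bins[s] == 0) next
    g <- bins[s]; queue <- s; seen[s] <- TRUE; size <- 0
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]; size <- size + 1
      ci <- (cur - 1) %% d[1] + 1
      cj <- ((cur - 1) %/% d[1]) %% d[2] + 1
      ck <- (cur - 1) %/% (d[1] * d[2]) + 1
      for (o in seq_len(nrow(off))) {
        i2 <- ci + off[o, 1]; j2 <- cj + off[o, 2]; k2 <- ck + off[o, 3]
        if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
        idx <- i2 + (j2 - 1) * d[1] + (k2 - 1) * d[1] * d[2]
        if (!seen[idx] && bins[idx] == g) { seen[idx] <- TRUE; queue <- c(queue, idx) }
      }
    }
    zones <- rbind(zones, c(g, size))
  }
  zones
}

oracle_ngtdm <- function(bins, nbins, require_full) {
  d <- dim(bins)
  off <- all_offsets26()
  n_i <- s_i <- numeric(nbins); n_valid <- 0
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    g <- bins[i, j, k]; if (g == 0) next
    nb <- integer(0)
    for (o in seq_len(nrow(off))) {
      i2 <- i + off[o, 1]; j2 <- j + off[o, 2]; k2 <- k + off[o, 3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      if (bins[i2, j2, k2] > 0) nb <- c(nb, bins[i2, j2, k2])
    }
    ok <- if (require_full) length(nb) == 26 else length(nb) >= 1
    if (!ok) next
    n_valid <- n_valid + 1
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  list(n_i = n_i, s_i = s_i, n_valid = n_valid)
}

# literal-formula feature oracles (double loops over matrix entries)

oracle_glcm_features <- function(P) {
  nb <- nrow(P)
  px <- rowSums(P)
  mu <- 0; for (i in 1:nb) mu <- mu + i * px[i]
  sig2 <- 0; for (i in 1:nb) sig2 <- sig2 + (i - mu)^2 * px[i]
  pd <- numeric(nb); ps <- numeric(2 * nb)
  for (i in 1:nb) for (j in 1:nb) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  out <- c(Contrast = 0, Correlation = 0, Dissimilarity = 0, Energy = 0,
           Entropy = ent(P), InverseDifference = 0, Autocorrelation = 0,
           JointAverage = mu, ClusterProminence = 0, ClusterTendency = 0,
           ClusterShade = 0, DifferenceVariance = 0, DifferenceEntropy = ent(pd),
           InverseVariance = 0, SumEntropy = ent(ps), JointVariance = sig2,
           JointMaximum = max(P), NID = 0)
  mud <- sum((0:(nb - 1)) * pd)
  for (kk in 0:(nb - 1))
    out["DifferenceVariance"] <- out["DifferenceVariance"] + (kk - mud)^2 * pd[kk + 1]
  acc_corr <- 0
  for (i in 1:nb) for (j in 1:nb) {
    p <- P[i, j]
    out["Contrast"] <- out["Contrast"] + (i - j)^2 * p
    out["Dissimilarity"] <- out["Dissimilarity"] + abs(i - j) * p
    out["Energy"] <- out["Energy"] + p^2
    out["InverseDifference"] <- out["InverseDifference"] + p / (1 + abs(i - j))
    out["Autocorrelation"] <- out["Autocorrelation"] + i * j * p
    out["ClusterProminence"] <- out["ClusterProminence"] + (i + j - 2 * mu)^4 * p
    out["ClusterTendency"] <- out["ClusterTendency"] + (i + j - 2 * mu)^2 * p
    out["ClusterShade"] <- out["ClusterShade"] + (i + j - 2 * mu)^3 * p
    if (i != j) out["InverseVariance"] <- out["InverseVariance"] + p / (i - j)^2
    out["NID"] <- out["NID"] + p / (1 + abs(i - j) / nb)
    acc_corr <- acc_corr + i * j * p
  }
  out["Correlation"] <- if (sig2 > 0) (acc_corr - mu^2) / sig2 else NaN
  names(out) <- paste0("GLCM_", names(out))
  out
}

oracle_rlm_features <- function(R, n_vox_eff) {
  Ns <- sum(R)
  out <- c(SRE = 0, LRE = 0, GLNU = 0, RLNU = 0, RP = Ns / n_vox_eff,
           LGRE = 0, HGRE = 0, SRLGE = 0, SRHGE = 0, LRLGE = 0, LRHGE = 0)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    r <- R[i, j]
    out["SRE"] <- out["SRE"] + r / j^2
    out["LRE"] <- out["LRE"] + r * j^2
    out["LGRE"] <- out["LGRE"] + r / i^2
    out["HGRE"] <- out["HGRE"] + r * i^2
    out["SRLGE"] <- out["SRLGE"] + r / (i^2 * j^2)
    out["SRHGE"] <- out["SRHGE"] + r * i^2 / j^2
    out["LRLGE"] <- out["LRLGE"] + r * j^2 / i^2
    out["LRHGE"] <- out["LRHGE"] + r * i^2 * j^2
  }
  for (i in seq_len(nrow(R))) out["GLNU"] <- out["GLNU"] + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) out["RLNU"] <- out["RLNU"] + sum(R[, j])^2
  idx <- names(out) != "RP"
  out[idx] <- out[idx] / Ns
  names(out) <- paste0("GLRLM_", names(out))
  out
}

oracle_szm_features <- function(S, n_vox) {
  Nz <- sum(S)
  mu <- 0
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) mu <- mu + i * S[i, j]
  mu <- mu / Nz
  out <- c(SZE = 0, LZE = 0, GLNU = 0, ZLNU = 0, ZP = Nz / n_vox, GLV = 0,
           LGZE = 0, HGZE = 0, SZLGE = 0, SZHGE = 0, LZLGE = 0, LZHGE = 0)
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    s <- S[i, j]
    out["SZE"] <- out["SZE"] + s / j^2
    out["LZE"] <- out["LZE"] + s * j^2
    out["GLV"] <- out["GLV"] + (i - mu)^2 * s
    out["LGZE"] <- out["LGZE"] + s / i^2
    out["HGZE"] <- out["HGZE"] + s * i^2
    out["SZLGE"] <- out["SZLGE"] + s / (i^2 * j^2)
    out["SZHGE"] <- out["SZHGE"] + s * i^2 / j^2
    out["LZLGE"] <- out["LZLGE"] + s * j^2 / i^2
    out["LZHGE"] <- out["LZHGE"] + s * i^2 * j^2
  }
  for (i in seq_len(nrow(S))) out["GLNU"] <- out["GLNU"] + sum(S[i, ])^2
  for (j in seq_len(ncol(S))) out["ZLNU"] <- out["ZLNU"] + sum(S[, j])^2
  idx <- !(names(out) %in% "ZP")
  out[idx] <- out[idx] / Nz
  names(out) <- paste0("GLZLM_", names(out))
  out
}

oracle_ngtdm_features <- function(n_i, s_i, n_valid) {
  p <- n_i / n_valid
  lev <- which(p > 0)
  Ngp <- length(lev)
  ps <- sum(p * s_i)
  coars <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in lev) for (j in lev) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (Ngp > 1) contrast / (Ngp * (Ngp - 1)) * sum(s_i) / n_valid else 0
  c(NGTDM_Coarseness = coars,
    NGTDM_Complexity = if (Ngp > 1) complexity / n_valid else 0,
    NGTDM_Busyness = if (busy_den > 0) ps / busy_den else 0,
    NGTDM_Strength = if (sum(s_i) > 0) strength / sum(s_i) else 0,
    NGTDM_Contrast = contrast)
}

# explicit sums-of-squares two-way ANOVA ICC(A,1)
oracle_icc <- function(y) {
  n <- nrow(y); k <- ncol(y); g <- mean(y)
  ssr <- 0; for (i in 1:n) ssr <- ssr + k * (mean(y[i, ]) - g)^2
  ssc <- 0; for (j in 1:k) ssc <- ssc + n * (mean(y[, j]) - g)^2
  sst <- sum((y - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# random discretized ROI for property tests
random_disc <- function(dims, nbins, p_in = 0.7) {
  repeat {
    m <- array(stats::runif(prod(dims)) < p_in, dims)
    if (sum(m) >= 2) break
  }
  b <- array(0L, dims)
  b[m] <- sample.int(nbins, sum(m), replace = TRUE)
  structure(list(bins = b, n_bins = as.integer(nbins), roi_min = 0,
                 roi_max = nbins, voxel_count = sum(m), degenerate = FALSE,
                 spacing = c(1, 1, 1)),
            class = "discretized_roi")
}

# small helper: image volume + mask wrapping an array
vol_of <- function(arr, spacing = c(1, 1, 1), modality = "CT")
  image_volume(arr, spacing, modality = modality)
full_mask <- function(arr, spacing = c(1, 1, 1))
  roi_mask(array(1L, dim(arr)), spacing)
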