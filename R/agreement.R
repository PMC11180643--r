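# Agreement analysis: two-way mixed-effects, absolute-agreement,
# single-measurement ICC; four-band reliability classification; per-band
# percentage summaries for dialect-vs-dialect and CT-vs-MRI comparisons.

#' Classify an ICC value into a reliability band
#'
#' poor (< 0.5), moderate (0.5 <= ICC < 0.75), good (0.75 <= ICC < 0.9),
#' excellent (>= 0.9). Negative ICCs are reported as computed and banded
#' poor (no clamping).
#'
#' @param icc Numeric ICC value(s).
#' @return Character vector of bands.
#' @export
icc_band <- function(icc) {
  ifelse(icc >= 0.9, "excellent",
         ifelse(icc >= 0.75, "good",
                ifelse(icc >= 0.5, "moderate", "poor")))
}

#' Single-measurement absolute-agreement ICC
#'
#' Two-way ANOVA without replication on an n x k ratings matrix gives the
#' mean squares for rows/subjects (MS_R), columns/raters (MS_C) and residual
#' error (MS_E); then
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
#' An F test of subject separation (F = MS_R/MS_E on (n-1), (n-1)(k-1) df)
#' is reported alongside but never used for banding.
#'
#' @param ratings n x k numeric matrix (n subjects >= 2, k raters >= 2).
#' @return An `icc_result`: `icc`, `ms_r`, `ms_c`, `ms_e`, `n`, `k`, `band`,
#'   `f_value`, `f_pvalue`.
#' @export
icc_single <- function(ratings) {
  y <- as.matrix(ratings)
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) stop("need n >= 2 subjects and k >= 2 raters")
  if (any(!is.finite(y))) stop("non-finite ratings")
  grand <- mean(y)
  rm_ <- rowMeans(y); cm_ <- colMeans(y)
  ms_r <- k * sum((rm_ - grand)^2) / (n - 1)
  ms_c <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  scale <- max(abs(y - grand), 1)
  if (abs(denom) <= 1e-14 * scale^2) stop("ICC undefined (no variance)")
  icc <- (ms_r - ms_e) / denom
  f <- if (ms_e > 0) ms_r / ms_e else Inf
  structure(list(icc = icc, ms_r = ms_r, ms_c = ms_c, ms_e = ms_e,
                 n = n, k = k, band = icc_band(icc), f_value = f,
                 f_pvalue = stats::pf(f, n - 1, (n - 1) * (k - 1),
                                      lower.tail = FALSE)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f [%s]  (n = %d, k = %d, F = %.3g, p = %.3g)\n",
              x$icc, x$band, x$n, x$k, x$f_value, x$f_pvalue))
  invisible(x)
}

# Build the per-feature ICC table for a pair of rater columns.
feature_icc_table <- function(tab, rater_col, raters, min_n = 3L) {
  res <- data.frame(feature = FEATURE_NAMES,
                    category = unname(FEATURE_CATEGORIES[FEATURE_NAMES]),
                    icc = NA_real_, band = NA_character_,
                    n_used = NA_integer_, f_pvalue = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (fi in seq_along(FEATURE_NAMES)) {
    f <- FEATURE_NAMES[fi]
    sub <- tab[tab$feature == f, c("patient_id", rater_col, "value", "degenerate")]
    w <- stats::reshape(sub[, c("patient_id", rater_col, "value")],
                        direction = "wide", idvar = "patient_id",
                        timevar = rater_col)
    vcols <- paste0("value.", raters)
    if (!all(vcols %in% names(w)))
      stop("missing cells for feature ", f, ": raters ",
           paste(setdiff(raters, sub[[rater_col]]), collapse = ", "))
    m <- as.matrix(w[, vcols])
    bad_pat <- unique(sub$patient_id[sub$degenerate | !is.finite(sub$value)])
    keep <- stats::complete.cases(m) & is.finite(rowSums(m)) &
      !(w$patient_id %in% bad_pat)
    m <- m[keep, , drop = FALSE]
    res$n_used[fi] <- nrow(m)
    res$flagged[fi] <- nrow(m) < nrow(w)
    if (nrow(m) < min_n) { res$flagged[fi] <- TRUE; next }
    r <- tryCatch(icc_single(m), error = function(e) NULL)
    if (is.null(r)) { res$flagged[fi] <- TRUE; next }
    res$icc[fi] <- r$icc
    res$band[fi] <- r$band
    res$f_pvalue[fi] <- r$f_pvalue
  }
  res
}

check_complete <- function(tab, rater_col, raters) {
  need <- expand.grid(patient_id = unique(tab$patient_id),
                      rater = raters, feature = FEATURE_NAMES,
                      stringsAsFactors = FALSE)
  have <- paste(tab$patient_id, tab[[rater_col]], tab$feature)
  gaps <- need[!(paste(need$patient_id, need$rater, need$feature) %in% have), ]
  if (nrow(gaps) > 0)
    stop("missing cells: ",
         paste(utils::head(paste0("(", gaps$patient_id, ", ", gaps$rater, ", ",
                                  gaps$feature, ")"), 5), collapse = " "),
         if (nrow(gaps) > 5) sprintf(" ... and %d more", nrow(gaps) - 5) else "")
  invisible(TRUE)
}

make_summary <- function(per_feature, comparison, arm, resampling) {
  defined <- per_feature[!is.na(per_feature$band), ]
  bands <- c("excellent", "good", "moderate", "poor")
  counts <- vapply(bands, function(b) sum(defined$band == b), 0L)
  pct <- if (nrow(defined) > 0) 100 * counts / nrow(defined) else counts * NA_real_
  stable <- per_feature$feature[!is.na(per_feature$band) &
                                  per_feature$band %in% c("good", "excellent")]
  structure(list(comparison = comparison, arm = arm, resampling = resampling,
                 per_feature = per_feature,
                 band_percentages = stats::setNames(pct, bands),
                 stable_features = stable,
                 n_undefined = sum(is.na(per_feature$band)),
                 flagged_features = per_feature$feature[per_feature$flagged]),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<%s | %s | %s>  excellent %.1f%%  good %.1f%%  moderate %.1f%%  poor %.1f%%\n",
              x$comparison, x$arm, x$resampling,
              x$band_percentages[1], x$band_percentages[2],
              x$band_percentages[3], x$band_percentages[4]))
  invisible(x)
}

#' Dialect-vs-dialect agreement for one modality and resampling arm
#'
#' Per feature, the ratings matrix is patients x the two dialects' values;
#' each feature gets an ICC and band; band percentages are over the features
#' with a defined ICC. Patients in which a feature is degenerate (in either
#' dialect) are dropped for that feature; features with fewer than 3 usable
#' patients, or an undefined ICC, are flagged and excluded from percentages.
#'
#' @param table Tidy cohort feature table with columns `patient_id`,
#'   `modality`, `dialect`, `resampling`, `feature`, `category`, `value`,
#'   `degenerate`.
#' @param modality "CT" or "MRI".
#' @param resampling "original", "internal" or "external".
#' @param dialects The two dialect names to compare (default c("A", "B")).
#' @return An `agreement_summary`.
#' @export
compare_dialects <- function(table, modality, resampling, dialects = c("A", "B")) {
  stopifnot(length(dialects) == 2)
  tab <- table[table$modality == modality & table$resampling == resampling &
                 table$dialect %in% dialects, ]
  check_complete(tab, "dialect", dialects)
  pf <- feature_icc_table(tab, "dialect", dialects)
  make_summary(pf, "dialectA_vs_dialectB", modality, resampling)
}

#' CT-vs-MRI agreement for one dialect and resampling arm
#'
#' As [compare_dialects()], with raters = the CT value and the MRI value of
#' each feature (computed by the same dialect). ICCs are computed on raw
#' feature values despite modality scale differences; absolute agreement
#' penalizes systematic offsets, which is the intended behaviour.
#'
#' @inheritParams compare_dialects
#' @param dialect The dialect name whose features are compared.
#' @return An `agreement_summary`.
#' @export
compare_modalities <- function(table, dialect, resampling) {
  tab <- table[table$dialect == dialect & table$resampling == resampling, ]
  check_complete(tab, "modality", c("CT", "MRI"))
  pf <- feature_icc_table(tab, "modality", c("CT", "MRI"))
  make_summary(pf, "CT_vs_MRI", dialect, resampling)
}

djb2_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write agreement reports
#'
#' One CSV row per (comparison, arm, resampling) with Excellent/Good/
#' Moderate/Poor percentages (one decimal) and the stable-feature list
#' ("none" when empty); a JSON file with per-feature ICC detail; and a
#' plain-text table. Every file starts with a provenance block (config hash,
#' seed, package version).
#'
#' @param summaries List of `agreement_summary` objects (>= 1).
#' @param dir Output directory (created if needed).
#' @param config Optional config list included in the provenance hash.
#' @param seed Optional seed recorded in the provenance block.
#' @return Invisibly, the paths written (`csv`, `json`, `txt`).
#' @export
report <- function(summaries, dir, config = NULL, seed = NULL) {
  if (inherits(summaries, "agreement_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ver <- as.character(utils::packageVersion("radagree"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg_hash <- djb2_hash(jsonlite::toJSON(strip(config), auto_unbox = TRUE,
                                         digits = NA))
  prov <- c(sprintf("# radagree %s", ver),
            sprintf("# config_hash %s", cfg_hash),
            sprintf("# seed %s", if (is.null(seed)) "NA" else seed))

  rows <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(comparison = s$comparison, arm = s$arm, resampling = s$resampling,
               excellent = sprintf("%.1f", s$band_percentages["excellent"]),
               good = sprintf("%.1f", s$band_percentages["good"]),
               moderate = sprintf("%.1f", s$band_percentages["moderate"]),
               poor = sprintf("%.1f", s$band_percentages["poor"]),
               stable_features = if (length(s$stable_features) > 0)
                 paste(s$stable_features, collapse = ";") else "none",
               stringsAsFactors = FALSE)
  }))

  csv <- file.path(dir, "agreement_bands.csv")
  writeLines(prov, csv)
  suppressWarnings(utils::write.table(rows, csv, sep = ",", row.names = FALSE,
                                      col.names = TRUE, append = TRUE, qmethod = "double"))

  json <- file.path(dir, "agreement_detail.json")
  detail <- lapply(summaries, function(s) {
    list(comparison = s$comparison, arm = s$arm, resampling = s$resampling,
         band_percentages = as.list(s$band_percentages),
         n_undefined = s$n_undefined,
         flagged_features = s$flagged_features,
         per_feature = s$per_feature)
  })
  jsonlite::write_json(list(provenance = list(version = ver, config_hash = cfg_hash,
                                              seed = seed),
                            summaries = detail),
                       json, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")

  txt <- file.path(dir, "agreement_bands.txt")
  hdr <- sprintf("%-22s %-6s %-10s %9s %6s %8s %6s", "comparison", "arm",
                 "resampling", "excellent", "good", "moderate", "poor")
  lines <- c(prov, hdr,
             vapply(seq_len(nrow(rows)), function(i)
               sprintf("%-22s %-6s %-10s %9s %6s %8s %6s", rows$comparison[i],
                       rows$arm[i], rows$resampling[i], rows$excellent[i],
                       rows$good[i], rows$moderate[i], rows$poor[i]), ""))
  writeLines(lines, txt)
  invisible(list(csv = csv, json = json, txt = txt))
}
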