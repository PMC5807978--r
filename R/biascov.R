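# Per-sample 3'-coverage bias estimation from binned coverage profiles.
#
# Degraded poly-A-selected libraries over-represent reads near transcript
# 3' ends.  The per-sample bias statistic z is the fraction of coverage in
# the 3' half of each of a set of long, high-coverage "index" transcripts,
# averaged over the index set.

#' Criteria for selecting index transcripts
#'
#' @param min_bp,max_bp transcript length window (default 2,000-6,000 bp).
#' @param require_full_length require the near-full-length flag (in real
#'   data: >= `align_fraction` of the transcript aligning to >=
#'   `reference_fraction` of a reference transcript; in synthetic data the
#'   flag is carried directly, with the two fractions recorded here).
#' @param align_fraction,reference_fraction the fractions behind the
#'   full-length rule (recorded for provenance; both default 0.9).
#' @param min_coverage_quantile candidates must have mean total coverage at
#'   or above this quantile of all candidates ("high read coverage").
#' @param max_cv maximum coefficient of variation of total coverage across
#'   samples ("little variation between samples").
#' @return Object of class `index_criteria`.
#' @export
index_criteria <- function(min_bp = 2000, max_bp = 6000,
                           require_full_length = TRUE,
                           align_fraction = 0.9, reference_fraction = 0.9,
                           min_coverage_quantile = 0.75, max_cv = 0.5) {
  if (!(min_bp > 0 && min_bp < max_bp))
    stop_msg("need 0 < min_bp < max_bp")
  if (align_fraction <= 0 || align_fraction > 1 ||
      reference_fraction <= 0 || reference_fraction > 1)
    stop_msg("full-length fractions must be in (0, 1]")
  structure(list(min_bp = min_bp, max_bp = max_bp,
                 require_full_length = require_full_length,
                 align_fraction = align_fraction,
                 reference_fraction = reference_fraction,
                 min_coverage_quantile = min_coverage_quantile,
                 max_cv = max_cv),
            class = "index_criteria")
}

check_coverage_array <- function(coverage, bins = 100) {
  if (length(dim(coverage)) != 3)
    stop_msg("coverage must be a [transcript, sample, bin] array")
  if (dim(coverage)[3] != bins)
    stop_msg("coverage must have exactly %d bins, got %d", bins, dim(coverage)[3])
  if (any(coverage < 0)) stop_msg("coverage contains negative depths")
  invisible(TRUE)
}

#' Select index transcripts for bias estimation
#'
#' Applies the length window, the near-full-length rule, a mean-coverage
#' quantile threshold and a cross-sample coefficient-of-variation cap.
#' Selection is fully deterministic.
#'
#' @param coverage `[transcript, sample, bin]` array of candidate
#'   profiles; every candidate must be profiled in every sample.
#' @param info data.frame with columns `transcript_id`, `length_bp` and
#'   (if the full-length rule is active) logical `full_length`.
#' @param criteria an [index_criteria()].
#' @return Character vector of selected transcript ids.
#' @export
select_index_transcripts <- function(coverage, info,
                                     criteria = index_criteria()) {
  check_coverage_array(coverage)
  ids <- dimnames(coverage)[[1]]
  if (!all(ids %in% info$transcript_id))
    stop_msg("info lacks rows for %d profiled transcript(s)",
             sum(!ids %in% info$transcript_id))
  info <- info[match(ids, info$transcript_id), , drop = FALSE]
  totals <- apply(coverage, c(1, 2), sum)           # transcript x sample
  mean_cov <- rowMeans(totals)
  cv <- apply(totals, 1, stats::sd) / mean_cov
  thr <- stats::quantile(mean_cov, criteria$min_coverage_quantile,
                         names = FALSE, type = 7)
  ok <- info$length_bp >= criteria$min_bp &
    info$length_bp <= criteria$max_bp &
    mean_cov >= thr &
    is.finite(cv) & cv <= criteria$max_cv
  if (criteria$require_full_length) {
    if (is.null(info$full_length))
      stop_msg("criteria require a full_length flag but info has none")
    ok <- ok & info$full_length
  }
  sel <- ids[ok]
  if (length(sel) == 0)
    stop_msg("no transcript satisfies the index criteria; consider relaxing the length window, coverage quantile or CV cap")
  sel
}

#' Fraction of coverage in the 3' half of a profile
#'
#' With bins ordered 5' to 3', returns `sum(bins 51..100) / sum(bins
#' 1..100)`.  Invariant to rescaling the profile by any positive constant.
#'
#' @param bins numeric vector of 100 non-negative binned depths.
#' @return fraction in `[0, 1]`.
#' @export
three_prime_fraction <- function(bins) {
  if (length(bins) != 100)
    stop_msg("profile must have exactly 100 bins, got %d", length(bins))
  if (any(bins < 0)) stop_msg("profile contains negative depths")
  tot <- sum(bins)
  if (tot <= 0) stop_msg("all-zero profile: 3' fraction undefined")
  sum(bins[51:100]) / tot
}

#' Per-sample 3'-bias table from an index-transcript set
#'
#' For each sample, z is the unweighted mean of the per-transcript 3'-half
#' fractions over the index set.  Index transcripts with zero total
#' coverage in a sample are excluded from that sample's mean and counted
#' in the attached QC report.
#'
#' @param coverage `[transcript, sample, bin]` array.
#' @param index_set character vector of index transcript ids.
#' @return data.frame of class `bias_table` with columns `sample_id`, `z`,
#'   `n_index`; attribute `qc` tabulates per-sample zero-coverage
#'   exclusions.
#' @export
sample_bias_table <- function(coverage, index_set) {
  check_coverage_array(coverage)
  missing <- setdiff(index_set, dimnames(coverage)[[1]])
  if (length(missing) > 0)
    stop_msg("index transcripts missing from coverage: %s",
             paste(utils::head(missing, 3), collapse = ", "))
  cov <- coverage[index_set, , , drop = FALSE]
  tot <- apply(cov, c(1, 2), sum)
  three <- apply(cov[, , 51:100, drop = FALSE], c(1, 2), sum)
  frac <- three / tot                      # NaN where total == 0
  frac[tot == 0] <- NA
  z <- colMeans(frac, na.rm = TRUE)
  n_used <- colSums(!is.na(frac))
  out <- data.frame(sample_id = colnames(tot), z = as.numeric(z),
                    n_index = length(index_set), stringsAsFactors = FALSE)
  attr(out, "qc") <- data.frame(sample_id = colnames(tot),
                                n_zero_coverage = length(index_set) - n_used,
                                stringsAsFactors = FALSE)
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Correlation of estimated 3' bias with RIN
#'
#' Reports the Pearson correlation between the per-sample bias statistic z
#' and RIN, and flags samples whose z residual from the z-on-RIN
#' regression exceeds 2 residual standard deviations (samples with higher
#' 3' coverage than their RIN predicts).
#'
#' @param bias a [sample_bias_table()] result.
#' @param meta sample metadata with columns `sample_id` and `rin`.
#' @return list with `r`, `p`, `n`, `flagged` (data.frame of outlier
#'   samples with their residuals) and `defined` (FALSE when RIN is
#'   constant, in which case the correlation is undefined and `r`/`p` are
#'   `NA`).
#' @export
bias_rin_report <- function(bias, meta) {
  df <- merge(as.data.frame(bias), meta[, c("sample_id", "rin")],
              by = "sample_id", sort = FALSE)
  if (nrow(df) < 3) stop_msg("need >= 3 samples for a correlation report")
  if (stats::sd(df$rin) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = nrow(df),
                flagged = df[0, ], defined = FALSE))
  }
  ct <- stats::cor.test(df$z, df$rin, method = "pearson")
  fit <- stats::lm(z ~ rin, data = df)
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  flag <- which(res > 2 * s)
  flagged <- data.frame(sample_id = df$sample_id[flag],
                        z = df$z[flag], rin = df$rin[flag],
                        residual = res[flag], stringsAsFactors = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(df),
       flagged = flagged, defined = TRUE)
}
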