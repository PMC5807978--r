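# Nested per-transcript linear models with likelihood-ratio tests.
#
# The response is log(TPM + 0.5).  The full model FM contains morph, time,
# their interaction and a second-degree polynomial in the per-sample
# 3'-bias statistic z; reduced models R1-R3 drop design terms while
# keeping the bias polynomial, and R4-R7 are the bias-free family:
#   FM = M + T + M:T + z + z^2      R4 = M + T + M:T
#   R1 = M + T     + z + z^2        R5 = M + T
#   R2 =     T     + z + z^2        R6 =     T
#   R3 = M         + z + z^2        R7 = M
# Each comparison of nested models yields the Gaussian likelihood-ratio
# statistic Lambda = n log(RSS_reduced / RSS_full).  Lambda is a monotone
# function of the classical F statistic, whose exact finite-sample null
# distribution under Gaussian errors is F(df1, df2); p-values are taken
# from that exact distribution (the chi-square asymptotic p is reported
# alongside) so that null calibration holds at the study's sample sizes.

MODEL_TERMS <- list(
  FM = c("morph", "time", "mt", "bias"),
  R1 = c("morph", "time", "bias"),
  R2 = c("time", "bias"),
  R3 = c("morph", "bias"),
  R4 = c("morph", "time", "mt"),
  R5 = c("morph", "time"),
  R6 = c("time"),
  R7 = c("morph"))

COMPARISONS <- data.frame(
  comparison = c("FMvR1", "R1vR2", "R1vR3", "FMvR4",
                 "R4vR5", "R5vR6", "R5vR7"),
  full = c("FM", "R1", "R1", "FM", "R4", "R5", "R5"),
  reduced = c("R1", "R2", "R3", "R4", "R5", "R6", "R7"),
  effect = c("MxT", "Morph", "Time", "Bias", "MxT", "Morph", "Time"),
  family = c("bias", "bias", "bias", "bias", "nobias", "nobias", "nobias"),
  stringsAsFactors = FALSE)

#' Retain transcripts above the low-count filter
#'
#' @param counts transcripts x samples matrix of estimated reads.
#' @param min_total retain transcripts with strictly more than this many
#'   estimated reads summed over all samples (default 200).
#' @return character vector of retained transcript ids.
#' @export
filter_low_counts <- function(counts, min_total = 200) {
  tot <- rowSums(counts)
  rownames(counts)[tot > min_total]
}

#' Build the design matrix for one model of the nested family
#'
#' Morph and time are unordered factors; the interaction is parameterised
#' over observed cells only (columns for unobserved morph x time cells are
#' dropped).  The bias polynomial uses z centred at its sample mean,
#' `(z - zbar)` and `(z - zbar)^2`, to reduce collinearity.  Whole design
#' cells can be excluded before fitting via `drop_cells`.
#'
#' @param meta sample metadata (`sample_id`, `morph`, `tau`).
#' @param model model name in `FM`, `R1`..`R7`, or a character vector of
#'   terms among `morph`, `time`, `mt`, `bias`.
#' @param z numeric per-sample bias statistic, aligned with `meta` rows
#'   (required when the model includes the bias polynomial).
#' @param drop_cells optional data.frame (`morph`, `tau`) of design cells
#'   to exclude entirely.
#' @return list with the design matrix `X` (full column rank), `keep`
#'   (logical row filter applied to `meta`), `terms`, `model`, `rank`.
#' @export
build_design <- function(meta, model = "FM", z = NULL, drop_cells = NULL) {
  terms <- if (length(model) == 1 && model %in% names(MODEL_TERMS))
    MODEL_TERMS[[model]] else model
  if (!all(terms %in% c("morph", "time", "mt", "bias")))
    stop_msg("unknown model terms: %s",
             paste(setdiff(terms, c("morph", "time", "mt", "bias")), collapse = ", "))
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(drop_cells) && nrow(drop_cells) > 0)
    keep <- !(paste(meta$morph, meta$tau) %in%
                paste(drop_cells$morph, drop_cells$tau))
  md <- meta[keep, , drop = FALSE]
  morph <- factor(md$morph, levels = unique(meta$morph))
  morph <- droplevels(morph)
  time <- factor(md$tau, levels = sort(unique(meta$tau)))
  time <- droplevels(time)
  X <- matrix(1, nrow(md), 1, dimnames = list(md$sample_id, "(Intercept)"))
  add <- function(X, M) cbind(X, M)
  if ("morph" %in% terms && nlevels(morph) > 1) {
    M <- stats::model.matrix(~morph)[, -1, drop = FALSE]
    colnames(M) <- paste0("morph_", levels(morph)[-1])
    X <- add(X, M)
  }
  if ("time" %in% terms && nlevels(time) > 1) {
    M <- stats::model.matrix(~time)[, -1, drop = FALSE]
    colnames(M) <- paste0("time_", levels(time)[-1])
    X <- add(X, M)
  }
  if ("mt" %in% terms && nlevels(morph) > 1 && nlevels(time) > 1) {
    M <- stats::model.matrix(~morph:time)[, -1, drop = FALSE]
    cn <- sub("^morph", "", colnames(M))
    cn <- sub(":time", "_", cn)
    colnames(M) <- paste0("mt_", cn)
    # drop the main-effect-aliased blocks (reference rows/cols) and
    # unobserved cells (all-zero columns)
    lev_m <- levels(morph); lev_t <- levels(time)
    want <- as.vector(outer(lev_m[-1], lev_t[-1],
                            function(a, b) paste0("mt_", a, "_", b)))
    M <- M[, intersect(want, colnames(M)), drop = FALSE]
    M <- M[, colSums(M != 0) > 0, drop = FALSE]
    X <- add(X, M)
  }
  if ("bias" %in% terms) {
    if (is.null(z)) stop_msg("model includes the bias polynomial but z is missing")
    if (length(z) != nrow(meta))
      stop_msg("z must have one value per sample (%d != %d)",
               length(z), nrow(meta))
    zc <- z[keep] - mean(z[keep])
    if (max(abs(zc)) > .Machine$double.eps^0.5) {
      X <- add(X, cbind(z1 = zc, z2 = zc^2))
    }
    # constant z leaves the bias polynomial inert (no columns added)
  }
  qx <- qr(X)
  dropped_mt <- character(0)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    # with missing design cells the observed-cell-means space can be
    # smaller than main effects + per-cell interaction coding; redundant
    # interaction columns are dropped (the fitted subspace is unchanged),
    # whereas aliasing among main or bias terms is a genuine error
    mt_aliased <- grepl("^mt_", aliased)
    if (!all(mt_aliased))
      stop_msg("rank-deficient design for model {%s}: aliased terms: %s",
               paste(terms, collapse = ","), paste(aliased, collapse = ", "))
    dropped_mt <- aliased
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop_msg("rank-deficient design for model {%s} after dropping: %s",
               paste(terms, collapse = ","), paste(aliased, collapse = ", "))
  }
  list(X = X, keep = keep, terms = terms, dropped_aliased = dropped_mt,
       model = if (length(model) == 1) model else paste(terms, collapse = "+"),
       rank = qx$rank)
}

fit_design <- function(Y, design) {
  # Y: transcripts x samples (already subset to design$keep columns)
  X <- design$X
  n <- nrow(X)
  qx <- qr(X)
  coef <- qr.coef(qx, t(Y))
  fitted <- X %*% coef
  res <- t(Y) - fitted
  rss <- colSums(res^2)
  loglik <- -n / 2 * (log(2 * pi * pmax(rss, .Machine$double.xmin) / n) + 1)
  list(model = design$model, terms = design$terms,
       coefficients = t(coef), rss = rss, n = n,
       rank = design$rank, df_residual = n - design$rank,
       loglik = loglik, transcripts = rownames(Y))
}

#' Fit one nested model to one transcript by ordinary least squares
#'
#' @param y numeric log-abundance vector (one value per sample in `meta`).
#' @param meta sample metadata.
#' @param model model name (`FM`, `R1`..`R7`) or term vector.
#' @param z per-sample bias statistic (if the model needs it).
#' @param drop_cells optional excluded design cells.
#' @return list of class `transcript_fit`: coefficients, `rss`, `n`,
#'   `rank`, `df_residual`, maximised Gaussian `loglik`, `terms`, `model`.
#' @export
fit_transcript_model <- function(y, meta, model = "FM", z = NULL,
                                 drop_cells = NULL) {
  design <- build_design(meta, model, z, drop_cells)
  Y <- matrix(y[design$keep], nrow = 1,
              dimnames = list("y", meta$sample_id[design$keep]))
  fit <- fit_design(Y, design)
  out <- list(model = fit$model, terms = fit$terms,
              coefficients = drop(fit$coefficients),
              rss = unname(fit$rss), n = fit$n, rank = fit$rank,
              df_residual = fit$df_residual, loglik = unname(fit$loglik))
  class(out) <- "transcript_fit"
  out
}

#' Likelihood-ratio test of two nested transcript fits
#'
#' `Lambda = 2 (loglik_full - loglik_reduced) = n log(RSS_r / RSS_f)`.
#' The primary p-value comes from the exact finite-sample null
#' distribution of the monotone-equivalent F statistic (Gaussian errors);
#' the chi-square asymptotic p-value is reported as `p_chisq`.
#'
#' @param full,reduced [fit_transcript_model()] results; the reduced
#'   model's terms must be a strict subset of the full model's, fitted on
#'   the same samples.
#' @return list: `stat` (Lambda), `df`, `p`, `p_chisq`, `f`, `df2`.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$terms %in% full$terms))
    stop_msg("models are not nested (%s vs %s)", full$model, reduced$model)
  if (full$n != reduced$n)
    stop_msg("fits use different sample sets (n = %d vs %d)", full$n, reduced$n)
  lrt_from_rss(full$rss, reduced$rss, full$n, full$rank, reduced$rank)
}

lrt_from_rss <- function(rss_f, rss_r, n, rank_f, rank_r) {
  stat <- n * log(pmax(rss_r, .Machine$double.xmin) /
                    pmax(rss_f, .Machine$double.xmin))
  stat <- pmax(stat, 0)                       # guard tiny negative roundoff
  df <- rank_f - rank_r
  df2 <- n - rank_f
  if (df <= 0) {
    # identical parameterisations: Lambda = 0, p = 1
    return(list(stat = stat, df = 0L, p = rep(1, length(stat)),
                p_chisq = rep(1, length(stat)), f = rep(0, length(stat)),
                df2 = df2))
  }
  f <- ((rss_r - rss_f) / df) / (rss_f / df2)
  f <- pmax(f, 0)
  p <- stats::pf(f, df, df2, lower.tail = FALSE)
  p_chisq <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p, p_chisq = p_chisq, f = f, df2 = df2)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment applied separately per comparison family by the
#' callers.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values (monotone in p, `q >= p`).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Run the full nested-model analysis over an abundance matrix
#'
#' Fits the eight models to every retained transcript and performs the
#' seven nested comparisons (interaction, morph and time with the bias
#' polynomial; the bias term itself; and the three bias-free analogues),
#' adjusting p-values per comparison family.
#'
#' @param abundance transcripts x samples TPM matrix.
#' @param counts matching estimated-count matrix (for the low-count
#'   filter); pass `NULL` to skip filtering.
#' @param meta sample metadata (`sample_id`, `morph`, `tau`).
#' @param bias a [sample_bias_table()] result (or any data.frame with
#'   `sample_id`, `z`).  Required unless `families = "nobias"`.
#' @param min_total low-count filter threshold (strictly-greater rule).
#' @param drop_cells optional data.frame of design cells excluded before
#'   fitting (e.g. a known heavily degraded timepoint).
#' @param families which comparison families to run: `"bias"`,
#'   `"nobias"` or both (default).
#' @param pseudocount log-transform pseudocount.
#' @return Object of class `detest_result`: `tests` (long per-transcript
#'   per-comparison table with `stat`, `df`, `p`, `p_chisq`, `q`),
#'   `wide` (one row per transcript: `q_MxT`, `q_Morph`, `q_Time`,
#'   `q_Tprime`, the no-bias analogues, and pairwise morph log
#'   fold-changes from the FM coefficients), `fm_coefficients`,
#'   `retained`, `n_samples`, `meta`, `z`.
#' @export
run_detest <- function(abundance, counts, meta, bias = NULL,
                       min_total = 200, drop_cells = NULL,
                       families = c("bias", "nobias"),
                       pseudocount = 0.5) {
  families <- match.arg(families, several.ok = TRUE)
  retained <- if (is.null(counts)) rownames(abundance)
  else filter_low_counts(counts, min_total)
  if (length(retained) == 0) stop_msg("no transcript passes the low-count filter")
  if (!all(meta$sample_id %in% colnames(abundance)))
    stop_msg("abundance lacks columns for some samples in meta")
  A <- abundance[retained, meta$sample_id, drop = FALSE]
  Y <- log(A + pseudocount)

  z <- NULL
  if ("bias" %in% families) {
    if (is.null(bias)) stop_msg("bias table required for the with-bias family")
    bz <- as.data.frame(bias)
    if (!all(meta$sample_id %in% bz$sample_id))
      stop_msg("bias table lacks z for some samples")
    z <- bz$z[match(meta$sample_id, bz$sample_id)]
  }

  comps <- COMPARISONS[COMPARISONS$family %in% families, , drop = FALSE]
  models <- unique(c(comps$full, comps$reduced))
  designs <- lapply(models, function(m) build_design(meta, m, z, drop_cells))
  names(designs) <- models
  keep <- designs[[1]]$keep
  Yk <- Y[, keep, drop = FALSE]
  fits <- lapply(designs, function(d) fit_design(Yk, d))

  tests <- do.call(rbind, lapply(seq_len(nrow(comps)), function(i) {
    fu <- fits[[comps$full[i]]]; re <- fits[[comps$reduced[i]]]
    lr <- lrt_from_rss(fu$rss, re$rss, fu$n, fu$rank, re$rank)
    data.frame(transcript_id = retained, comparison = comps$comparison[i],
               effect = comps$effect[i], family = comps$family[i],
               stat = lr$stat, df = lr$df, p = lr$p, p_chisq = lr$p_chisq,
               stringsAsFactors = FALSE)
  }))
  tests$q <- stats::ave(tests$p, tests$comparison, FUN = fdr_adjust)

  wide <- data.frame(transcript_id = retained, stringsAsFactors = FALSE)
  qcol <- c(FMvR1 = "q_MxT", R1vR2 = "q_Morph", R1vR3 = "q_Time",
            FMvR4 = "q_Tprime", R4vR5 = "q_MxT_nobias",
            R5vR6 = "q_Morph_nobias", R5vR7 = "q_Time_nobias")
  for (cmp in comps$comparison) {
    sub <- tests[tests$comparison == cmp, ]
    wide[[qcol[[cmp]]]] <- sub$q[match(retained, sub$transcript_id)]
  }

  fm_coef <- NULL
  if ("FM" %in% names(fits)) {
    fm_coef <- fits$FM$coefficients
    morphs <- unique(meta$morph)
    cf <- function(m) {
      cn <- paste0("morph_", m)
      if (cn %in% colnames(fm_coef)) fm_coef[, cn] else numeric(nrow(fm_coef))
    }
    pairs <- utils::combn(morphs, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      wide[[paste0("FC_", b, "_", a)]] <- cf(b) - cf(a)
    }
  }

  structure(list(tests = tests, wide = wide, fm_coefficients = fm_coef,
                 retained = retained, n_samples = fits[[1]]$n,
                 meta = meta[keep, , drop = FALSE],
                 z = if (!is.null(z)) z[keep] else NULL,
                 drop_cells = drop_cells, families = families),
            class = "detest_result")
}

#' @export
print.detest_result <- function(x, ...) {
  cat(sprintf("detest_result: %d transcripts, %d samples, families: %s\n",
              length(x$retained), x$n_samples,
              paste(x$families, collapse = ", ")))
  invisible(x)
}

#' Classify transcripts by significant effects
#'
#' Tabulates, per family and fdr threshold, the number of transcripts
#' significant for each effect (a Table-4-style summary), the upset-style
#' intersection counts over the with-bias effects, and the
#' cluster-eligibility flag (morph or interaction significant at
#' fdr < 0.01).
#'
#' @param result a [run_detest()] result.
#' @param thresholds fdr thresholds (default 0.05, 0.01, 0.001).
#' @param intersection_threshold threshold for the intersection table.
#' @return list: `counts` (family x threshold x effect), `intersections`
#'   (pattern counts over Bias/MxT/Morph/Time in the with-bias family),
#'   `flags` (per-transcript logical significance at
#'   `intersection_threshold`), `cluster_eligible` (transcript ids).
#' @export
classify_effects <- function(result, thresholds = c(0.05, 0.01, 0.001),
                             intersection_threshold = 0.01) {
  tests <- result$tests
  counts <- do.call(rbind, lapply(thresholds, function(th) {
    ag <- stats::aggregate(q ~ family + effect, data = tests,
                           FUN = function(q) sum(q < th))
    ag$fdr <- th
    ag
  }))
  names(counts)[names(counts) == "q"] <- "n_significant"

  wb <- tests[tests$family == "bias", ]
  flags <- NULL
  intersections <- NULL
  if (nrow(wb) > 0) {
    eff <- unique(wb$effect)
    flags <- data.frame(transcript_id = result$retained,
                        stringsAsFactors = FALSE)
    for (e in eff) {
      sub <- wb[wb$effect == e, ]
      flags[[e]] <- sub$q[match(result$retained, sub$transcript_id)] <
        intersection_threshold
    }
    pat <- apply(flags[, eff, drop = FALSE], 1, function(r)
      paste(eff[which(r)], collapse = "+"))
    pat[pat == ""] <- "(none)"
    intersections <- as.data.frame(table(pattern = pat),
                                   stringsAsFactors = FALSE)
    names(intersections)[2] <- "n"
  }

  eligible <- character(0)
  if (!is.null(flags) && all(c("Morph", "MxT") %in% names(flags))) {
    el <- flags$Morph | flags$MxT
    eligible <- flags$transcript_id[el]
  }
  list(counts = counts, intersections = intersections, flags = flags,
       cluster_eligible = eligible,
       thresholds = thresholds,
       intersection_threshold = intersection_threshold)
}

#' Cross-tabulate significance with vs without the bias polynomial
#'
#' For each design effect, cross-tabulates per-transcript significance
#' under the with-bias and bias-free model families and lists the
#' transcripts whose apparent morph-by-time interaction disappears (or
#' resolves into a time effect) once the bias polynomial is included.
#'
#' @param result a [run_detest()] run with both families.
#' @param threshold fdr threshold (default 0.01).
#' @return list: `crosstab` (per effect, 2x2 counts), `mxt_moved`
#'   (transcripts interaction-significant only without bias correction,
#'   with their with-bias status), `fp_rate` helper columns are left to
#'   the caller.
#' @export
bias_impact_report <- function(result, threshold = 0.01) {
  if (!all(c("bias", "nobias") %in% result$families))
    stop_msg("bias_impact_report needs both model families")
  w <- result$wide
  crosstab <- lapply(c("MxT", "Morph", "Time"), function(e) {
    a <- w[[paste0("q_", e)]] < threshold
    b <- w[[paste0("q_", e, "_nobias")]] < threshold
    table(with_bias = a, without_bias = b)
  })
  names(crosstab) <- c("MxT", "Morph", "Time")
  moved_idx <- which(w$q_MxT_nobias < threshold & !(w$q_MxT < threshold))
  mxt_moved <- data.frame(
    transcript_id = w$transcript_id[moved_idx],
    with_bias_time_significant = w$q_Time[moved_idx] < threshold,
    stringsAsFactors = FALSE)
  list(crosstab = crosstab, mxt_moved = mxt_moved, threshold = threshold)
}

#' Confusion of planted effect classes against detected significance
#'
#' Predicts a coarse effect label per transcript from the with-bias
#' q-values (interaction if the interaction term is significant, else
#' morph, else time, else null) and tabulates it against the generator's
#' planted classes.
#'
#' @param truth generator truth table.
#' @param result a [run_detest()] result.
#' @param threshold fdr threshold (default 0.01).
#' @return contingency table (planted class x predicted label).
#' @export
effect_confusion <- function(truth, result, threshold = 0.01) {
  w <- result$wide
  pred <- ifelse(w$q_MxT < threshold, "interaction",
                 ifelse(w$q_Morph < threshold, "morph",
                        ifelse(w$q_Time < threshold, "time_only", "null")))
  tt <- truth$effect_class[match(w$transcript_id, truth$transcript_id)]
  table(planted = tt, predicted = pred)
}
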