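# qPCR relative quantification and group comparisons.
#
# Target Ct values are normalised against the mean Ct of two reference
# genes (equivalent to the geometric mean on the linear expression scale),
# expressed relative to a calibrator sample (2^-ddCt, amplification
# efficiency fixed at 2), and compared across morphs and timepoints by
# two-way ANOVA on dCt with Tukey post-hoc tests.

#' Validate and normalise a Ct table
#'
#' @param df data.frame with columns `sample_id`, `morph`, `tau`, `gene`,
#'   `ct`; technical replicates (repeated sample x gene rows) are averaged.
#' @param ref_genes the two (or more) reference genes (default `actb`,
#'   `ub2l3`).
#' @param calibrator sample id of the calibrator.
#' @return list of class `ct_table`: `data` (one row per sample x gene),
#'   `ref_genes`, `calibrator`.
#' @export
ct_table <- function(df, ref_genes = c("actb", "ub2l3"), calibrator) {
  need <- c("sample_id", "morph", "tau", "gene", "ct")
  if (!all(need %in% names(df)))
    stop_msg("Ct table must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0) || any(df$ct >= 45))
    stop_msg("Ct values must be finite and in (0, 45)")
  agg <- stats::aggregate(ct ~ sample_id + morph + tau + gene, data = df,
                          FUN = mean)
  have_refs <- tapply(agg$gene, agg$sample_id,
                      function(g) all(ref_genes %in% g))
  if (!all(have_refs))
    stop_msg("sample(s) missing reference-gene Ct: %s",
             paste(names(have_refs)[!have_refs], collapse = ", "))
  if (!calibrator %in% agg$sample_id)
    stop_msg("calibrator sample '%s' absent from the Ct table", calibrator)
  structure(list(data = agg, ref_genes = ref_genes, calibrator = calibrator),
            class = "ct_table")
}

#' Reference-normalised dCt values
#'
#' `dCt = Ct_target - mean(Ct_reference)` per sample; the arithmetic mean
#' of reference Cts corresponds to the geometric mean of reference
#' expression on the `2^-Ct` scale.  Reference genes themselves are not
#' returned as targets.
#'
#' @param ct a [ct_table()].
#' @return data.frame: `sample_id`, `morph`, `tau`, `gene`, `dct`.
#' @export
delta_ct <- function(ct) {
  d <- ct$data
  refs <- d[d$gene %in% ct$ref_genes, , drop = FALSE]
  ref_mean <- tapply(refs$ct, refs$sample_id, mean)
  targets <- d[!d$gene %in% ct$ref_genes, , drop = FALSE]
  if (nrow(targets) == 0) stop_msg("no target genes in the Ct table")
  targets$dct <- targets$ct - as.numeric(ref_mean[targets$sample_id])
  targets[, c("sample_id", "morph", "tau", "gene", "dct")]
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = dCt - dCt(calibrator)` per gene; relative expression is
#' `2^-ddCt`, so the calibrator sample has relative expression exactly 1
#' for every gene.
#'
#' @param dct a [delta_ct()] table.
#' @param calibrator calibrator sample id.
#' @return `dct` with columns `ddct` and `rel_expr` appended.
#' @export
rel_expression <- function(dct, calibrator) {
  cal <- dct[dct$sample_id == calibrator, , drop = FALSE]
  if (nrow(cal) == 0) stop_msg("calibrator sample '%s' has no target dCt", calibrator)
  cal_dct <- stats::setNames(cal$dct, cal$gene)
  missing <- setdiff(unique(dct$gene), names(cal_dct))
  if (length(missing) > 0)
    stop_msg("calibrator lacks Ct for gene(s): %s", paste(missing, collapse = ", "))
  dct$ddct <- dct$dct - as.numeric(cal_dct[dct$gene])
  dct$rel_expr <- 2^(-dct$ddct)
  dct
}

#' Two-way ANOVA of dCt on morph and timepoint
#'
#' Ordinary-least-squares ANOVA (`dct ~ morph * tau`, factors), reporting
#' per-term sums of squares, F and p, plus a Shapiro-Wilk residual
#' normality check (reported, not gating).
#'
#' @param dct [delta_ct()] rows for one gene.
#' @return list of class `qpcr_anova`: `table` (term, df, ss, ms, f, p),
#'   `shapiro_w`, `shapiro_p`, `fit`.
#' @export
anova_two_way <- function(dct) {
  if (length(unique(dct$gene)) != 1)
    stop_msg("anova_two_way expects dCt rows for exactly one gene")
  d <- data.frame(dct = dct$dct, morph = factor(dct$morph),
                  tau = factor(dct$tau))
  fit <- stats::aov(dct ~ morph * tau, data = d)
  an <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(an)), df = an$Df,
                    ss = an$`Sum Sq`, ms = an$`Mean Sq`,
                    f = an$`F value`, p = an$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  if (stats::sd(d$dct) < .Machine$double.eps^0.5) {
    # constant response: zero sums of squares, F ratios undefined
    tab$ss <- tab$ms <- 0
    tab$f <- tab$p <- NA_real_
  }
  res <- stats::residuals(fit)
  sw <- if (length(unique(round(res, 12))) > 2 && length(res) >= 3 &&
            stats::sd(res) > 0) stats::shapiro.test(res)
  else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(table = tab, shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value, fit = fit),
            class = "qpcr_anova")
}

#' Tukey honest-significant-difference comparisons among morphs
#'
#' Studentized-range-based pairwise comparisons of morph means of dCt.
#'
#' @param dct [delta_ct()] rows for one gene.
#' @return data.frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(dct) {
  if (length(unique(dct$gene)) != 1)
    stop_msg("tukey_posthoc expects dCt rows for exactly one gene")
  d <- data.frame(dct = dct$dct, morph = factor(dct$morph))
  if (nlevels(d$morph) < 2) stop_msg("need >= 2 morphs for Tukey comparisons")
  hsd <- stats::TukeyHSD(stats::aov(dct ~ morph, data = d))$morph
  data.frame(contrast = rownames(hsd), diff = hsd[, "diff"],
             lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}
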