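# Nested linear models, likelihood-ratio tests and FDR machinery.

test_that("the low-count filter uses the strictly-greater rule", {
  counts <- rbind(a = c(100, 100), b = c(150, 51), c = c(0, 0), d = c(100, 99))
  expect_setequal(filter_low_counts(counts, 200), c("b"))
  # exactly 200 estimated reads is dropped
  expect_false("a" %in% filter_low_counts(counts, 200))
})

test_that("noiseless data generated from the full model is recovered exactly", {
  meta <- simulate_degradation(simulate_design(), degradation_model(), seed = 1)
  des <- build_design(meta, "FM", z = meta$z_true)
  set.seed(2)
  beta <- rnorm(ncol(des$X), 0, 1)
  y <- as.vector(des$X %*% beta)
  fit <- fit_transcript_model(y, meta, "FM", z = meta$z_true)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
})

test_that("matrix fits agree with a direct normal-equations solver", {
  meta <- simulate_degradation(simulate_design(), degradation_model(), seed = 3)
  set.seed(4)
  Y <- matrix(rnorm(20 * 48), 20, 48,
              dimnames = list(sprintf("t%02d", 1:20), meta$sample_id))
  for (model in c("FM", "R1", "R5", "R7")) {
    des <- build_design(meta, model, z = meta$z_true)
    fit <- morphde:::fit_design(Y, des)
    X <- des$X
    beta_o <- solve(t(X) %*% X, t(X) %*% t(Y))
    rss_o <- colSums((t(Y) - X %*% beta_o)^2)
    expect_equal(unname(fit$rss), unname(rss_o), tolerance = 1e-8)
  }
})

test_that("likelihood-ratio tests follow the closed-form Gaussian formula", {
  # two groups x 4 observations, hand-computable RSS ratio
  meta <- data.frame(sample_id = sprintf("s%d", 1:8),
                     morph = rep(c("A", "B"), each = 4),
                     tau = rep(1, 8))
  y <- c(1, 2, 3, 4, 10, 11, 12, 13)
  full <- fit_transcript_model(y, meta, "morph")
  red <- fit_transcript_model(y, meta, character(0))   # intercept only
  lr <- lrt(full, red)
  rss_f <- sum((y - ave(y, meta$morph))^2)
  rss_r <- sum((y - mean(y))^2)
  expect_equal(lr$stat, 8 * log(rss_r / rss_f), tolerance = 1e-10)
  expect_equal(lr$df, 1)
  # the exact p equals the classical F/t test for this comparison
  tt <- t.test(y ~ meta$morph, var.equal = TRUE)
  expect_equal(lr$p, tt$p.value, tolerance = 1e-10)
  # identical models: Lambda = 0, p = 1
  same <- lrt(full, full)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  # non-nested pairs are rejected
  meta2 <- meta
  meta2$tau <- rep(c(1, 2), 4)
  f_time <- fit_transcript_model(y, meta2, "time")
  f_morph <- fit_transcript_model(y, meta2, "morph")
  expect_error(lrt(f_time, f_morph), "not nested")
})

test_that("LRT statistics are invariant to affine transformation of the response", {
  meta <- simulate_degradation(simulate_design(), degradation_model(), seed = 5)
  set.seed(6)
  y <- rnorm(48)
  f1 <- fit_transcript_model(y, meta, "R1", z = meta$z_true)
  f2 <- fit_transcript_model(y, meta, "R2", z = meta$z_true)
  a <- lrt(f1, f2)
  y2 <- 3.7 * y - 11
  g1 <- fit_transcript_model(y2, meta, "R1", z = meta$z_true)
  g2 <- fit_transcript_model(y2, meta, "R2", z = meta$z_true)
  b <- lrt(g1, g2)
  expect_equal(a$stat, b$stat, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("a single-level factor collapses to the intercept and blocks nesting", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     morph = rep(c("A", "B"), 3), tau = rep(5, 6))
  y <- rnorm(6)
  f_r6 <- fit_transcript_model(y, meta, "R6")   # time only, 1 level
  expect_equal(f_r6$rank, 1)                     # intercept-only equivalent
  f_r7 <- fit_transcript_model(y, meta, "R7")
  expect_error(lrt(f_r6, f_r7), "not nested")
})

test_that("Benjamini-Hochberg adjustment matches a brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.037), 0.037)
  set.seed(7)
  for (i in 1:5) {
    p <- runif(40)^2
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # q monotone in p and q >= p
  p <- runif(100)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("constant z makes the bias polynomial inert", {
  an <- default_analysis()
  sim <- an$sim
  sub <- an$detest$retained[1:40]
  bias_const <- data.frame(sample_id = sim$sample_meta$sample_id, z = 0.6)
  det <- run_detest(sim$abundance[sub, ], NULL, sim$sample_meta,
                    bias = bias_const)
  # with-bias and bias-free families coincide
  expect_equal(det$wide$q_MxT, det$wide$q_MxT_nobias, tolerance = 1e-10)
  expect_equal(det$wide$q_Morph, det$wide$q_Morph_nobias, tolerance = 1e-10)
  expect_true(all(det$wide$q_Tprime == 1))
})

test_that("run_detest produces coherent per-comparison tables and fold changes", {
  an <- default_analysis()
  det <- an$detest
  expect_setequal(unique(det$tests$comparison),
                  c("FMvR1", "R1vR2", "R1vR3", "FMvR4",
                    "R4vR5", "R5vR6", "R5vR7"))
  expect_true(all(det$tests$stat >= -1e-8))
  expect_true(all(det$tests$p >= 0 & det$tests$p <= 1))
  expect_true(all(det$tests$q >= det$tests$p - 1e-12))
  expect_true(all(c("q_MxT", "q_Morph", "q_Time", "q_Tprime",
                    "q_MxT_nobias", "FC_LB_SB", "FC_PL_SB", "FC_PL_LB")
                  %in% names(det$wide)))
  # fold-change consistency: FC_PL_LB = FC_PL_SB - FC_LB_SB
  expect_equal(det$wide$FC_PL_LB,
               det$wide$FC_PL_SB - det$wide$FC_LB_SB, tolerance = 1e-10)
  # missing bias table with the with-bias family requested
  expect_error(run_detest(an$sim$abundance, an$sim$counts,
                          an$sim$sample_meta, bias = NULL),
               "bias table required")
})

test_that("effect classification flags are threshold-monotone and partition", {
  an <- default_analysis()
  cl <- classify_effects(an$detest)
  counts <- cl$counts
  for (eff in unique(counts$effect)) for (fam in unique(counts$family)) {
    sub <- counts[counts$effect == eff & counts$family == fam, ]
    sub <- sub[order(sub$fdr), ]
    expect_true(all(diff(sub$n_significant) >= 0))   # monotone in threshold
  }
  # intersection counts sum to the number of transcripts significant anywhere
  flags <- cl$flags
  anysig <- rowSums(as.matrix(flags[, c("Bias", "MxT", "Morph", "Time")])) > 0
  inter <- cl$intersections
  expect_equal(sum(inter$n[inter$pattern != "(none)"]), sum(anysig))
  expect_equal(sum(inter$n), nrow(flags))
  # cluster eligibility definition
  expect_setequal(cl$cluster_eligible,
                  flags$transcript_id[flags$Morph | flags$MxT])
})

test_that("planted effects are recovered and misattribution is repaired", {
  an <- default_analysis()
  w <- an$detest$wide
  tr <- an$truth
  # morph effects of 1.0 log-units at sigma 0.3: near-complete power
  expect_gte(mean(w$q_Morph[tr$effect_class == "morph"] < 0.01), 0.9)
  # no-interaction transcripts: inflated false positives without the bias term
  nomt <- tr$effect_class != "interaction"
  fpr_with <- mean(w$q_MxT[nomt] < 0.01)
  fpr_without <- mean(w$q_MxT_nobias[nomt] < 0.01)
  expect_gte(fpr_without, 3 * fpr_with)
  rep <- bias_impact_report(an$detest)
  expect_named(rep$crosstab, c("MxT", "Morph", "Time"))
  moved_ids <- rep$mxt_moved$transcript_id
  bo_ids <- tr$transcript_id[tr$effect_class == "bias_only"]
  expect_gte(length(intersect(moved_ids, bo_ids)) / length(bo_ids), 0.8)
  conf <- effect_confusion(an$sim$truth, an$detest)
  expect_true(all(c("morph", "interaction") %in% rownames(conf)))
})
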