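# Synthetic-data generator: design, degradation, expression, determinism.

test_that("design enumeration matches the factorial layout", {
  expect_equal(nrow(simulate_design()), 48)
  d <- study_design(morphs = c("A", "B"),
                    timepoints = list(A = c(1, 2), B = c(1, 2)),
                    replicates = 3)
  m <- simulate_design(d)
  expect_equal(nrow(m), 12)
  expect_equal(anyDuplicated(m$sample_id), 0)
  # invalid designs name the violated invariant
  expect_error(study_design(morphs = "A", timepoints = list(A = c(1, 2))),
               ">= 2 morphs")
  expect_error(study_design(morphs = c("A", "B"),
                            timepoints = list(A = 1, B = c(1, 2))),
               "< 2 timepoints")
  expect_error(study_design(morphs = c("A", "B"),
                            timepoints = list(A = c(2, 1), B = c(1, 2))),
               "strictly increasing")
  expect_error(study_design(replicates = 0), "replicates")
})

test_that("degradation confounds the designated cells and anticorrelates with RIN", {
  meta <- simulate_design()
  dm <- degradation_model()
  md <- simulate_degradation(meta, dm, seed = 4)
  expect_true(all(md$d >= 0 & md$d <= 1))
  expect_true(all(md$rin >= 1 & md$rin <= 10))
  expect_gt(mean(md$d[md$confounded_cell]), mean(md$d[!md$confounded_cell]))
  expect_lt(cor(md$rin, md$d), 0)
  expect_error(degradation_model(decay_rate = -1), "decay_rate")
  expect_error(
    simulate_degradation(meta, degradation_model(
      confounded_cells = data.frame(morph = "XX", tau = 5)), seed = 1),
    "not present")
})

test_that("without confounded cells degradation is independent of the design", {
  dm <- degradation_model(confounded_cells = NULL)
  ps <- vapply(1:60, function(s) {
    md <- simulate_degradation(simulate_design(), dm, seed = s)
    fit <- stats::lm(d ~ morph * factor(tau), data = md)
    stats::anova(fit)[["Pr(>F)"]][1:3]
  }, numeric(3))
  # p-values behave uniformly: empirical rejection near nominal level
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.12)
  expect_gt(suppressWarnings(stats::ks.test(as.vector(ps), "punif")$p.value),
            0.001)
})

test_that("coverage profiles follow the degradation mixture", {
  # d = 1 with a strong decay rate concentrates nearly all mass 3'-ward
  expect_equal(true_three_prime_mass(0, 8), 0.5)
  expect_gt(true_three_prime_mass(1, 10), 0.99)
  meta <- simulate_design(study_design(
    morphs = c("A", "B"), timepoints = list(A = c(1, 2), B = c(1, 2)),
    replicates = 1))
  truth <- simulate_truth(n_transcripts = 5, n_index_candidates = 20,
                          n_index_compliant = 5, seed = 1)
  meta$d <- c(0, 1, 0.5, 0.2)
  meta$z_true <- true_three_prime_mass(meta$d, 10)
  cov <- simulate_coverage_profiles(truth, meta,
                                    degradation_model(decay_rate = 10),
                                    seed = 3, cov_depth = 50)
  expect_true(all(cov >= 0))
  # d = 0 sample: profile uniform up to Poisson noise
  p0 <- colSums(cov[, 1, , drop = FALSE][, 1, ])
  frac0 <- sum(cov[1, 1, 51:100]) / sum(cov[1, 1, ])
  expect_lt(abs(frac0 - 0.5), 0.05)
  # d = 1 sample: >= 99% of mass in the 3' half
  frac1 <- sum(cov[, 2, 51:100]) / sum(cov[, 2, ])
  expect_gt(frac1, 0.99)
  # determinism
  cov2 <- simulate_coverage_profiles(truth, meta,
                                     degradation_model(decay_rate = 10),
                                     seed = 3, cov_depth = 50)
  expect_identical(cov, cov2)
})

test_that("expression matrix realises the generative linear model", {
  design <- study_design()
  meta <- simulate_degradation(simulate_design(design),
                               degradation_model(), seed = 9)
  # all effects zero, sigma = 0 -> each transcript constant across samples
  truth0 <- simulate_truth(design, n_transcripts = 20, sigma = 0,
                           class_probs = c(null = 1, time_only = 0, morph = 0,
                                           interaction = 0, bias_only = 0,
                                           mixed = 0),
                           frac_low = 0, n_index_candidates = 0, seed = 2)
  e0 <- simulate_expression_matrix(truth0, meta, seed = 3)
  expect_equal(max(apply(log(e0$abundance + 0.5), 1, stats::sd)), 0)
  expect_equal(unname(log(e0$abundance + 0.5)[, 1]), truth0$baseline)

  # with noise, per-transcript sample means track the generative means
  truth <- simulate_truth(design, n_transcripts = 200, frac_low = 0,
                          n_index_candidates = 0, seed = 5)
  e <- simulate_expression_matrix(truth, meta, seed = 6)
  mu <- morphde:::expression_mean_matrix(truth, meta)
  # restrict to transcripts the TPM >= 0 floor cannot censor
  ok <- apply(mu, 1, min) > 0
  expect_gt(sum(ok), 100)
  dev <- rowMeans(log(e$abundance + 0.5))[ok] - rowMeans(mu)[ok]
  # each mean of 48 draws has sd sigma/sqrt(48); allow 4.5 sd
  expect_true(all(abs(dev) < 4.5 * 0.3 / sqrt(48)))
  expect_error(simulate_expression_matrix(truth, simulate_design(design)),
               "z_true")
})

test_that("OLS refit of the full model recovers generator coefficients without bias", {
  design <- study_design()
  # unconfounded degradation spread over the full range keeps the bias
  # polynomial well conditioned, so coefficient sampling noise stays small
  meta <- simulate_degradation(
    simulate_design(design),
    degradation_model(confounded_cells = NULL,
                      d_base_range = c(0.05, 0.9)), seed = 11)
  truth <- simulate_truth(design, n_transcripts = 500,
                          class_probs = c(null = 1, time_only = 0, morph = 0,
                                          interaction = 0, bias_only = 0,
                                          mixed = 0),
                          frac_low = 0, n_index_candidates = 0, seed = 12)
  e <- simulate_expression_matrix(truth, meta, seed = 13)
  Y <- log(e$abundance + 0.5)
  des <- build_design(meta, "FM", z = meta$z_true)
  fit <- morphde:::fit_design(Y[, meta$sample_id], des)
  # null transcripts: every coefficient unbiased around zero; raw bias for
  # the well-conditioned design coefficients, standardised bias for the
  # high-variance polynomial terms
  est <- fit$coefficients[, setdiff(colnames(fit$coefficients), "(Intercept)")]
  m <- colMeans(est)
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  dsg <- setdiff(colnames(est), c("z1", "z2"))
  expect_lt(max(abs(m[dsg])), 0.05)
  expect_lt(max(abs(m / se)), 4)
})

test_that("the generator is deterministic and internally consistent", {
  s1 <- simulate_dataset(seed = 77, n_transcripts = 150,
                         n_index_candidates = 40, n_index_compliant = 10)
  s2 <- simulate_dataset(seed = 77, n_transcripts = 150,
                         n_index_candidates = 40, n_index_compliant = 10)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$coverage, s2$coverage)
  expect_identical(s1$sample_meta, s2$sample_meta)
  expect_false(any(s1$abundance < 0))
  expect_setequal(colnames(s1$abundance), s1$sample_meta$sample_id)
  s3 <- simulate_dataset(seed = 78, n_transcripts = 150,
                         n_index_candidates = 40, n_index_compliant = 10)
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("planted low-count transcripts are exactly the ones the filter drops", {
  an <- default_analysis()
  sim <- an$sim
  expect_setequal(an$detest$retained,
                  sim$truth$transcript_id[!sim$truth$low_expressed])
})

test_that("coverage long-format round-trips through TSV and the array form", {
  sim <- simulate_dataset(seed = 5, n_transcripts = 30,
                          n_index_candidates = 12, n_index_compliant = 4)
  sub <- dimnames(sim$coverage)[[1]][1:3]
  long <- coverage_to_long(sim$coverage, sub)
  back <- coverage_from_long(long)
  expect_equal(back[sub, dimnames(sim$coverage)[[2]], ],
               sim$coverage[sub, , ])
  tmp <- withr::local_tempdir()
  write_dataset(sim, tmp, coverage_transcripts = sub)
  expect_true(all(file.exists(file.path(
    tmp, c("abundance.tsv", "counts.tsv", "sample_meta.tsv",
           "truth.tsv", "coverage.tsv")))))
  ab <- morphde:::read_matrix_tsv(file.path(tmp, "abundance.tsv"))
  expect_equal(dim(ab), dim(sim$abundance))
})
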