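# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the default 48-sample study at the frozen analysis seed, with the full
# bias -> nested-model chain already run
default_analysis <- function() {
  memo("default_analysis", {
    sim <- simulate_dataset(seed = 101)
    info <- sim$truth[sim$truth$index_candidate,
                      c("transcript_id", "length_bp", "full_length")]
    idx <- select_index_transcripts(sim$coverage, info)
    bias <- sample_bias_table(sim$coverage, idx)
    det <- run_detest(sim$abundance, sim$counts, sim$sample_meta, bias)
    truth <- sim$truth[match(det$retained, sim$truth$transcript_id), ]
    list(sim = sim, index = idx, bias = bias, detest = det, truth = truth)
  })
}

# 5,000 null transcripts (no effects of any kind), default design
null_analysis <- function() {
  memo("null_analysis", {
    sim <- simulate_dataset(
      seed = 202, n_transcripts = 5000,
      class_probs = c(null = 1, time_only = 0, morph = 0, interaction = 0,
                      bias_only = 0, mixed = 0),
      frac_low = 0, n_index_candidates = 0)
    bias <- data.frame(sample_id = sim$sample_meta$sample_id,
                       z = sim$sample_meta$z_true)
    det <- run_detest(sim$abundance, sim$counts, sim$sample_meta, bias)
    list(sim = sim, detest = det)
  })
}

# small two-morph design for cheap unit fixtures
mini_meta <- function(reps = 3) {
  d <- study_design(morphs = c("A", "B"),
                    timepoints = list(A = c(1, 2), B = c(1, 2)),
                    replicates = reps)
  simulate_design(d)
}

# chain ontology root -> n1 -> n2 -> ... -> n_depth
chain_dag <- function(depth) {
  edges <- data.frame(child = paste0("n", seq_len(depth)),
                      parent = c("root", paste0("n", seq_len(depth - 1))))
  ontology_dag(edges)
}

# brute-force O(m^2) Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ge <- which(p >= p[i])
    q[i] <- min(vapply(ge, function(j) {
      rank_j <- sum(p <= p[j])
      p[j] * m / rank_j
    }, numeric(1)))
    q[i] <- min(q[i], 1)
  }
  q
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# mean silhouette width on a 1-d score vector for a 2-group labelling
silhouette_1d <- function(x, group) {
  stopifnot(length(unique(group)) == 2)
  s <- vapply(seq_along(x), function(i) {
    same <- setdiff(which(group == group[i]), i)
    a <- if (length(same) > 0) mean(abs(x[i] - x[same])) else 0
    b <- mean(abs(x[i] - x[group != group[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
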