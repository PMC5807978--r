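# morphde

Degradation-bias-aware differential expression for factorial
developmental transcriptomes.

## The problem

Poly-A-selected RNA-seq libraries made from partially degraded RNA
over-represent reads near transcript 3' ends, and the strength of that 3'
bias varies sample by sample. In a factorial design — here, embryos of
three sympatric Arctic charr morphs (SB, LB, PL) sampled across
developmental timepoints in tau-somite units, with heavy degradation in
one timepoint of two morphs — the technical signal is *confounded with
the design*, and naive models misattribute it to the morph-by-time
interaction. `morphde` is for analysts who need to detect and correct
that misattribution rather than discard the affected samples.

The core of the package is a per-transcript family of nested Gaussian
linear models on `y = log(TPM + 0.5)`:

    FM: y = M_i + T_j + (MxT)_ij + b1 z_k + b2 z_k^2
    R1: drop MxT      R2: drop MxT, M      R3: drop MxT, T
    R4-R7: the same ladder without the bias polynomial

where `z_k` is the per-sample 3'-bias statistic — the fraction of
coverage in the 3' half of a set of long, high-coverage index
transcripts, averaged over the set. Nested pairs are compared with
likelihood-ratio tests (`Lambda = n log(RSS_r/RSS_f)`, p-values from the
exact finite-sample F form of the same statistic), with
Benjamini-Hochberg adjustment per comparison family. Around that core sit
temperature-based embryonic staging, fuzzy c-means co-expression
clustering (k = 16, m = 1.1) of bias-normalised profiles, PCA of
morph-type clusters, dual-level (length-aware transcript + hypergeometric
gene) ontology enrichment with DAG depth filtering and Wang-similarity
super-clustering, and 2^-ddCt qPCR quantification. A seeded
synthetic-data generator reproduces the statistical structure of such a
study — including the confounded degradation and ground-truth effect
classes — so the whole chain is testable without external data.

## Worked example

```r
library(morphde)

sim  <- simulate_dataset(seed = 1)          # 48-sample default study
info <- sim$truth[sim$truth$index_candidate,
                  c("transcript_id", "length_bp", "full_length")]
idx  <- select_index_transcripts(sim$coverage, info)
bias <- sample_bias_table(sim$coverage, idx)
rep  <- bias_rin_report(bias, sim$sample_meta)
cat(sprintf("index transcripts: %d; cor(z, RIN): r = %.2f (p = %.2g)\n",
            length(idx), rep$r, rep$p))

det  <- run_detest(sim$abundance, sim$counts, sim$sample_meta, bias)
summ <- summarize_detest(det)
print(subset(summ$counts, fdr == 0.01), row.names = FALSE)
```

```
index transcripts: 381; cor(z, RIN): r = -0.86 (p = 3.7e-15)
 family effect n_significant  fdr
   bias   Bias             2 0.01
   bias  Morph           345 0.01
   bias    MxT           116 0.01
   bias   Time           433 0.01
 nobias  Morph           341 0.01
 nobias    MxT           338 0.01
 nobias   Time           656 0.01
```

The selection finds the 381 engineered index transcripts, the bias
statistic anticorrelates with RIN as degraded samples should, and the
summary shows the central phenomenon: without the bias polynomial
(`nobias` rows) the morph-by-time interaction count is inflated roughly
threefold (338 vs 116 transcripts at fdr < 0.01) — those extra
"interactions" are degradation artefacts riding on the confounded cells —
while the overall morph effect is barely changed (341 vs 345). The
inflated `nobias` Time count includes bias-driven transcripts that the
corrected family attributes properly.

The whole chain, including clustering, PCA and enrichment, runs as one
call:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "morphde_out"))
```

which writes TSV artifacts (bias table, per-transcript results, cluster
memberships and centroids, PCA scores, enrichment tables, effect-count
summaries) plus a `manifest.json` recording the seed and configuration
hash; reruns with the same configuration are byte-identical. A thin CLI
wrapper with `simulate` / `stage` / `bias` / `detest` / `qpcr` / `run` /
`report` subcommands is installed at `inst/cli/morphde-cli.R`.

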