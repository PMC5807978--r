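# Synthetic ontology generator: a single-rooted is_a DAG with planted
# enriched categories, gene annotations and the transcript-gene map, used
# to exercise the dual-level enrichment stage with known ground truth.

gene_classes <- function(truth) {
  pr <- c("interaction", "morph", "mixed", "time_only", "bias_only", "null")
  cls <- factor(truth$effect_class, levels = pr)
  ag <- tapply(as.integer(cls), truth$gene_id, min)
  stats::setNames(pr[ag], names(ag))
}

#' Simulate an annotated ontology with planted enriched categories
#'
#' Builds a random acyclic single-rooted is_a DAG over `n_categories`
#' categories arranged in levels 1..`max_depth` (each category has one
#' parent in the level above and, with probability `extra_parent_prob`, a
#' second parent higher up, so longest and shortest paths to the root can
#' differ).  Genes are annotated directly to 1-3 random categories below
#' the top level.  For each row of `planted`, one depth-filter-eligible
#' category is (re)annotated with `size` genes drawn without replacement
#' with odds `odds_ratio` in favour of genes whose effect class matches
#' `effect_class`, planting a known enrichment signal.
#'
#' @param truth a [simulate_truth()] table (supplies gene ids, effect
#'   classes, transcript-gene map and transcript lengths); or `NULL`
#'   together with `n_genes` for a class-free ontology.
#' @param n_categories number of non-root categories.
#' @param n_genes number of genes when `truth` is `NULL`.
#' @param planted data.frame with columns `effect_class`, `odds_ratio`,
#'   `size`; zero rows plant nothing.
#' @param max_depth number of DAG levels below the root.
#' @param extra_parent_prob probability of a second is_a parent.
#' @param annotations_per_gene range (min, max) of direct annotations.
#' @param seed integer seed.
#' @return list of class `ontology_sim`: `dag` ([ontology_dag()]),
#'   `direct` (gene_id, category), `t2g`, `lengths` (named by
#'   transcript), `planted` (with the chosen `category` ids filled in),
#'   `gene_class`.
#' @export
simulate_ontology <- function(truth = NULL, n_categories = 60,
                              n_genes = 400,
                              planted = data.frame(effect_class = "morph",
                                                   odds_ratio = 8, size = 40,
                                                   stringsAsFactors = FALSE),
                              max_depth = 6, extra_parent_prob = 0.3,
                              annotations_per_gene = c(1, 3),
                              seed = 1L) {
  set.seed(seed)
  root <- "SC:0000000"
  ids <- sprintf("SC:%07d", seq_len(n_categories))
  # spread categories over levels, heavier in the mid-depth band
  lev_w <- pmin(seq_len(max_depth), 3)
  level <- sort(sample(seq_len(max_depth), n_categories, replace = TRUE,
                       prob = lev_w))
  # guarantee occupancy of every level from 1 up
  for (l in seq_len(max_depth)) if (!any(level == l)) level[which.max(level)] <- l
  level <- sort(level)
  edges <- list()
  for (i in seq_len(n_categories)) {
    l <- level[i]
    pool <- if (l == 1) root else ids[level == l - 1]
    p1 <- if (length(pool) == 1) pool else sample(pool, 1)
    edges[[length(edges) + 1]] <- data.frame(child = ids[i], parent = p1,
                                             stringsAsFactors = FALSE)
    if (l > 2 && stats::runif(1) < extra_parent_prob) {
      up <- ids[level == l - 2]
      if (length(up) > 0) {
        p2 <- if (length(up) == 1) up else sample(up, 1)
        edges[[length(edges) + 1]] <- data.frame(child = ids[i], parent = p2,
                                                 stringsAsFactors = FALSE)
      }
    }
  }
  dag <- ontology_dag(do.call(rbind, edges))

  if (!is.null(truth)) {
    t2g <- data.frame(transcript_id = truth$transcript_id,
                      gene_id = truth$gene_id, stringsAsFactors = FALSE)
    lengths <- stats::setNames(truth$length_bp, truth$transcript_id)
    gcls <- gene_classes(truth)
  } else {
    genes <- sprintf("G%05d", seq_len(n_genes))
    t2g <- data.frame(transcript_id = paste0("TR_", genes), gene_id = genes,
                      stringsAsFactors = FALSE)
    lengths <- stats::setNames(round(exp(stats::rnorm(n_genes, log(1800), 0.5))),
                               t2g$transcript_id)
    gcls <- stats::setNames(rep("null", n_genes), genes)
  }
  genes <- names(gcls)

  annotatable <- ids[level >= 2]
  n_ann <- sample(annotations_per_gene[1]:annotations_per_gene[2],
                  length(genes), replace = TRUE)
  direct <- data.frame(
    gene_id = rep(genes, n_ann),
    category = sample(annotatable, sum(n_ann), replace = TRUE),
    stringsAsFactors = FALSE)

  if (!is.null(planted) && nrow(planted) > 0) {
    eligible <- depth_filter(dag)
    if (nrow(planted) > length(eligible))
      stop_msg("cannot plant %d categories: only %d pass the depth filter",
               nrow(planted), length(eligible))
    # prefer categories with the fewest descendants so the planted gene set
    # is not diluted by annotations propagating up from below
    ndesc <- vapply(eligible, function(v) length(dag_descendants(dag, v)),
                    numeric(1))
    eligible <- eligible[order(ndesc, eligible)]
    planted$category <- eligible[seq_len(nrow(planted))]
    for (i in seq_len(nrow(planted))) {
      s <- min(planted$size[i], length(genes))
      or <- planted$odds_ratio[i]
      cls_genes <- genes[gcls == planted$effect_class[i]]
      oth_genes <- setdiff(genes, cls_genes)
      if (or == 1 || length(cls_genes) == 0) {
        pick <- sample(genes, s)
      } else {
        # category composition realising the requested odds ratio exactly:
        # odds(in category | class) = or * odds(in category | other)
        K <- length(cls_genes); N <- length(genes)
        a_grid <- seq(max(0, s - (N - K)), min(s, K))
        odds_c <- a_grid / pmax(K - a_grid, 0.5)
        odds_o <- (s - a_grid) / pmax(N - K - (s - a_grid), 0.5)
        a <- a_grid[which.min(abs(odds_c - or * pmax(odds_o, 1e-12)))]
        pick <- c(sample(cls_genes, a), sample(oth_genes, s - a))
      }
      direct <- direct[direct$category != planted$category[i], , drop = FALSE]
      direct <- rbind(direct,
                      data.frame(gene_id = pick,
                                 category = planted$category[i],
                                 stringsAsFactors = FALSE))
    }
  }
  direct <- unique(direct)
  structure(list(dag = dag, direct = direct, t2g = t2g, lengths = lengths,
                 planted = planted, gene_class = gcls),
            class = "ontology_sim")
}
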