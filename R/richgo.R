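# Ontology handling and dual-level category enrichment.
#
# Categories form a single-rooted acyclic is_a DAG.  Annotations are
# propagated to all ancestors; testing is restricted to categories at
# mid-depth (longest path to root >= 3 and shortest path to root <= 4),
# where annotation coverage is informative without being hopelessly
# generic.  Each transcript cluster is tested at two levels: a
# length-aware resampling test on transcripts and a hypergeometric test on
# genes; a category counts as significant only when fdr < 0.01 holds at
# both levels.  Significant categories are grouped into super-categories
# by Wang semantic similarity and complete-linkage clustering.

#' Construct an ontology DAG from an is_a edge list
#'
#' @param edges data.frame with columns `child`, `parent` (category ids).
#' @param names optional named character vector of category names.
#' @return Object of class `ontology_dag`: `nodes`, `edges`, `root`,
#'   `parents`/`children` adjacency lists, `term_names`.
#' @export
ontology_dag <- function(edges, names = NULL) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, factor(edges$child, levels = nodes))
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  roots <- nodes[lengths(parents) == 0]
  if (length(roots) != 1)
    stop_msg("ontology must have exactly one root, found %d (%s)",
             length(roots), paste(utils::head(roots, 5), collapse = ", "))
  dag <- structure(list(nodes = nodes, edges = edges, root = roots,
                        parents = parents, children = children,
                        term_names = names),
                   class = "ontology_dag")
  d <- dag_depths(dag)                       # errors on cycles
  unreachable <- nodes[is.na(d$shortest)]
  if (length(unreachable) > 0)
    stop_msg("categories not reaching the root: %s",
             paste(utils::head(unreachable, 5), collapse = ", "))
  dag
}

# topological order from root downward (parents before children)
topo_order <- function(dag) {
  indeg <- lengths(dag$parents)
  queue <- names(indeg)[indeg == 0]
  out <- character(0)
  indeg_left <- indeg
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in dag$children[[v]]) {
      indeg_left[ch] <- indeg_left[ch] - 1
      if (indeg_left[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(dag$nodes))
    stop_msg("ontology contains a cycle involving: %s",
             paste(utils::head(setdiff(dag$nodes, out), 5), collapse = ", "))
  out
}

#' Longest and shortest path lengths to the root
#'
#' Path lengths are counted in is_a steps from each category up to the
#' root; the root's distance to itself is 0.  Distinct paths from one
#' category may differ in length, hence the pair.
#'
#' @param dag an [ontology_dag()].
#' @return list of named vectors `longest`, `shortest`.
#' @export
dag_depths <- function(dag) {
  ord <- topo_order_cached(dag)
  longest <- shortest <- stats::setNames(rep(NA_real_, length(dag$nodes)),
                                         dag$nodes)
  longest[dag$root] <- shortest[dag$root] <- 0
  for (v in ord) {
    if (v == dag$root) next
    pl <- longest[dag$parents[[v]]]
    ps <- shortest[dag$parents[[v]]]
    longest[v] <- max(pl) + 1
    shortest[v] <- min(ps) + 1
  }
  list(longest = longest, shortest = shortest)
}

topo_order_cached <- function(dag) {
  # small graphs; recompute (kept as a seam for memoisation)
  topo_order(dag)
}

#' Mid-depth category filter
#'
#' Retains categories whose longest path to the root is at least
#' `min_longest` and whose shortest path to the root is at most
#' `max_shortest` (defaults 3 and 4).
#'
#' @param dag an [ontology_dag()].
#' @param min_longest,max_shortest bounds on the two path lengths.
#' @return character vector of retained category ids.
#' @export
depth_filter <- function(dag, min_longest = 3, max_shortest = 4) {
  d <- dag_depths(dag)
  dag$nodes[d$longest >= min_longest & d$shortest <= max_shortest]
}

#' Ancestor sets of every category
#' @param dag an [ontology_dag()].
#' @return named list: for each category, its ancestors including itself.
#' @export
dag_ancestors <- function(dag) {
  ord <- topo_order_cached(dag)
  anc <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in ord) {
    up <- unique(unlist(anc[dag$parents[[v]]], use.names = FALSE))
    anc[[v]] <- unique(c(v, dag$parents[[v]], up))
  }
  anc
}

dag_descendants <- function(dag, node) {
  out <- character(0)
  frontier <- dag$children[[node]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier], use.names = FALSE)),
                        out)
  }
  out
}

#' Propagate direct annotations to all ancestors
#'
#' A gene annotated to a category is annotated to every ancestor of that
#' category; the operation is idempotent.
#'
#' @param direct data.frame with columns `gene_id`, `category`.
#' @param dag an [ontology_dag()].
#' @return data.frame (`gene_id`, `category`) of the propagated map,
#'   without duplicates.
#' @export
propagate_ancestors <- function(direct, dag) {
  bad <- setdiff(direct$category, dag$nodes)
  if (length(bad) > 0)
    stop_msg("annotation references unknown categories: %s",
             paste(utils::head(bad, 5), collapse = ", "))
  anc <- dag_ancestors(dag)
  reps <- lengths(anc[direct$category])
  out <- data.frame(
    gene_id = rep(direct$gene_id, reps),
    category = unlist(anc[direct$category], use.names = FALSE),
    stringsAsFactors = FALSE)
  unique(out)
}

#' Read a minimal OBO-subset ontology
#'
#' Parses `[Term]` stanzas with `id:`, `name:` and `is_a:` lines (the only
#' fields the pipeline uses).
#'
#' @param path OBO file path.
#' @return an [ontology_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- which(lines == "[Term]")
  if (length(idx) == 0) stop_msg("no [Term] stanzas in %s", path)
  bounds <- c(idx, length(lines) + 1)
  edges <- list(); nm <- character(0)
  for (i in seq_along(idx)) {
    block <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    name <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    isa <- sub("^is_a: *", "", grep("^is_a:", block, value = TRUE))
    isa <- sub(" *!.*$", "", isa)
    if (!is.na(name)) nm[id] <- name
    if (length(isa) > 0)
      edges[[length(edges) + 1]] <- data.frame(child = id, parent = isa,
                                               stringsAsFactors = FALSE)
  }
  ontology_dag(do.call(rbind, edges), names = nm)
}

#' Write an ontology as a minimal OBO subset
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (v in dag$nodes) {
    writeLines(c("", "[Term]", paste0("id: ", v),
                 paste0("name: ", dag$term_names[v] %||% v)), con)
    for (p in dag$parents[[v]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Gene-level hypergeometric enrichment
#'
#' Upper-tail hypergeometric probability of the observed overlap or more
#' between the cluster gene set and each category gene set, without any
#' length correction.
#'
#' @param cluster_genes character vector of genes in the cluster.
#' @param category_genes named list of gene vectors per category.
#' @param universe character vector of all testable genes.
#' @return data.frame: `category`, `overlap`, `size`, `p`.
#' @export
gene_level_test <- function(cluster_genes, category_genes, universe) {
  cluster_genes <- intersect(unique(cluster_genes), universe)
  n_u <- length(universe)
  n_c <- length(cluster_genes)
  res <- lapply(names(category_genes), function(cat) {
    k <- intersect(unique(category_genes[[cat]]), universe)
    ov <- length(intersect(k, cluster_genes))
    p <- stats::phyper(ov - 1, length(k), n_u - length(k), n_c,
                       lower.tail = FALSE)
    data.frame(category = cat, overlap = ov, size = length(k), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Length-aware probability weighting function
#'
#' Isotonic (monotone non-decreasing) fit of the cluster-membership
#' fraction against transcript length over length deciles; each
#' transcript's sampling weight is the fitted value of its decile,
#' floored at a small positive value.
#'
#' @param is_de logical vector (transcript in cluster).
#' @param lengths transcript lengths (bp), aligned with `is_de`.
#' @param n_bins number of length bins (default 10).
#' @return numeric vector of weights; attribute `degenerate` is `TRUE`
#'   when all lengths are equal (uniform weights).
#' @export
make_pwf <- function(is_de, lengths, n_bins = 10) {
  if (length(unique(lengths)) == 1) {
    w <- rep(1, length(lengths))
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  br <- unique(stats::quantile(lengths, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(lengths, br, include.lowest = TRUE, labels = FALSE)
  frac <- tapply(as.numeric(is_de), bin, mean)
  iso <- stats::isoreg(sort(unique(bin)), frac)$yf
  w <- iso[match(bin, sort(unique(bin)))]
  w <- pmax(w, 1e-6)
  attr(w, "degenerate") <- FALSE
  w
}

#' Transcript-level length-aware enrichment by weighted resampling
#'
#' The null draws `|cluster|` transcripts from the universe without
#' replacement with probabilities proportional to the probability
#' weighting function of transcript length, and compares the observed
#' category overlap against the resampled overlaps:
#' `p = (1 + #(resampled overlap >= observed)) / (1 + n_resamples)`.
#' With degenerate (all-equal) lengths the weights are uniform and the
#' procedure reduces to a Monte-Carlo hypergeometric test (a note is
#' emitted).
#'
#' @param cluster_tx transcripts in the cluster.
#' @param category_tx named list of transcript vectors per category.
#' @param universe all testable transcript ids.
#' @param lengths named lengths (bp) for the universe.
#' @param n_resamples resampling depth (default 10,000).
#' @param seed integer seed.
#' @return data.frame: `category`, `overlap`, `size`, `p`.
#' @export
transcript_level_test <- function(cluster_tx, category_tx, universe, lengths,
                                  n_resamples = 10000, seed = 1L) {
  cluster_tx <- intersect(unique(cluster_tx), universe)
  lengths <- lengths[universe]
  if (anyNA(lengths)) stop_msg("lengths missing for some universe transcripts")
  is_de <- universe %in% cluster_tx
  w <- make_pwf(is_de, as.numeric(lengths))
  if (isTRUE(attr(w, "degenerate")))
    message("all transcript lengths equal; falling back to uniform-weight (hypergeometric) resampling")
  set.seed(seed)
  n_c <- length(cluster_tx)
  memb <- matrix(FALSE, length(category_tx), length(universe),
                 dimnames = list(names(category_tx), universe))
  for (cat in names(category_tx))
    memb[cat, intersect(unique(category_tx[[cat]]), universe)] <- TRUE
  observed <- as.vector(memb %*% is_de)
  exceed <- rep(0L, length(category_tx))
  if (n_c > 0) {
    block <- 500L
    done <- 0L
    while (done < n_resamples) {
      nb <- min(block, n_resamples - done)
      S <- matrix(0, length(universe), nb)
      for (b in seq_len(nb))
        S[sample.int(length(universe), n_c, prob = w), b] <- 1
      ov <- memb %*% S
      exceed <- exceed + rowSums(ov >= observed)
      done <- done + nb
    }
  }
  data.frame(category = names(category_tx),
             overlap = observed,
             size = rowSums(memb),
             p = (1 + exceed) / (1 + n_resamples),
             stringsAsFactors = FALSE)
}

#' Dual-level ontology enrichment for one transcript cluster
#'
#' Annotations are propagated to ancestors, categories are restricted to
#' the mid-depth band, and each retained category is tested at the
#' transcript level (length-aware resampling) and the gene level
#' (hypergeometric; a gene belongs to the cluster if any of its
#' transcripts does).  Benjamini-Hochberg adjustment is applied within
#' each level; a category is dual-significant when both adjusted values
#' fall below `fdr`.
#'
#' @param cluster_tx transcript ids in the cluster.
#' @param annotation list with `direct` (gene_id, category), `t2g`
#'   (transcript_id, gene_id) and `lengths` (named bp vector over the
#'   universe).
#' @param dag an [ontology_dag()].
#' @param universe transcript universe (default: all transcripts in
#'   `t2g` with annotated genes).
#' @param fdr dual-significance threshold (default 0.01).
#' @param min_longest,max_shortest depth-filter bounds.
#' @param n_resamples,seed transcript-level resampling controls.
#' @return data.frame of class `enrichment_result` with columns
#'   `category`, `term`, `numDE.t`, `numIn.t`, `p.t`, `fdr.t`, `numDE.g`,
#'   `numIn.g`, `p.g`, `fdr.g`, `dual_significant`.
#' @export
dual_enrichment <- function(cluster_tx, annotation, dag, universe = NULL,
                            fdr = 0.01, min_longest = 3, max_shortest = 4,
                            n_resamples = 10000, seed = 1L) {
  t2g <- annotation$t2g
  prop <- propagate_ancestors(annotation$direct, dag)
  keep_cats <- depth_filter(dag, min_longest, max_shortest)
  prop <- prop[prop$category %in% keep_cats, , drop = FALSE]
  if (nrow(prop) == 0) stop_msg("no annotation left after the depth filter")
  annotated_genes <- unique(prop$gene_id)
  if (is.null(universe))
    universe <- unique(t2g$transcript_id[t2g$gene_id %in% annotated_genes])
  cluster_tx <- intersect(cluster_tx, universe)

  cat_genes <- split(prop$gene_id, prop$category)
  g2t <- split(t2g$transcript_id, t2g$gene_id)
  cat_tx <- lapply(cat_genes, function(g)
    intersect(unique(unlist(g2t[g], use.names = FALSE)), universe))

  tl <- transcript_level_test(cluster_tx, cat_tx, universe,
                              annotation$lengths, n_resamples, seed)
  gene_univ <- intersect(unique(t2g$gene_id[t2g$transcript_id %in% universe]),
                         annotated_genes)
  cluster_genes <- unique(t2g$gene_id[t2g$transcript_id %in% cluster_tx])
  gl <- gene_level_test(cluster_genes, cat_genes, gene_univ)

  stopifnot(identical(tl$category, gl$category))
  out <- data.frame(
    category = tl$category,
    term = if (!is.null(dag$term_names)) unname(dag$term_names[tl$category])
    else tl$category,
    numDE.t = tl$overlap, numIn.t = tl$size,
    p.t = tl$p, fdr.t = fdr_adjust(tl$p),
    numDE.g = gl$overlap, numIn.g = gl$size,
    p.g = gl$p, fdr.g = fdr_adjust(gl$p),
    stringsAsFactors = FALSE)
  out$dual_significant <- out$fdr.t < fdr & out$fdr.g < fdr
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Wang semantic similarity between two categories
#'
#' Each category's ancestors receive an S-value: 1 for the category
#' itself, and for every ancestor the maximum over down-edges of
#' `w_is_a * S(child)`.  The similarity is the sum of both categories'
#' S-values over their shared ancestors divided by the sum of all their
#' S-values; it lies in `[0, 1]`, is symmetric, and equals 1 for
#' identical categories.
#'
#' @param a,b category ids.
#' @param dag an [ontology_dag()].
#' @param w_is_a is_a edge weight (default 0.8).
#' @return similarity in `[0, 1]`.
#' @export
wang_similarity <- function(a, b, dag, w_is_a = 0.8) {
  sa <- wang_svalues(a, dag, w_is_a)
  sb <- wang_svalues(b, dag, w_is_a)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0) return(0)
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

wang_svalues <- function(term, dag, w = 0.8) {
  if (!term %in% dag$nodes) stop_msg("unknown category: %s", term)
  s <- stats::setNames(1, term)
  # relax upward until fixpoint (ancestor graphs are small)
  repeat {
    changed <- FALSE
    for (v in names(s)) {
      for (p in dag$parents[[v]]) {
        cand <- w * s[[v]]
        cur <- if (p %in% names(s)) s[[p]] else 0
        if (cand > cur + 1e-15) { s[p] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  s
}

#' Group significant categories into super-categories
#'
#' Complete-linkage hierarchical clustering on the distance
#' `1 - wang_similarity`, cut at `cutoff` (default 0.8).
#'
#' @param categories character vector of category ids (e.g. the
#'   dual-significant set).
#' @param dag an [ontology_dag()].
#' @param cutoff tree cut height (distance scale).
#' @param w_is_a Wang edge weight.
#' @return list of class `category_clusters`: `similarity` matrix,
#'   `tree` (hclust, `NULL` for a single category), `super_category`
#'   (named integer labels).
#' @export
cluster_categories <- function(categories, dag, cutoff = 0.8, w_is_a = 0.8) {
  categories <- unique(categories)
  k <- length(categories)
  if (k == 0) stop_msg("no categories to cluster")
  sim <- matrix(1, k, k, dimnames = list(categories, categories))
  if (k > 1) {
    sv <- lapply(categories, wang_svalues, dag = dag, w = w_is_a)
    names(sv) <- categories
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sa <- sv[[i]]; sb <- sv[[j]]
      shared <- intersect(names(sa), names(sb))
      s <- if (length(shared) == 0) 0
      else (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
      sim[i, j] <- sim[j, i] <- s
    }
  }
  if (k == 1) {
    return(structure(list(similarity = sim, tree = NULL,
                          super_category = stats::setNames(1L, categories)),
                     class = "category_clusters"))
  }
  tree <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
  labels <- stats::cutree(tree, h = cutoff)
  structure(list(similarity = sim, tree = tree, super_category = labels),
            class = "category_clusters")
}
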