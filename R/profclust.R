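# Bias normalisation, fuzzy c-means co-expression clustering and PCA.
#
# Transcripts with significant morph or morph-by-time effects are
# residualised for the fitted bias polynomial, standardised per transcript
# and clustered into soft co-expression profiles; clusters dominated by
# time-invariant between-morph differences feed a sample-level PCA.

#' Remove the fitted 3'-bias contribution and standardise
#'
#' Per transcript, subtracts `b1 (z - zbar) + b2 (z - zbar)^2` using that
#' transcript's full-model coefficients, then centres and scales the row
#' to mean 0 / sd 1 across samples.  Rows with zero residual variance are
#' excluded with a warning.
#'
#' @param abundance transcripts x samples TPM matrix (only rows to be
#'   clustered need be present).
#' @param fm_coefficients coefficient matrix from [run_detest()] (columns
#'   `z1`, `z2`), or a two-column matrix of per-transcript bias
#'   coefficients with matching rownames.
#' @param bias a [sample_bias_table()] result aligned with the abundance
#'   columns.
#' @param pseudocount log-transform pseudocount.
#' @return standardised matrix (class `normalized_matrix` attribute
#'   `dropped` listing excluded transcripts).
#' @export
normalize_by_bias <- function(abundance, fm_coefficients, bias,
                              pseudocount = 0.5) {
  bz <- as.data.frame(bias)
  if (!all(colnames(abundance) %in% bz$sample_id))
    stop_msg("bias table lacks z for some abundance columns")
  z <- bz$z[match(colnames(abundance), bz$sample_id)]
  zc <- z - mean(z)
  ids <- rownames(abundance)
  if (!all(ids %in% rownames(fm_coefficients)))
    stop_msg("fm_coefficients lacks rows for %d transcript(s)",
             sum(!ids %in% rownames(fm_coefficients)))
  has_z <- all(c("z1", "z2") %in% colnames(fm_coefficients))
  b1 <- if (has_z) fm_coefficients[ids, "z1"] else numeric(length(ids))
  b2 <- if (has_z) fm_coefficients[ids, "z2"] else numeric(length(ids))
  Y <- log(abundance + pseudocount)
  R <- Y - outer(b1, zc) - outer(b2, zc^2)
  mu <- rowMeans(R)
  s <- apply(R, 1, stats::sd)
  zero <- s < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sprintf("%d transcript(s) with zero variance excluded from the normalized matrix",
                    sum(zero)), call. = FALSE)
    R <- R[!zero, , drop = FALSE]
    mu <- mu[!zero]; s <- s[!zero]
  }
  X <- (R - mu) / s
  attr(X, "dropped") <- ids[zero]
  X
}

# deterministic farthest-point initial centroids (random first pick)
fcm_init <- function(X, k, seed) {
  set.seed(seed)
  n <- nrow(X)
  first <- sample.int(n, 1)
  centers <- first
  if (k > 1) {
    d2 <- rowSums((X - matrix(X[first, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      nxt <- which.max(d2)          # deterministic: lowest index on ties
      centers <- c(centers, nxt)
      dn <- rowSums((X - matrix(X[nxt, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, dn)
    }
  }
  X[centers, , drop = FALSE]
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Standard fuzzy c-means on Euclidean distances: membership
#' `u_ij = 1 / sum_l (d_ij / d_lj)^(2/(m-1))`, centroids the
#' `u^m`-weighted means.  The objective `sum u^m d^2` is non-increasing
#' over iterations and its trace is returned.  A point at exact zero
#' distance from a centroid takes full membership in (the first of) such
#' centroid(s).  Initial centroids are chosen by a deterministic
#' farthest-point rule after a seeded random first pick, so results are
#' reproducible and invariant to row order up to relabelling.
#'
#' @param X transcripts x samples matrix (typically a
#'   [normalize_by_bias()] result).
#' @param k number of clusters (default 16).
#' @param m fuzzification exponent, > 1 (default 1.1; close to hard
#'   clustering).
#' @param tol convergence threshold on the maximum centroid shift.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initial pick.
#' @return list of class `fuzzy_cmeans`: `centroids` (k x samples),
#'   `membership` (transcripts x k, rows sum to 1), `cluster` (hard
#'   assignment), `objective` (trace), `iterations`, `converged`, `k`,
#'   `m`.
#' @export
fuzzy_cmeans <- function(X, k = 16, m = 1.1, tol = 1e-6, max_iter = 200,
                         seed = 1L) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop_msg("k = %d exceeds the number of rows (%d)", k, nrow(X))
  if (m <= 1) stop_msg("fuzzification exponent m must be > 1")
  C <- fcm_init(X, k, seed)
  n <- nrow(X)
  obj <- numeric(0)
  conv <- FALSE
  iter <- 0
  memb_from_d2 <- function(d2) {
    U <- matrix(0, n, k)
    zero <- d2 < .Machine$double.xmin
    hasz <- rowSums(zero) > 0
    if (any(hasz))
      U[hasz, ] <- t(apply(zero[hasz, , drop = FALSE], 1, function(r) {
        u <- numeric(k); u[which(r)[1]] <- 1; u
      }))
    if (any(!hasz)) {
      w <- d2[!hasz, , drop = FALSE]^(-1 / (m - 1))
      U[!hasz, ] <- w / rowSums(w)
    }
    U
  }
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
    d2 <- pmax(d2, 0)
    U <- memb_from_d2(d2)
    Um <- U^m
    Cnew <- (t(Um) %*% X) / colSums(Um)
    empty <- colSums(Um) < .Machine$double.xmin
    if (any(empty)) Cnew[empty, ] <- C[empty, ]
    obj <- c(obj, sum(Um * d2))
    shift <- max(abs(Cnew - C))
    C <- Cnew
    if (shift < tol) { conv <- TRUE; break }
  }
  # final membership consistent with the returned centroids
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
    outer(rep(1, n), rowSums(C^2))
  d2 <- pmax(d2, 0)
  U <- memb_from_d2(d2)
  dimnames(U) <- list(rownames(X), paste0("cluster_", seq_len(k)))
  dimnames(C) <- list(paste0("cluster_", seq_len(k)), colnames(X))
  structure(list(centroids = C, membership = U,
                 cluster = max.col(U, ties.method = "first"),
                 objective = obj, iterations = iter, converged = conv,
                 k = k, m = m),
            class = "fuzzy_cmeans")
}

#' Summarise clusters by morph and timepoint, label morph-type clusters
#'
#' Relabels clusters `A`, `B`, ... in decreasing size order, computes each
#' cluster's centroid profile per morph x timepoint cell, labels a cluster
#' "morph-type" when the between-morph variance of its centroid exceeds
#' the mean within-morph across-time variance by more than
#' `ratio_threshold`, and cross-tabulates effect significance per cluster
#' when a [run_detest()] result is supplied.
#'
#' @param fcm a [fuzzy_cmeans()] result.
#' @param meta sample metadata aligned with the clustered columns.
#' @param detest optional [run_detest()] result for the significance
#'   cross-tabulation.
#' @param ratio_threshold morph-type labelling threshold (default 2).
#' @param threshold fdr threshold for the cross-tabulation.
#' @return list: `assignment` (transcript, cluster letter), `profiles`
#'   (cluster x morph x timepoint centroid means), `morph_type` (named
#'   logical), `sizes`, `effect_table` (counts of Morph / Time / MxT
#'   significant transcripts per cluster, or `NULL`).
#' @export
cluster_profiles <- function(fcm, meta, detest = NULL, ratio_threshold = 2,
                             threshold = 0.01) {
  sizes <- tabulate(fcm$cluster, nbins = fcm$k)
  ord <- order(sizes, decreasing = TRUE)
  letters_k <- make.unique(rep(LETTERS, length.out = fcm$k), sep = "")
  label <- character(fcm$k)
  label[ord] <- letters_k[seq_len(fcm$k)]
  assignment <- data.frame(transcript_id = rownames(fcm$membership),
                           cluster = label[fcm$cluster],
                           stringsAsFactors = FALSE)

  morphs <- unique(meta$morph)
  taus <- sort(unique(meta$tau))
  profiles <- array(NA_real_, dim = c(fcm$k, length(morphs), length(taus)),
                    dimnames = list(label, morphs, as.character(taus)))
  for (ci in seq_len(fcm$k)) {
    cen <- fcm$centroids[ci, ]
    agg <- tapply(cen, list(meta$morph, meta$tau), mean)
    profiles[label[ci], rownames(agg), colnames(agg)] <- agg
  }
  morph_type <- vapply(label, function(lab) {
    if (length(morphs) < 2) return(FALSE)
    pm <- matrix(profiles[lab, , ], length(morphs), length(taus))  # morph x tau
    morph_means <- rowMeans(pm, na.rm = TRUE)
    between <- stats::var(morph_means)
    within <- mean(apply(pm, 1, stats::var, na.rm = TRUE), na.rm = TRUE)
    if (!is.finite(within) || within < .Machine$double.eps) within <- .Machine$double.eps
    is.finite(between) && between / within > ratio_threshold
  }, logical(1))

  effect_table <- NULL
  if (!is.null(detest)) {
    w <- detest$wide
    idx <- match(assignment$transcript_id, w$transcript_id)
    flags <- data.frame(cluster = assignment$cluster,
                        Morph = w$q_Morph[idx] < threshold,
                        Time = w$q_Time[idx] < threshold,
                        MxT = w$q_MxT[idx] < threshold)
    effect_table <- stats::aggregate(cbind(Morph, Time, MxT) ~ cluster,
                                     data = flags, FUN = sum)
    effect_table$size <- as.integer(table(flags$cluster)[effect_table$cluster])
  }
  names(sizes) <- label
  list(assignment = assignment, profiles = profiles,
       morph_type = morph_type, sizes = sizes[order(names(sizes))],
       effect_table = effect_table, ratio_threshold = ratio_threshold)
}

#' PCA of samples over transcripts from selected clusters
#'
#' Samples are observations and transcripts variables; columns are
#' centred, the decomposition is SVD-based, and each component's sign is
#' fixed by making its largest-magnitude loading positive.
#'
#' @param X transcripts x samples matrix restricted to the clusters of
#'   interest (e.g. morph-type clusters).
#' @return list of class `morphde_pca`: `scores` (samples x components),
#'   `loadings` (transcripts x components, orthonormal),
#'   `variance_fraction`.
#' @export
pca_morph_clusters <- function(X) {
  M <- t(as.matrix(X))                        # samples x transcripts
  M <- sweep(M, 2, colMeans(M))
  sv <- svd(M)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(d, ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(M)
  rownames(loadings) <- colnames(M)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncomp))
  vf <- d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf),
            class = "morphde_pca")
}
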