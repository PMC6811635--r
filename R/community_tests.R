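# ANOSIM, Mantel and UPGMA: the community-comparison analyses.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

lower_tri <- function(d) d[lower.tri(d)]

anosim_statistic <- function(rank_d, groups_i) {
  # rank_d: midranks of the n(n-1)/2 pairwise dissimilarities (lower tri,
  # column-major); groups_i: integer group per unit.
  n <- length(groups_i)
  same <- outer(groups_i, groups_i, `==`)[lower.tri(diag(n))]
  r_w <- mean(rank_d[same])
  r_b <- mean(rank_d[!same])
  (r_b - r_w) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether dissimilarities between groups exceed those
#' within groups. All \code{n(n-1)/2} pairwise dissimilarities are ranked
#' (ties receive midranks); the statistic is
#' \code{R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)},
#' which lies in \code{[-1, 1]} and equals 1 when every between-group
#' dissimilarity is larger than every within-group one. Being rank-based, R
#' is invariant to any strictly monotone transform of the dissimilarities.
#' Significance comes from random relabelling of the units:
#' \code{p = (#\{permuted R >= observed R\} + 1) / (n_perm + 1)} (one-sided,
#' add-one convention).
#'
#' @param d Symmetric dissimilarity matrix with unit labels.
#' @param groups Named character vector or factor mapping every unit of
#'   \code{d} to a group; every group must have at least two members.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; identical seeds give identical results.
#' @return List of class \code{kb_anosim}: \code{R}, \code{p_value},
#'   \code{n_permutations}, \code{groups}, \code{seed}.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  check_dissimilarity(d)
  labels <- rownames(d)
  if (!is.null(names(groups))) {
    miss <- setdiff(labels, names(groups))
    if (length(miss)) {
      kb_reference_error(sprintf("unit(s) without group label: %s", paste(miss, collapse = ", ")))
    }
    groups <- groups[labels]
  } else if (length(groups) != length(labels)) {
    kb_value_error("groups must be named by unit or aligned with the matrix")
  }
  g <- as.integer(factor(as.character(groups)))
  tab <- table(g)
  if (length(tab) < 2L) kb_value_error("ANOSIM needs at least two groups")
  if (any(tab < 2L)) kb_value_error("every group must have at least two members")
  rank_d <- rank(lower_tri(d))
  R_obs <- anosim_statistic(rank_d, g)
  n <- length(g)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      anosim_statistic(rank_d, g[sample.int(n)])
    }, numeric(1L))
  })
  p <- (sum(perm_R >= R_obs) + 1) / (n_perm + 1)
  structure(list(
    R = R_obs, p_value = p, n_permutations = as.integer(n_perm),
    groups = stats::setNames(as.character(groups), labels),
    seed = seed, null_R = perm_R
  ), class = "kb_anosim")
}

#' Pairwise ANOSIM between all group pairs
#'
#' Runs [anosim_test()] once per unordered pair of groups, on the submatrix
#' of units belonging to that pair — the design used to compare massif zones
#' (three runs for three zones).
#'
#' @inheritParams anosim_test
#' @return A data.frame with one row per group pair: \code{group1},
#'   \code{group2}, \code{R}, \code{p_value}, \code{n_permutations}.
#' @export
anosim_pairwise <- function(d, groups, n_perm = 999, seed = NULL) {
  check_dissimilarity(d)
  labels <- rownames(d)
  if (is.null(names(groups))) groups <- stats::setNames(as.character(groups), labels)
  lev <- sort(unique(as.character(groups[labels])))
  pairs <- utils::combn(lev, 2L)
  seeds <- if (is.null(seed)) rep(list(NULL), ncol(pairs)) else as.list(seed + seq_len(ncol(pairs)) - 1L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- labels[groups[labels] %in% pairs[, k]]
    res <- anosim_test(d[keep, keep, drop = FALSE], groups[keep],
                       n_perm = n_perm, seed = seeds[[k]])
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               R = res$R, p_value = res$p_value,
               n_permutations = res$n_permutations,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mantel test with Spearman rank correlation
#'
#' Correlates the off-diagonal entries of two distance matrices (community
#' dissimilarity vs. spatial distance) by Spearman rank correlation, which
#' accommodates non-linear but monotone relations. Significance comes from
#' jointly permuting the row/column order of one matrix;
#' \code{p = (#\{permuted r >= observed r\} + 1) / (n_perm + 1)}.
#'
#' @param d1,d2 Symmetric matrices with identical unit labels in identical
#'   order; at least four units.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class \code{kb_mantel}: \code{r}, \code{p_value},
#'   \code{n_permutations}, \code{correlation_method}, \code{seed}.
#' @export
mantel_spearman <- function(d1, d2, n_perm = 999, seed = NULL) {
  check_dissimilarity(d1)
  check_dissimilarity(d2)
  if (!identical(rownames(d1), rownames(d2))) {
    kb_reference_error("the two matrices must share the same unit labels in the same order")
  }
  n <- nrow(d1)
  if (n < 4L) kb_value_error("Mantel test needs at least 4 units")
  v1 <- lower_tri(d1)
  r_obs <- stats::cor(v1, lower_tri(d2), method = "spearman")
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(n)
      stats::cor(v1, lower_tri(d2[ord, ord]), method = "spearman")
    }, numeric(1L))
  })
  p <- (sum(perm_r >= r_obs) + 1) / (n_perm + 1)
  structure(list(
    r = r_obs, p_value = p, n_permutations = as.integer(n_perm),
    correlation_method = "spearman", seed = seed, null_r = perm_r
  ), class = "kb_mantel")
}

#' UPGMA clustering of sampling units
#'
#' Agglomerative clustering with unweighted arithmetic average linkage: at
#' each step the pair of clusters with the smallest mean inter-cluster
#' dissimilarity is merged, at a height of half that mean (so the tree is
#' ultrametric and the cophenetic distance between two leaves equals twice
#' the height of their lowest common ancestor). Units are ordered
#' lexicographically before clustering so that ties between candidate merges
#' resolve identically on every platform.
#'
#' @param d Symmetric dissimilarity matrix with at least two units.
#' @return Object of class \code{kb_dendrogram}: fields \code{hclust} (the
#'   underlying average-linkage tree, heights on the dissimilarity scale),
#'   \code{heights} (merge heights, = dissimilarity / 2) and \code{labels}.
#' @seealso [write_newick()], [cophenetic_matrix()]
#' @export
upgma <- function(d) {
  check_dissimilarity(d)
  if (nrow(d) < 2L) kb_value_error("UPGMA needs at least two units")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  h <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = h, heights = h$height / 2, labels = h$labels),
            class = "kb_dendrogram")
}

#' Cophenetic distances of a UPGMA dendrogram
#'
#' Distances on the scale of the input dissimilarities (twice the merge
#' height of the lowest common ancestor).
#'
#' @param tree A \code{kb_dendrogram} from [upgma()].
#' @return A symmetric labelled matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "kb_dendrogram")) kb_value_error("expected a kb_dendrogram")
  as.matrix(stats::cophenetic(tree$hclust))
}

#' @export
print.kb_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
print.kb_mantel <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
print.kb_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram with %d leaves, root height %.4f\n",
              length(x$labels), max(x$heights)))
  invisible(x)
}
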