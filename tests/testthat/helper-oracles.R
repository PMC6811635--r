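# Independent brute-force oracles, deliberately written with explicit set
# operations and exhaustive enumeration rather than the package's linear
# algebra, so agreement is evidence and not tautology.

# Jaccard dissimilarity matrix via explicit species sets.
oracle_jaccard <- function(m) {
  sets <- lapply(seq_len(ncol(m)), function(j) rownames(m)[m[, j] > 0])
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    uni <- union(sets[[i]], sets[[j]])
    d[i, j] <- if (length(uni) == 0) NA else 1 - length(intersect(sets[[i]], sets[[j]])) / length(uni)
  }
  d
}

# Multiple-site aggregates via pair enumeration on explicit sets.
oracle_aggregates <- function(m, ids = colnames(m)) {
  sets <- lapply(ids, function(u) rownames(m)[m[, u] > 0])
  smin <- 0L; smax <- 0L
  for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
    bij <- length(setdiff(sets[[i]], sets[[j]]))
    bji <- length(setdiff(sets[[j]], sets[[i]]))
    smin <- smin + min(bij, bji); smax <- smax + max(bij, bji)
  }
  list(S_T = length(unique(unlist(sets))),
       sum_Si = sum(lengths(sets)), sum_min = smin, sum_max = smax,
       n_sites = length(sets))
}

# Brute-force unweighted average linkage; returns the cophenetic matrix on
# the input dissimilarity scale.
oracle_avg_linkage_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best - 1e-12) { best <- avg; bi <- i; bj <- j }
      }
    }
    coph[clusters[[bi]], clusters[[bj]]] <- best
    coph[clusters[[bj]], clusters[[bi]]] <- best
    clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
    clusters[[bi]] <- NULL
  }
  coph
}

# Exact one-sided Mantel p-value (Spearman) by exhausting all n! joint
# row/column permutations of the second matrix, identity included.
oracle_mantel_exact_p <- function(d1, d2) {
  n <- nrow(d1)
  perms <- gtools_permutations(n)
  v1 <- d1[lower.tri(d1)]
  r_obs <- stats::cor(v1, d2[lower.tri(d2)], method = "spearman")
  r_all <- apply(perms, 1L, function(ord) {
    stats::cor(v1, d2[ord, ord][lower.tri(d1)], method = "spearman")
  })
  mean(r_all >= r_obs - 1e-12)
}

# All permutations of 1..n (tiny n only).
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

# Random binary incidence matrix with no empty unit.
random_incidence <- function(n_sp, n_units, p = 0.35) {
  m <- matrix(as.integer(stats::runif(n_sp * n_units) < p), n_sp, n_units,
              dimnames = list(sprintf("sp%02d", seq_len(n_sp)),
                              sprintf("u%02d", seq_len(n_units))))
  for (j in which(colSums(m) == 0L)) m[sample.int(n_sp, 1L), j] <- 1L
  m
}

# Random symmetric zero-diagonal dissimilarity matrix with distinct entries.
random_dissimilarity <- function(n, labels = sprintf("u%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[lower.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  d + t(d)
}
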