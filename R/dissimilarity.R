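# Pairwise community dissimilarity (incidence-based Jaccard) and 3D spatial
# distances between sampling units.

#' Shared/unique species counts for a pair of communities
#'
#' Computes the classical (a, b, c) components of incidence-based pairwise
#' indices: \code{a} species present in both units, \code{b} only in the
#' first, \code{c} only in the second.
#'
#' @param x,y Binary presence/absence vectors of equal length.
#' @return An object of class \code{pair_counts}: list with integer fields
#'   \code{a}, \code{b}, \code{c}.
#' @export
pair_counts <- function(x, y) {
  if (length(x) != length(y)) kb_value_error("incidence vectors differ in length")
  if (anyNA(x) || anyNA(y) || !all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    kb_value_error("incidence vectors must be binary (0/1)")
  }
  structure(list(
    a = as.integer(sum(x == 1 & y == 1)),
    b = as.integer(sum(x == 1 & y == 0)),
    c = as.integer(sum(x == 0 & y == 1))
  ), class = "pair_counts")
}

#' Build pair counts from printed richness and overlap figures
#'
#' Convenience constructor for desk calculations from reported zone richness
#' values: with richness \code{r1}, \code{r2} and \code{shared} species in
#' common, \code{a = shared}, \code{b = r1 - shared}, \code{c = r2 - shared}.
#'
#' @param r1,r2 Species richness of the two communities.
#' @param shared Number of species present in both.
#' @return A \code{pair_counts} object.
#' @examples
#' pair_counts_from_richness(16, 17, 12)  # a=12, b=4, c=5
#' @export
pair_counts_from_richness <- function(r1, r2, shared) {
  if (shared > min(r1, r2)) kb_value_error("shared richness exceeds a community's richness")
  if (any(c(r1, r2, shared) < 0)) kb_value_error("richness values must be non-negative")
  structure(list(a = as.integer(shared), b = as.integer(r1 - shared),
                 c = as.integer(r2 - shared)), class = "pair_counts")
}

check_pair_nonempty <- function(p) {
  if (!inherits(p, "pair_counts")) kb_value_error("expected a pair_counts object")
  if (p$a + p$b + p$c == 0L) {
    kb_value_error("both communities are empty; Jaccard dissimilarity is undefined")
  }
  invisible(p)
}

#' Jaccard dissimilarity from pair counts
#'
#' \code{(b + c) / (a + b + c)}: the proportion of the pooled species list
#' not shared by the two communities. Complements the shared fraction
#' exactly: \code{jaccard_dissimilarity(p) + a/(a+b+c) == 1}.
#'
#' @param p A \code{pair_counts} object with \code{a + b + c > 0}.
#' @return A dissimilarity in \code{[0, 1]}.
#' @export
jaccard_dissimilarity <- function(p) {
  check_pair_nonempty(p)
  (p$b + p$c) / (p$a + p$b + p$c)
}

#' Percentage of species shared by two communities
#'
#' \code{100 * a / (a + b + c)}, rounded half-up to the nearest integer
#' percent — the convention used for reported shared-species figures.
#'
#' @param p A \code{pair_counts} object with \code{a + b + c > 0}.
#' @return Integer percent.
#' @examples
#' shared_percentage(pair_counts_from_richness(16, 17, 12))  # 57
#' @export
shared_percentage <- function(p) {
  check_pair_nonempty(p)
  as.integer(floor(100 * p$a / (p$a + p$b + p$c) + 0.5))
}

#' Pairwise Jaccard dissimilarity matrix of an incidence matrix
#'
#' @param m Binary incidence matrix (species x units); every unit must have
#'   at least one presence.
#' @return A symmetric, zero-diagonal dissimilarity matrix labelled by unit
#'   id, with attribute \code{metric = "jaccard"}.
#' @export
jaccard_matrix <- function(m) {
  if (anyNA(m) || !all(m %in% c(0, 1))) kb_value_error("incidence matrix must be binary")
  empty <- colSums(m) == 0
  if (any(empty)) {
    kb_value_error(sprintf("empty sampling unit(s): %s; drop them before computing Jaccard",
                           paste(colnames(m)[empty], collapse = ", ")))
  }
  A <- crossprod(m)                      # shared species a_ij
  S <- diag(A)                           # per-unit richness
  U <- outer(S, S, `+`) - A              # union a + b + c
  d <- 1 - A / U
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  attr(d, "metric") <- "jaccard"
  d
}

#' 3D Euclidean distances between sampling units
#'
#' Straight-line distances in the shared Cartesian frame of the massif,
#' in meters.
#'
#' @param units Sampling-unit table with numeric columns \code{x}, \code{y},
#'   \code{z}.
#' @return Symmetric distance matrix labelled by unit id, attribute
#'   \code{metric = "euclidean_3d"}.
#' @export
spatial_distance_matrix <- function(units) {
  coords <- as.matrix(units[, c("x", "y", "z")])
  if (anyNA(coords)) {
    kb_value_error(sprintf(
      "missing coordinates for unit(s): %s",
      paste(units$unit_id[apply(is.na(coords), 1L, any)], collapse = ", ")
    ))
  }
  d <- as.matrix(stats::dist(coords, method = "euclidean"))
  dimnames(d) <- list(units$unit_id, units$unit_id)
  attr(d, "metric") <- "euclidean_3d"
  d
}

check_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) kb_value_error("dissimilarity must be a square matrix")
  if (anyNA(d)) kb_value_error("dissimilarity matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-9) kb_value_error("dissimilarity matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) kb_value_error("dissimilarity matrix has non-zero diagonal")
  if (is.null(rownames(d))) kb_value_error("dissimilarity matrix must be labelled")
  invisible(d)
}
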