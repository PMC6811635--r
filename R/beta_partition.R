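# Additive partitioning of Jaccard-family beta diversity into species
# turnover and nestedness, pairwise and multiple-site, plus the vertical and
# horizontal comparison-set constructions used across a massif.

new_bd_partition <- function(total, turnover, n_sites) {
  structure(list(
    total = total, turnover = turnover, nestedness = total - turnover,
    n_sites = as.integer(n_sites), family = "jaccard"
  ), class = "bd_partition")
}

#' Pairwise beta-diversity partition (Jaccard family)
#'
#' Splits the Jaccard dissimilarity of two communities additively into a
#' species-turnover component (replacement of species between the sites,
#' independent of richness difference) and a nestedness component (species
#' loss, one community being a partial subset of the other):
#' \deqn{total = (b+c)/(a+b+c), \quad turnover = 2\min(b,c)/(a + 2\min(b,c)),}
#' \deqn{nestedness = total - turnover.}
#' A strictly nested pair (\code{b = 0} or \code{c = 0}) has zero turnover;
#' two equally rich communities sharing nothing have turnover 1.
#'
#' @param p A \code{pair_counts} object (see [pair_counts()]).
#' @return An object of class \code{bd_partition}: \code{total},
#'   \code{turnover}, \code{nestedness}, \code{n_sites = 2},
#'   \code{family = "jaccard"}.
#' @export
pairwise_partition <- function(p) {
  check_pair_nonempty(p)
  total <- (p$b + p$c) / (p$a + p$b + p$c)
  mn <- min(p$b, p$c)
  turnover <- if (p$a + 2 * mn == 0) 0 else 2 * mn / (p$a + 2 * mn)
  new_bd_partition(total, turnover, 2L)
}

#' Multiple-site aggregates of an incidence matrix
#'
#' The integer building blocks of the multiple-site partition over a set of
#' sites: pooled richness \code{S_T}, summed per-site richness
#' \code{sum_Si}, and the sums over all unordered site pairs of
#' \code{min(b_ij, b_ji)} and \code{max(b_ij, b_ji)}, where \code{b_ij} is
#' the number of species present at site i but absent from site j.
#'
#' @param m Binary incidence matrix (species x units).
#' @param unit_ids Units making up the site set (>= 2, all non-empty).
#' @return List with integer fields \code{S_T}, \code{sum_Si},
#'   \code{sum_min}, \code{sum_max}, \code{n_sites}.
#' @export
multisite_aggregates <- function(m, unit_ids = colnames(m)) {
  miss <- setdiff(unit_ids, colnames(m))
  if (length(miss)) {
    kb_reference_error(sprintf("unit(s) not in incidence matrix: %s", paste(miss, collapse = ", ")))
  }
  x <- m[, unit_ids, drop = FALSE]
  if (anyNA(x) || !all(x %in% c(0, 1))) kb_value_error("incidence matrix must be binary")
  if (ncol(x) < 2L) kb_value_error("a multiple-site set needs at least two units")
  empty <- colSums(x) == 0
  if (any(empty)) {
    kb_value_error(sprintf("empty sampling unit(s) in set: %s",
                           paste(unit_ids[empty], collapse = ", ")))
  }
  k <- ncol(x)
  S <- colSums(x)
  A <- crossprod(x)                 # a_ij shared species
  B <- matrix(S, k, k) - A          # B[i, j] = b_ij (row index varies first)
  ut <- upper.tri(B)
  bij <- t(B)[ut]                   # pairs i < j
  bji <- B[ut]
  list(
    S_T = as.integer(sum(rowSums(x) > 0)),
    sum_Si = as.integer(sum(S)),
    sum_min = as.integer(sum(pmin(bij, bji))),
    sum_max = as.integer(sum(pmax(bij, bji))),
    n_sites = k
  )
}

#' Multiple-site beta-diversity partition (Jaccard family)
#'
#' A single beta-diversity value summarizing the unique/shared species
#' structure of the whole site set (not an average of pairwise values),
#' partitioned additively:
#' \deqn{total = (Smin + Smax) / ((\Sigma S_i - S_T) + Smin + Smax)}
#' \deqn{turnover = 2 Smin / ((\Sigma S_i - S_T) + 2 Smin)}
#' with \code{Smin, Smax} the pair sums from [multisite_aggregates()] and
#' nestedness the difference. For two sites this reduces exactly to
#' [pairwise_partition()]. A degenerate set where every denominator is zero
#' (all sites identical, single species) has total 0 by convention.
#'
#' @param agg Aggregates from [multisite_aggregates()].
#' @return A \code{bd_partition} object.
#' @export
multisite_partition <- function(agg) {
  with(agg, {
    denom_t <- (sum_Si - S_T) + sum_min + sum_max
    total <- if (denom_t == 0) 0 else (sum_min + sum_max) / denom_t
    denom_r <- (sum_Si - S_T) + 2 * sum_min
    turnover <- if (denom_r == 0) 0 else 2 * sum_min / denom_r
    new_bd_partition(total, turnover, n_sites)
  })
}

#' Multiple-site partition of a unit set, in one call
#' @inheritParams multisite_aggregates
#' @return A \code{bd_partition} object.
#' @export
beta_partition <- function(m, unit_ids = colnames(m)) {
  multisite_partition(multisite_aggregates(m, unit_ids))
}

#' Componentwise mean of beta-diversity partitions
#'
#' Averages total, turnover and nestedness over a list of partitions.
#' Because every member satisfies turnover + nestedness = total, so does the
#' mean, exactly.
#'
#' @param partitions Non-empty list of \code{bd_partition} objects.
#' @return A \code{bd_partition}-like summary; \code{n_sites} is the mean
#'   set size.
#' @export
average_bd <- function(partitions) {
  if (!length(partitions)) kb_value_error("cannot average an empty list of partitions")
  tot <- mean(vapply(partitions, `[[`, numeric(1L), "total"))
  tur <- mean(vapply(partitions, `[[`, numeric(1L), "turnover"))
  out <- new_bd_partition(tot, tur, round(mean(vapply(partitions, `[[`, integer(1L), "n_sites"))))
  out$n_partitions <- length(partitions)
  out
}

#' @export
print.bd_partition <- function(x, ...) {
  cat(sprintf("Beta diversity (%s family, %d sites): total %.4f = turnover %.4f + nestedness %.4f\n",
              x$family, x$n_sites, x$total, x$turnover, x$nestedness))
  invisible(x)
}

comparison_set <- function(set_id, setting, label, unit_ids) {
  if (length(unit_ids) < 2L) {
    kb_value_error(sprintf("comparison set '%s' needs at least two units", set_id))
  }
  structure(list(set_id = set_id, setting = setting, label = label,
                 unit_ids = unit_ids), class = "kb_comparison_set")
}

#' Vertical beta-diversity comparison sets
#'
#' Vertical beta diversity in the central massif is the average diversity
#' over all combinations of one shallow-upper unit with the deep-core units
#' of one deep cave: each shallow unit is paired with each deep cave's full
#' stack of deep strata (5 shallow units x 2 deep caves = 10 sets of 6
#' units in the reference design). The slope zone has one community per
#' elevation, so it contributes a single multiple-site set of all slope
#' units.
#'
#' @param units Sampling-unit table (see [read_metadata_csv()]).
#' @param expected_strata Number of deep strata a deep cave is expected to
#'   contribute (default 5); caves with a different count are used as-is
#'   with a warning.
#' @return List of \code{kb_comparison_set}: settings
#'   \code{"vertical_central"} (one per shallow unit x deep cave) and
#'   \code{"vertical_slope"} (one set).
#' @export
build_vertical_sets <- function(units, expected_strata = 5L) {
  shallow <- units$unit_id[units$zone == "shallow_upper"]
  deep <- units[units$zone == "deep_core", , drop = FALSE]
  slope <- units$unit_id[units$zone == "slope"]
  sets <- list()
  if (length(shallow) && nrow(deep)) {
    for (cave in sort(unique(deep$cave_code))) {
      deep_units <- deep$unit_id[deep$cave_code == cave]
      if (length(deep_units) != expected_strata) {
        warning(sprintf("deep cave '%s' has %d deep strata (expected %d); using available strata",
                        cave, length(deep_units), expected_strata), call. = FALSE)
      }
      for (su in shallow) {
        sets[[length(sets) + 1L]] <- comparison_set(
          set_id = sprintf("vert_%s_x_%s", su, cave),
          setting = "vertical_central",
          label = sprintf("%s + deep %s", su, cave),
          unit_ids = c(su, deep_units)
        )
      }
    }
  }
  if (length(slope) >= 2L) {
    sets[[length(sets) + 1L]] <- comparison_set(
      set_id = "vert_slope", setting = "vertical_slope",
      label = "slope zone", unit_ids = slope
    )
  }
  sets
}

#' Horizontal beta-diversity comparison sets
#'
#' One set per depth stratum, containing every sampling unit assigned that
#' stratum regardless of zone or lateral position (slope caves enter deeper
#' strata through their explicit stratum labels). Strata with fewer than two
#' units are skipped with a warning.
#'
#' @param units Sampling-unit table with a \code{stratum} column.
#' @return List of \code{kb_comparison_set} with setting
#'   \code{"horizontal"}, in stratum depth order.
#' @export
build_horizontal_sets <- function(units) {
  sets <- list()
  for (s in KB_STRATA) {
    ids <- units$unit_id[units$stratum == s]
    if (length(ids) < 2L) {
      if (length(ids) == 1L) {
        warning(sprintf("stratum '%s' has a single unit (%s); skipped", s, ids), call. = FALSE)
      }
      next
    }
    sets[[length(sets) + 1L]] <- comparison_set(
      set_id = sprintf("horiz_%s", s), setting = "horizontal",
      label = s, unit_ids = ids
    )
  }
  sets
}

# Restrict a comparison set to units actually present in the incidence
# matrix (e.g. after empty units were dropped); warns rather than fails.
prune_set <- function(set, m) {
  keep <- intersect(set$unit_ids, colnames(m))
  if (length(keep) < length(set$unit_ids)) {
    warning(sprintf("set '%s': dropping unit(s) absent from the incidence matrix: %s",
                    set$set_id, paste(setdiff(set$unit_ids, keep), collapse = ", ")),
            call. = FALSE)
    set$unit_ids <- keep
  }
  set
}

#' Observed beta diversity of a comparison set
#'
#' For \code{vertical_central} sets the observed statistic of a group of
#' sets is their [average_bd()]; this helper evaluates a single set's
#' multiple-site partition.
#'
#' @param m Binary incidence matrix.
#' @param set A \code{kb_comparison_set}.
#' @return A \code{bd_partition}.
#' @export
set_partition <- function(m, set) {
  set <- prune_set(set, m)
  beta_partition(m, set$unit_ids)
}
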