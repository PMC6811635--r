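# Fill-preserving randomization of incidence matrices and significance of
# observed beta-diversity components against the null ensemble.

#' Randomize an incidence matrix holding total fill constant
#'
#' The default null model of the package: the overall diversity of the
#' massif (total number of presences) is held constant while the presences
#' are re-placed uniformly at random over all cells, without row- or
#' column-sum constraints — the number of occurrences per sampling unit and
#' per species is left free. Species and unit labels are retained. A
#' stricter variant, \code{method = "species_totals"}, additionally fixes
#' each species' number of occurrences, shuffling presences within rows.
#'
#' Uses the current RNG stream; wrap calls in a seeded context (or use
#' [null_test()] / [run_fig_battery()], which seed for you) for
#' reproducibility.
#'
#' @param m Binary incidence matrix (species x units).
#' @param method \code{"fill"} (default) or \code{"species_totals"}.
#' @return A binary matrix of the same shape, labels preserved, with exactly
#'   the same total number of presences.
#' @export
randomize_matrix <- function(m, method = c("fill", "species_totals")) {
  method <- match.arg(method)
  if (anyNA(m) || !all(m %in% c(0, 1))) kb_value_error("incidence matrix must be binary")
  out <- m
  if (method == "fill") {
    fill <- sum(m)
    out[] <- 0L
    out[sample.int(length(m), fill)] <- 1L
  } else {
    nc <- ncol(m)
    for (i in seq_len(nrow(m))) {
      ri <- sum(m[i, ])
      out[i, ] <- 0L
      if (ri > 0L) out[i, sample.int(nc, ri)] <- 1L
    }
  }
  out
}

# Observed statistic of a group of comparison sets on matrix `m`: the
# multiple-site partition of each set restricted to its non-empty units,
# averaged componentwise over sets. Returns NULL if any set degenerates to
# fewer than two non-empty units (callers resample such replicates).
group_statistic <- function(m, sets, warn = FALSE) {
  parts <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    ids <- sets[[k]]$unit_ids
    ids <- ids[colSums(m[, ids, drop = FALSE]) > 0]
    if (length(ids) < 2L) return(NULL)
    if (warn && length(ids) < length(sets[[k]]$unit_ids)) {
      warning(sprintf("set '%s': computing on %d non-empty unit(s)",
                      sets[[k]]$set_id, length(ids)), call. = FALSE)
    }
    parts[[k]] <- beta_partition(m, ids)
  }
  if (length(parts) == 1L) parts[[1L]] else average_bd(parts)
}

new_null_ensemble <- function(name, observed, null_values, seed) {
  n_null <- length(null_values)
  ge <- sum(null_values >= observed)
  le <- sum(null_values <= observed)
  p <- min(1, 2 * min(ge + 1L, le + 1L) / (n_null + 1))
  structure(list(
    statistic_name = name, observed = observed, null_values = null_values,
    n_null = n_null, p_value = p, direction = "two_sided",
    null_mean = mean(null_values),
    null_q025 = unname(stats::quantile(null_values, 0.025, type = 7)),
    null_q975 = unname(stats::quantile(null_values, 0.975, type = 7)),
    seed = seed
  ), class = "kb_null_ensemble")
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Null-model test of beta-diversity components
#'
#' Computes the observed multiple-site beta-diversity partition of a
#' comparison set (or the componentwise average over several sets, as in the
#' vertical-central design), then re-places the presences of the whole
#' massif matrix uniformly at random \code{n_null} times, recomputing the
#' same statistic on each replicate. Each component (total, turnover,
#' nestedness) gets a two-sided add-one p-value
#' \code{min(1, 2 min(#\{null >= obs\} + 1, #\{null <= obs\} + 1) / (n_null + 1))},
#' since departures in both directions (excess and deficient beta diversity)
#' are of interest. Replicates in which a set retains fewer than two
#' non-empty units are resampled (the count is recorded).
#'
#' @param m Binary incidence matrix of the whole massif.
#' @param sets A single \code{kb_comparison_set} or a list of them; several
#'   sets are averaged into one statistic per component.
#' @param n_null Number of null matrices (default 9999).
#' @param seed Integer seed.
#' @param method Randomization scheme, see [randomize_matrix()].
#' @return List of class \code{kb_null_test} with elements \code{total},
#'   \code{turnover}, \code{nestedness} (each a \code{kb_null_ensemble}),
#'   plus \code{n_resampled} and \code{seed}.
#' @export
null_test <- function(m, sets, n_null = 9999, seed = NULL,
                      method = c("fill", "species_totals")) {
  method <- match.arg(method)
  if (inherits(sets, "kb_comparison_set")) sets <- list(sets)
  sets <- lapply(sets, prune_set, m = m)
  obs <- group_statistic(m, sets, warn = TRUE)
  if (is.null(obs)) kb_value_error("observed comparison set has fewer than two non-empty units")
  nulls <- matrix(NA_real_, n_null, 3L,
                  dimnames = list(NULL, c("total", "turnover", "nestedness")))
  n_resampled <- 0L
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      repeat {
        stat <- group_statistic(randomize_matrix(m, method), sets)
        if (!is.null(stat)) break
        n_resampled <- n_resampled + 1L
        if (n_resampled > 100L * n_null) {
          kb_value_error("null replicates degenerate; comparison sets too sparse")
        }
      }
      nulls[r, ] <- c(stat$total, stat$turnover, stat$nestedness)
    }
  })
  structure(list(
    total = new_null_ensemble("total", obs$total, nulls[, "total"], seed),
    turnover = new_null_ensemble("turnover", obs$turnover, nulls[, "turnover"], seed),
    nestedness = new_null_ensemble("nestedness", obs$nestedness, nulls[, "nestedness"], seed),
    n_resampled = n_resampled, n_null = as.integer(n_null), seed = seed,
    method = method
  ), class = "kb_null_test")
}

#' @export
print.kb_null_test <- function(x, ...) {
  for (s in c("total", "turnover", "nestedness")) {
    e <- x[[s]]
    cat(sprintf("%-10s observed %.4f  null %.4f [%.4f, %.4f]  p = %.4g %s\n",
                s, e$observed, e$null_mean, e$null_q025, e$null_q975,
                e$p_value, significance_stars(e$p_value)))
  }
  invisible(x)
}

#' Run the full observed-vs-null beta-diversity battery
#'
#' Evaluates every horizontal stratum set separately, the vertical-central
#' combinations as one averaged statistic, and the slope set separately —
#' the bar-chart layout of observed vs. modelled beta diversity per setting.
#' All tests of one battery share the same stream of randomized massif
#' matrices (the massif is randomized once per replicate and every set is
#' evaluated on that replicate), preserving the correlation structure across
#' settings.
#'
#' @param m Binary incidence matrix of the whole massif.
#' @param sets List of comparison sets from [build_vertical_sets()] and/or
#'   [build_horizontal_sets()].
#' @param n_null Number of null matrices (default 9999).
#' @param seed Integer seed.
#' @param method Randomization scheme, see [randomize_matrix()].
#' @return A data.frame, one row per setting x component: \code{setting},
#'   \code{label}, \code{n_sets}, \code{n_units}, \code{statistic},
#'   \code{observed}, \code{null_mean}, \code{null_q025}, \code{null_q975},
#'   \code{p_value}, \code{stars}, \code{n_null}, \code{seed}.
#' @export
run_fig_battery <- function(m, sets, n_null = 9999, seed = NULL,
                            method = c("fill", "species_totals")) {
  method <- match.arg(method)
  sets <- lapply(sets, prune_set, m = m)
  settings <- vapply(sets, `[[`, character(1L), "setting")
  groups <- list()
  vc <- sets[settings == "vertical_central"]
  if (length(vc)) {
    groups[["vertical_central"]] <- list(sets = vc, setting = "vertical_central",
                                         label = "central massif (averaged combos)")
  }
  for (s in sets[settings == "vertical_slope"]) {
    groups[[s$set_id]] <- list(sets = list(s), setting = s$setting, label = s$label)
  }
  for (s in sets[settings == "horizontal"]) {
    groups[[s$set_id]] <- list(sets = list(s), setting = s$setting, label = s$label)
  }
  if (!length(groups)) kb_value_error("no comparison sets to test")

  obs <- lapply(groups, function(g) group_statistic(m, g$sets, warn = TRUE))
  bad <- vapply(obs, is.null, logical(1L))
  if (any(bad)) {
    kb_value_error(sprintf("comparison group(s) with <2 non-empty units: %s",
                           paste(names(groups)[bad], collapse = ", ")))
  }
  nulls <- array(NA_real_, c(n_null, length(groups), 3L),
                 dimnames = list(NULL, names(groups), c("total", "turnover", "nestedness")))
  n_resampled <- 0L
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      repeat {
        mr <- randomize_matrix(m, method)
        stats_r <- lapply(groups, function(g) group_statistic(mr, g$sets))
        if (!any(vapply(stats_r, is.null, logical(1L)))) break
        n_resampled <- n_resampled + 1L
        if (n_resampled > 100L * n_null) {
          kb_value_error("null replicates degenerate; comparison sets too sparse")
        }
      }
      for (j in seq_along(groups)) {
        nulls[r, j, ] <- c(stats_r[[j]]$total, stats_r[[j]]$turnover, stats_r[[j]]$nestedness)
      }
    }
  })
  rows <- list()
  for (j in seq_along(groups)) {
    g <- groups[[j]]
    for (s in c("total", "turnover", "nestedness")) {
      o <- obs[[j]][[s]]
      ens <- new_null_ensemble(s, o, nulls[, j, s], seed)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = g$setting, label = g$label,
        n_sets = length(g$sets),
        n_units = length(unique(unlist(lapply(g$sets, `[[`, "unit_ids")))),
        statistic = s, observed = o,
        null_mean = ens$null_mean, null_q025 = ens$null_q025,
        null_q975 = ens$null_q975, p_value = ens$p_value,
        stars = significance_stars(ens$p_value),
        n_null = as.integer(n_null),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_resampled") <- n_resampled
  rownames(out) <- NULL
  out
}
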