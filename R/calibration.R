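# Scenario-recovery and type-I-error calibration: the simulation experiments
# that validate the observed-vs-null testing machinery on data whose
# generating process is known.

deep_strata_labels <- function() KB_STRATA[-1L]

#' Does one synthetic data set recover its scenario's signature?
#'
#' Generates one data set under the given scenario and checks whether the
#' observed-vs-null battery shows the pattern that scenario was built to
#' produce:
#' \describe{
#'   \item{\code{nested_central}}{the averaged vertical-central total beta
#'     diversity falls significantly below its null (two-sided p < 0.05 with
#'     observed < null mean) and the observed nestedness component exceeds
#'     the null mean;}
#'   \item{\code{deep_turnover}}{a majority of deep strata show horizontal
#'     total beta diversity above the null mean, at least one deep stratum
#'     is significant (two-sided p < 0.05) in that direction, and in every
#'     significant stratum turnover dominates nestedness;}
#'   \item{\code{slope_distinct}}{the slope-involving pairwise ANOSIM runs
#'     both reject (p < 0.05) with larger R than the shallow-vs-deep run;}
#'   \item{\code{bfn_random}}{defined as the vertical-central total BD test
#'     NOT rejecting at p < 0.05 (used for significance-frequency checks).}
#' }
#'
#' @param scenario Scenario name, see [scenario_spec()].
#' @param seed Integer seed for this replicate (drives both the generator
#'   and the permutation/null streams).
#' @param n_null Null replicates for the battery (default 999).
#' @param effect_size Scenario structure strength (default 0.6).
#' @param ... Further arguments to [scenario_spec()].
#' @return List: \code{recovered} (logical), \code{battery} (or
#'   \code{anosim} table for \code{slope_distinct}).
#' @export
recover_scenario <- function(scenario, seed, n_null = 999L, effect_size = 0.6, ...) {
  dat <- generate_scenario(scenario_spec(scenario, seed = seed,
                                         effect_size = effect_size, ...))
  units <- dat$units
  inc <- dat$incidence

  if (scenario == "slope_distinct") {
    d <- jaccard_matrix(inc)
    groups <- stats::setNames(units$zone, units$unit_id)
    tab <- anosim_pairwise(d, groups, n_perm = n_null, seed = seed + 1L)
    slope_rows <- tab$group1 == "slope" | tab$group2 == "slope"
    other <- tab[!slope_rows, , drop = FALSE]
    hit <- all(tab$p_value[slope_rows] < 0.05) &&
      all(tab$R[slope_rows] > max(other$R))
    return(list(recovered = hit, anosim = tab))
  }

  sets <- suppressWarnings(c(build_vertical_sets(units), build_horizontal_sets(units)))
  settings <- vapply(sets, `[[`, character(1L), "setting")
  use <- switch(scenario,
    deep_turnover = {
      horiz <- sets[settings == "horizontal"]
      labs <- vapply(horiz, `[[`, character(1L), "label")
      horiz[labs %in% deep_strata_labels()]
    },
    sets[settings == "vertical_central"]
  )
  battery <- suppressWarnings(run_fig_battery(inc, use, n_null = n_null, seed = seed + 1L))

  hit <- if (scenario == "deep_turnover") {
    tot <- battery[battery$statistic == "total", ]
    tur <- battery[battery$statistic == "turnover", ]
    nes <- battery[battery$statistic == "nestedness", ]
    sig <- tot$p_value < 0.05 & tot$observed > tot$null_mean
    any(sig) && mean(tot$observed > tot$null_mean) > 0.5 &&
      all(tur$observed[sig] > nes$observed[sig])
  } else if (scenario == "nested_central") {
    tot <- battery[battery$setting == "vertical_central" & battery$statistic == "total", ]
    nes <- battery[battery$setting == "vertical_central" & battery$statistic == "nestedness", ]
    tot$p_value < 0.05 && tot$observed < tot$null_mean && nes$observed > nes$null_mean
  } else { # bfn_random: recovery = no rejection of the vertical-central test
    tot <- battery[battery$setting == "vertical_central" & battery$statistic == "total", ]
    tot$p_value >= 0.05
  }
  list(recovered = hit, battery = battery)
}

#' Scenario-recovery rate over seeded replicates
#'
#' @inheritParams recover_scenario
#' @param n_rep Number of replicate data sets (default 100).
#' @param seed Base seed; replicate i uses \code{seed + i}.
#' @return Proportion of replicates recovered, with attribute \code{hits}.
#' @export
recovery_rate <- function(scenario, n_rep = 100L, n_null = 999L, seed = 1L,
                          effect_size = 0.6, ...) {
  hits <- vapply(seq_len(n_rep), function(i) {
    recover_scenario(scenario, seed = seed + i * 1000L, n_null = n_null,
                     effect_size = effect_size, ...)$recovered
  }, logical(1L))
  structure(mean(hits), hits = hits)
}

#' Type-I-error calibration of the null test
#'
#' Generates data by the null process itself (\code{bfn_random}, which
#' places a fixed number of presences uniformly at random — the same
#' process [randomize_matrix()] uses) and measures how often the total-BD
#' null test of a single horizontal stratum set rejects at level
#' \code{alpha}. For a well-calibrated two-sided add-one permutation
#' p-value this frequency is close to (and not above) \code{alpha}; a
#' single multiple-site set is used because its statistic is computed from
#' small-integer aggregates, which is the discreteness regime the test must
#' handle.
#'
#' @param n_rep Number of replicate data sets (default 200).
#' @param n_null Null matrices per test (default 999).
#' @param seed Base seed.
#' @param alpha Nominal level (default 0.05).
#' @return Observed rejection frequency, with attribute \code{p_values}.
#' @export
null_rejection_rate <- function(n_rep = 200L, n_null = 999L, seed = 1L,
                                alpha = 0.05) {
  p <- vapply(seq_len(n_rep), function(i) {
    dat <- generate_scenario(scenario_spec("bfn_random", seed = seed + i * 1000L))
    sets <- suppressWarnings(build_horizontal_sets(dat$units))
    nt <- suppressWarnings(null_test(dat$incidence, sets[[1L]], n_null = n_null,
                                     seed = seed + i * 1000L + 1L))
    nt$total$p_value
  }, numeric(1L))
  structure(mean(p < alpha), p_values = p)
}
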