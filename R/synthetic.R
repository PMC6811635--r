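# Synthetic community data with the statistical structure each assembly
# hypothesis implies, plus plausible trap effort and 3D geometry, so every
# pipeline stage runs without field data.

#' Specify a synthetic assembly scenario
#'
#' The default design mirrors a typical deep-karst survey: five slope caves,
#' five shallow-upper sampling units (the entrance strata of the central
#' caves) and ten deep-core units (five depth strata in each of two deep
#' caves), with 34 obligate subterranean species. Four scenarios are
#' available:
#' \describe{
#'   \item{\code{bfn_random}}{presences placed uniformly at random over all
#'     cells with exactly \code{fill} occurrences — the fissure-network null
#'     hypothesis, and identical to the null generator used by
#'     [randomize_matrix()];}
#'   \item{\code{deep_turnover}}{a fraction \code{effect_size} of the species
#'     pool is made exclusive to the deep-core units, each such species
#'     occupying the deep column of a single cave — raising turnover among
#'     deep units of different caves;}
#'   \item{\code{nested_central}}{shallow-upper communities are random
#'     subsets of the pooled deep-core community of their cave (or of the
#'     whole deep core for caves without deep strata) — the
#'     shallow-nested-in-deep hypothesis;}
#'   \item{\code{slope_distinct}}{slope communities draw from a species
#'     subpool that the rest of the massif avoids (with a few core slope
#'     species present in nearly every slope cave), mirroring a
#'     thermally/ecologically distinct slope fauna.}
#' }
#' \code{effect_size} interpolates between pure randomness (0, every
#' scenario collapses to \code{bfn_random} structure) and the fully
#' deterministic structure (1).
#'
#' @param scenario One of \code{"bfn_random"}, \code{"deep_turnover"},
#'   \code{"nested_central"}, \code{"slope_distinct"}.
#' @param n_species Number of obligate species (default 34).
#' @param n_shallow,n_deep_caves,n_strata_per_deep_cave,n_slope Unit design
#'   (defaults 5, 2, 5, 5 giving 20 units).
#' @param n_non_obligate Number of additional non-obligate species carried
#'   through the raw data (default 26; removed by [filter_obligates()]).
#' @param occupancy Per-cell presence probability governing expected
#'   richness (default 0.3, giving per-unit richness roughly 4–18 of 34).
#' @param fill Total number of presences for \code{bfn_random} (default
#'   \code{round(occupancy * n_species * n_units)}).
#' @param effect_size Strength of scenario structure in \code{[0, 1]}
#'   (default 0.6).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return A validated list of class \code{kb_scenario_spec}.
#' @export
scenario_spec <- function(scenario = c("bfn_random", "deep_turnover",
                                       "nested_central", "slope_distinct"),
                          n_species = 34L, n_shallow = 5L, n_deep_caves = 2L,
                          n_strata_per_deep_cave = 5L, n_slope = 5L,
                          n_non_obligate = 26L, occupancy = 0.3, fill = NULL,
                          effect_size = 0.6, seed = NULL) {
  scenario <- match.arg(scenario)
  if (effect_size < 0 || effect_size > 1) {
    kb_value_error("effect_size must lie in [0, 1]")
  }
  if (n_species < 1L || n_shallow < 1L || n_deep_caves < 1L ||
      n_strata_per_deep_cave < 1L || n_slope < 1L) {
    kb_value_error("all design counts must be positive")
  }
  if (n_deep_caves > n_shallow) {
    kb_value_error("deep caves are a subset of the central caves (n_deep_caves <= n_shallow)")
  }
  n_units <- n_shallow + n_deep_caves * n_strata_per_deep_cave + n_slope
  if (is.null(fill)) fill <- round(occupancy * n_species * n_units)
  if (fill < 1L || fill > n_species * n_units) {
    kb_value_error("fill must lie in [1, n_species * n_units]")
  }
  structure(list(
    scenario = scenario, n_species = as.integer(n_species),
    n_shallow = as.integer(n_shallow), n_deep_caves = as.integer(n_deep_caves),
    n_strata_per_deep_cave = as.integer(n_strata_per_deep_cave),
    n_slope = as.integer(n_slope), n_non_obligate = as.integer(n_non_obligate),
    n_units = as.integer(n_units), occupancy = occupancy,
    fill = as.integer(fill), effect_size = effect_size, seed = seed
  ), class = "kb_scenario_spec")
}

# sample() without the scalar-x surprise: always samples from the elements
# of x, even when x has length one.
kb_sample <- function(x, k) x[sample.int(length(x), k)]

# Unit table of the synthetic massif: central caves on the plateau (one
# shallow entrance stratum each, the first n_deep_caves carrying a full deep
# column), slope caves laterally offset at lower altitude. Slope caves get
# explicit stratum labels from their entrance depth below the massif top,
# which places them in the deeper strata of the horizontal analysis.
synthetic_units <- function(spec) {
  top_alt <- 1190
  deep_strata <- KB_STRATA[-1L][seq_len(spec$n_strata_per_deep_cave)]
  stratum_mid <- c("0-50" = 25, "50-100" = 75, "100-200" = 150,
                   "200-330" = 265, "330-500" = 415, ">500" = 600)
  rows <- list()
  for (i in seq_len(spec$n_shallow)) {
    cave <- sprintf("C%d", i)
    cx <- stats::runif(1, 0, 3000); cy <- stats::runif(1, 0, 3000)
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = sprintf("%s_0-50", cave), cave_code = cave,
      zone = "shallow_upper", depth_m = 25,
      x = cx, y = cy, z = top_alt - 25,
      n_traps = sample(6:20, 1L),
      passage_length_m = round(stats::runif(1, 30, 200)),
      stratum = "0-50", stringsAsFactors = FALSE
    )
    if (i <= spec$n_deep_caves) {
      for (s in deep_strata) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = sprintf("%s_%s", cave, s), cave_code = cave,
          zone = "deep_core", depth_m = stratum_mid[[s]],
          x = cx + stats::runif(1, -50, 50), y = cy + stats::runif(1, -50, 50),
          z = top_alt - stratum_mid[[s]],
          n_traps = sample(6:30, 1L),
          passage_length_m = round(stats::runif(1, 40, 1700)),
          stratum = s, stringsAsFactors = FALSE
        )
      }
    }
  }
  for (i in seq_len(spec$n_slope)) {
    alt <- stats::runif(1, 250, 900)
    depth <- round(stats::runif(1, 10, 50))
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = sprintf("S%d", i), cave_code = sprintf("S%d", i),
      zone = "slope", depth_m = depth,
      x = stats::runif(1, 4000, 6500), y = stats::runif(1, 0, 3000),
      z = alt - depth / 2,
      n_traps = sample(6:15, 1L),
      passage_length_m = round(stats::runif(1, 20, 450)),
      stratum = assign_stratum(top_alt - alt), stringsAsFactors = FALSE
    )
  }
  validate_units(do.call(rbind, rows))
}

# Scenario-specific obligate incidence matrix (species x units).
synthetic_incidence <- function(spec, units) {
  n_sp <- spec$n_species
  sp_ids <- sprintf("sp%02d", seq_len(n_sp))
  uid <- units$unit_id
  m <- matrix(0L, n_sp, length(uid), dimnames = list(sp_ids, uid))
  occ <- spec$occupancy
  eff <- spec$effect_size
  deep_units <- units$unit_id[units$zone == "deep_core"]
  slope_units <- units$unit_id[units$zone == "slope"]
  shallow_units <- units$unit_id[units$zone == "shallow_upper"]

  if (spec$scenario == "bfn_random") {
    m[sample.int(length(m), spec$fill)] <- 1L
    return(m)
  }

  if (spec$scenario == "deep_turnover") {
    # Exclusive species are vertically continuous residents of one cave's
    # deep column: replacement happens between caves, not within them.
    n_excl <- round(eff * n_sp)
    excl <- seq_len(n_excl)
    caves <- sort(unique(units$cave_code[units$zone == "deep_core"]))
    cave_of <- rep(caves, length.out = n_excl)  # round-robin over deep caves
    for (k in seq_along(excl)) {
      col_units <- deep_units[units$cave_code[match(deep_units, units$unit_id)] == cave_of[k]]
      m[excl[k], col_units] <- 1L
    }
    bg <- setdiff(seq_len(n_sp), excl)
    if (length(bg)) {
      m[bg, ] <- (matrix(stats::runif(length(bg) * length(uid)),
                         length(bg)) < occ) + 0L
    }
  } else if (spec$scenario == "nested_central") {
    # Funnelling model: each deep cave column collects a species pool
    # (deep vertical caves act as collectors of the surrounding fissure
    # fauna) whose members are vertically continuous along the column —
    # a pool species occupies most strata of its cave. Shallow communities
    # are thinner subsamples of the realized deep communities, favouring
    # species that accumulated in many deep units. Slope caves are plain
    # random background. Within-column occupancy q rises with effect_size
    # while the pool shrinks as occ/q, keeping expected deep richness at
    # the background level and collapsing to uniform randomness at 0.
    q_deep <- occ + (0.7 - occ) * eff
    pool_prob <- min(1, occ / q_deep)
    caves <- sort(unique(units$cave_code[units$zone == "deep_core"]))
    for (cave in caves) {
      pool <- which(stats::runif(n_sp) < pool_prob)
      col_units <- deep_units[units$cave_code[match(deep_units, units$unit_id)] == cave]
      for (u in col_units) {
        pres <- pool[stats::runif(length(pool)) < q_deep]
        m[pres, u] <- 1L
      }
    }
    m[, slope_units] <- (matrix(stats::runif(n_sp * length(slope_units)), n_sp) < occ) + 0L
    for (su in shallow_units) {
      cave <- units$cave_code[units$unit_id == su]
      own_deep <- deep_units[units$cave_code[match(deep_units, units$unit_id)] == cave]
      donor_units <- if (length(own_deep)) own_deep else deep_units
      k_occ <- rowSums(m[, donor_units, drop = FALSE])  # funnelling weight
      # shallow entrance communities are thinner subsamples of the deep
      # collector columns, so their richness sits below the deep background
      r <- stats::rbinom(1L, n_sp, occ * (1 - 2 / 3 * eff))
      n_funnel <- stats::rbinom(1L, r, eff)
      donors <- which(k_occ > 0)
      from_deep <- if (length(donors)) {
        donors[sample.int(length(donors), min(n_funnel, length(donors)),
                          prob = k_occ[donors])]
      } else integer()
      free <- setdiff(seq_len(n_sp), from_deep)
      # at effect_size 1 the shallow community is a strict subsample of the
      # deep one, never topped up with outside species
      from_free <- if (eff >= 1) integer() else {
        kb_sample(free, min(r - length(from_deep), length(free)))
      }
      m[c(from_deep, from_free), su] <- 1L
    }
  } else if (spec$scenario == "slope_distinct") {
    # A slope species subpool the central massif avoids, and vice versa;
    # each side carries a few "core" widespread species (ubiquitous slope
    # fauna vs. ubiquitous massif fauna) whose occupancy grows to 1 at full
    # effect, so fully distinct faunas still cohere within their zone.
    subpool <- seq_len(max(3L, round(0.4 * n_sp)))
    slope_core <- subpool[seq_len(min(3L, length(subpool)))]
    complement <- setdiff(seq_len(n_sp), subpool)
    central_core <- complement[seq_len(min(3L, length(complement)))]
    p_core <- occ + (1 - occ) * eff
    other <- c(shallow_units, deep_units)
    for (s in seq_len(n_sp)) {
      in_sub <- s %in% subpool
      p_slope <- if (s %in% slope_core) p_core else if (in_sub) occ else occ * (1 - eff)
      p_other <- if (s %in% central_core) p_core else if (in_sub) occ * (1 - eff) else occ
      m[s, slope_units] <- (stats::runif(length(slope_units)) < p_slope) + 0L
      m[s, other] <- (stats::runif(length(other)) < p_other) + 0L
    }
  }

  # Every sampling unit must host at least one species; give empty units one
  # presence drawn from the species allowed there.
  empty <- colnames(m)[colSums(m) == 0L]
  for (u in empty) {
    allowed <- seq_len(n_sp)
    if (spec$scenario == "slope_distinct" && spec$effect_size >= 1) {
      subpool <- seq_len(max(3L, round(0.4 * n_sp)))
      allowed <- if (u %in% slope_units) subpool else setdiff(allowed, subpool)
    }
    if (spec$scenario == "deep_turnover" && !(u %in% deep_units)) {
      allowed <- setdiff(allowed, seq_len(round(eff * n_sp)))
    }
    if (length(allowed)) m[kb_sample(allowed, 1L), u] <- 1L
  }
  m
}

#' Generate a synthetic massif data set
#'
#' Produces everything the pipeline ingests: the obligate incidence matrix
#' with the scenario's structure, a raw count matrix (obligate plus
#' non-obligate species, counts of 1 or more wherever a species is present),
#' the sampling-unit table (zones, strata, depths, 3D coordinates, trap
#' counts and passage lengths) and the species table. Non-obligate species
#' are concentrated in the slope and shallow units, leaving the deep core
#' largely devoid of them.
#'
#' @param spec A \code{kb_scenario_spec} from [scenario_spec()].
#' @return List with elements \code{incidence} (binary obligate matrix),
#'   \code{abundance} (raw integer counts, all species), \code{units},
#'   \code{species}, \code{spec}.
#' @export
generate_scenario <- function(spec) {
  if (!inherits(spec, "kb_scenario_spec")) {
    kb_value_error("spec must come from scenario_spec()")
  }
  with_seed(spec$seed, {
    units <- synthetic_units(spec)
    inc <- synthetic_incidence(spec, units)
    counts <- inc * (1L + stats::rpois(length(inc), 2))
    if (spec$n_non_obligate > 0L) {
      no_ids <- sprintf("ns%02d", seq_len(spec$n_non_obligate))
      p_unit <- ifelse(units$zone == "deep_core", 0.02, 0.25)
      no_inc <- matrix(stats::runif(spec$n_non_obligate * nrow(units)),
                       spec$n_non_obligate) < rep(p_unit, each = spec$n_non_obligate)
      no_counts <- no_inc * (1L + stats::rpois(length(no_inc), 4))
      dimnames(no_counts) <- list(no_ids, units$unit_id)
      counts <- rbind(counts, no_counts)
    }
    species <- data.frame(
      species_id = rownames(counts),
      name = paste("Morphospecies", rownames(counts)),
      eco_class = c(rep("obligate", spec$n_species),
                    rep("non_obligate", spec$n_non_obligate)),
      stringsAsFactors = FALSE
    )
    list(incidence = inc, abundance = abundance_matrix(counts), units = units,
         species = validate_species(species), spec = spec)
  })
}

#' Split pooled counts into seasonal trap samples
#'
#' Inverse of [pool_seasons()] for testing and fixture generation: each
#' positive cell count is split binomially (p = 0.5) between the
#' spring/summer and winter seasons, so pooling the samples recovers the
#' matrix exactly.
#'
#' @param m Raw integer abundance matrix (species x units).
#' @param seed Integer seed.
#' @return data.frame with columns \code{unit_id}, \code{season},
#'   \code{species_id}, \code{count} (only positive counts are emitted).
#' @export
generate_trap_samples <- function(m, seed = NULL) {
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    kb_value_error("counts must be non-negative integers")
  }
  pos <- which(m > 0, arr.ind = TRUE)
  if (!nrow(pos)) {
    return(data.frame(unit_id = character(), season = character(),
                      species_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    totals <- m[pos]
    summer <- stats::rbinom(length(totals), totals, 0.5)
    winter <- totals - summer
    out <- rbind(
      data.frame(unit_id = colnames(m)[pos[, 2L]], season = "spring_summer",
                 species_id = rownames(m)[pos[, 1L]], count = summer,
                 stringsAsFactors = FALSE),
      data.frame(unit_id = colnames(m)[pos[, 2L]], season = "winter",
                 species_id = rownames(m)[pos[, 1L]], count = winter,
                 stringsAsFactors = FALSE)
    )
    out <- out[out$count > 0, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write all four scenarios to disk as CSV fixtures
#'
#' Materializes each scenario (matrix, metadata, species, trap samples) in
#' the exact CSV formats the readers ingest.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer base seed; scenario k uses \code{seed + k}.
#' @param ... Further arguments passed to [scenario_spec()].
#' @return Invisibly, the directory path.
#' @export
write_scenario_fixtures <- function(dir, seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- c("bfn_random", "deep_turnover", "nested_central", "slope_distinct")
  for (k in seq_along(scenarios)) {
    dat <- generate_scenario(scenario_spec(scenarios[k], seed = seed + k, ...))
    base <- file.path(dir, scenarios[k])
    write_matrix_csv(dat$abundance, paste0(base, "_abundance.csv"))
    utils::write.csv(dat$units, paste0(base, "_units.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(dat$species, paste0(base, "_species.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(generate_trap_samples(dat$abundance, seed = seed + k),
                     paste0(base, "_traps.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
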