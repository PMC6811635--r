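# End-to-end orchestration: raw data (or a synthetic scenario) through
# normalization, zone summaries, ANOSIM/UPGMA/Mantel and the observed-vs-null
# beta-diversity battery, into one structured report.

#' Pipeline configuration
#'
#' Either file inputs (\code{abundance_csv} or \code{traps_csv}, plus
#' \code{metadata_csv} and \code{species_csv}) or a synthetic
#' \code{scenario} spec. Defaults mirror the reference analysis: 999
#' permutations for ANOSIM and Mantel, 9,999 null matrices.
#'
#' @param abundance_csv Path to a raw species x unit count matrix, or
#'   \code{NULL} when \code{traps_csv} or \code{scenario} is given.
#' @param traps_csv Path to long-format seasonal trap samples (columns
#'   \code{unit_id}, \code{season}, \code{species_id}, \code{count}).
#' @param metadata_csv Path to the sampling-unit table.
#' @param species_csv Path to the species table.
#' @param scenario A \code{kb_scenario_spec}; overrides the file inputs.
#' @param n_perm_anosim,n_perm_mantel Permutation counts (default 999).
#' @param n_null Null-model replicates (default 9999).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir Optional directory for artifacts (matrices, Newick tree,
#'   JSON report).
#' @param drop_empty_units Drop units with no obligate presences before
#'   analysis (default \code{TRUE}).
#' @param null_method Randomization scheme, see [randomize_matrix()].
#' @return A validated configuration list of class \code{kb_config}.
#' @export
pipeline_config <- function(abundance_csv = NULL, traps_csv = NULL,
                            metadata_csv = NULL, species_csv = NULL,
                            scenario = NULL, n_perm_anosim = 999L,
                            n_perm_mantel = 999L, n_null = 9999L, seed = 1L,
                            out_dir = NULL, drop_empty_units = TRUE,
                            null_method = c("fill", "species_totals")) {
  null_method <- match.arg(null_method)
  if (is.null(scenario)) {
    if (is.null(abundance_csv) && is.null(traps_csv)) {
      kb_value_error("provide abundance_csv or traps_csv, or a synthetic scenario")
    }
    if (is.null(metadata_csv) || is.null(species_csv)) {
      kb_value_error("file-based runs need metadata_csv and species_csv")
    }
  } else if (!inherits(scenario, "kb_scenario_spec")) {
    kb_value_error("scenario must come from scenario_spec()")
  }
  structure(list(
    abundance_csv = abundance_csv, traps_csv = traps_csv,
    metadata_csv = metadata_csv, species_csv = species_csv,
    scenario = scenario, n_perm_anosim = as.integer(n_perm_anosim),
    n_perm_mantel = as.integer(n_perm_mantel), n_null = as.integer(n_null),
    seed = as.integer(seed), out_dir = out_dir,
    drop_empty_units = isTRUE(drop_empty_units), null_method = null_method
  ), class = "kb_config")
}

# Pooled incidence vector of a group of units.
pooled_incidence <- function(inc, unit_ids) {
  (rowSums(inc[, intersect(unit_ids, colnames(inc)), drop = FALSE]) > 0) + 0L
}

#' Zone-level richness and shared-species summary
#'
#' Pools the incidence matrix by massif zone and reports per-zone obligate
#' species richness, the maximum richness pooled per cave, and for each zone
#' pair the shared species count, shared percentage (rounded half-up) and
#' Jaccard dissimilarity.
#'
#' @param inc Binary obligate incidence matrix.
#' @param units Sampling-unit table covering the columns of \code{inc}.
#' @return List with \code{zone_richness} (named vector),
#'   \code{max_cave_richness}, \code{richest_cave} and \code{zone_pairs}
#'   (data.frame).
#' @export
zone_summary <- function(inc, units) {
  units <- units[units$unit_id %in% colnames(inc), , drop = FALSE]
  zones <- KB_ZONES[KB_ZONES %in% units$zone]
  pooled <- vapply(zones, function(z) {
    pooled_incidence(inc, units$unit_id[units$zone == z])
  }, integer(nrow(inc)))
  richness <- colSums(pooled)
  storage.mode(richness) <- "integer"
  cave_rich <- vapply(unique(units$cave_code), function(cc) {
    sum(pooled_incidence(inc, units$unit_id[units$cave_code == cc]))
  }, integer(1L))
  pairs <- utils::combn(zones, 2L)
  zp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    p <- pair_counts(pooled[, pairs[1L, k]], pooled[, pairs[2L, k]])
    data.frame(zone1 = pairs[1L, k], zone2 = pairs[2L, k],
               shared = p$a, shared_percent = shared_percentage(p),
               jaccard = jaccard_dissimilarity(p), stringsAsFactors = FALSE)
  }))
  list(zone_richness = richness,
       max_cave_richness = unname(max(cave_rich)),
       richest_cave = names(cave_rich)[which.max(cave_rich)],
       zone_pairs = zp)
}

#' Run the full analysis chain
#'
#' Executes, in order: data loading (or synthetic generation), seasonal
#' pooling, effort normalization, restriction to obligate species, reduction
#' to presence/absence, zone summaries, Jaccard dissimilarities, pairwise
#' ANOSIM between zones, UPGMA clustering, the Mantel test against 3D
#' Euclidean distances, construction of the vertical and horizontal
#' comparison sets, and the observed-vs-null beta-diversity battery. With an
#' \code{out_dir} every intermediate artifact (normalized matrix, incidence
#' matrix, dissimilarity matrices, Newick dendrogram, comparison sets,
#' battery table, JSON report) is written to disk. Identical seeds give
#' identical reports.
#'
#' @param config A \code{kb_config} from [pipeline_config()].
#' @return The report list (also serialized to \code{out_dir} when given):
#'   elements \code{data}, \code{zones}, \code{anosim}, \code{mantel},
#'   \code{upgma_newick}, \code{bd_battery}, \code{seeds}.
#' @export
run_full <- function(config) {
  if (!inherits(config, "kb_config")) kb_value_error("config must come from pipeline_config()")
  seed <- config$seed
  # Stage seeds are fixed offsets of the master seed so each stage is
  # independently reproducible.
  seeds <- list(anosim = seed + 101L, mantel = seed + 202L, nulls = seed + 303L)

  if (!is.null(config$scenario)) {
    dat <- generate_scenario(config$scenario)
    raw <- dat$abundance; units <- dat$units; species <- dat$species
  } else {
    units <- read_metadata_csv(config$metadata_csv)
    species <- read_species_csv(config$species_csv)
    raw <- if (!is.null(config$traps_csv)) {
      samples <- utils::read.csv(config$traps_csv, stringsAsFactors = FALSE)
      pool_seasons(samples, species$species_id, units$unit_id)
    } else {
      read_abundance_csv(config$abundance_csv)
    }
  }

  norm <- normalize_abundance(raw, units)
  obligate <- filter_obligates(norm, species)
  if (nrow(obligate) == 0L) kb_value_error("no obligate species in the data; nothing to analyse")
  inc <- to_incidence(obligate, drop_empty_units = config$drop_empty_units)
  used_units <- units[units$unit_id %in% colnames(inc), , drop = FALSE]

  zones <- zone_summary(inc, used_units)
  d_comm <- jaccard_matrix(inc)
  groups <- stats::setNames(used_units$zone, used_units$unit_id)
  anosim_tab <- anosim_pairwise(d_comm, groups, n_perm = config$n_perm_anosim,
                                seed = seeds$anosim)
  tree <- upgma(d_comm)
  d_space <- spatial_distance_matrix(used_units)
  mantel <- mantel_spearman(d_comm, d_space[colnames(inc), colnames(inc)],
                            n_perm = config$n_perm_mantel, seed = seeds$mantel)
  sets <- c(build_vertical_sets(used_units), build_horizontal_sets(used_units))
  battery <- run_fig_battery(inc, sets, n_null = config$n_null,
                             seed = seeds$nulls, method = config$null_method)

  report <- list(
    data = list(
      n_species_total = nrow(raw), n_obligate = nrow(obligate),
      n_units = ncol(inc), total_presences = sum(inc),
      scenario = if (is.null(config$scenario)) NULL else config$scenario$scenario
    ),
    zones = list(
      richness = as.list(zones$zone_richness),
      max_cave_richness = zones$max_cave_richness,
      richest_cave = zones$richest_cave,
      pairs = zones$zone_pairs
    ),
    anosim = anosim_tab,
    mantel = list(r = mantel$r, p_value = mantel$p_value,
                  n_permutations = mantel$n_permutations,
                  correlation_method = mantel$correlation_method,
                  seed = seeds$mantel),
    upgma_newick = ape::write.tree(as_phylo_dendrogram(tree)),
    bd_battery = battery,
    seeds = c(list(master = seed), seeds),
    n_perm_anosim = config$n_perm_anosim,
    n_perm_mantel = config$n_perm_mantel,
    n_null = config$n_null
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_matrix_csv(norm, file.path(od, "normalized_abundance.csv"))
    write_matrix_csv(inc, file.path(od, "incidence_obligate.csv"))
    write_matrix_csv(d_comm, file.path(od, "jaccard_dissimilarity.csv"))
    write_matrix_csv(d_space, file.path(od, "spatial_distance.csv"))
    write_newick(tree, file.path(od, "upgma.nwk"))
    utils::write.csv(battery, file.path(od, "bd_battery.csv"), row.names = FALSE)
    sets_df <- do.call(rbind, lapply(sets, function(s) {
      data.frame(set_id = s$set_id, setting = s$setting, unit_id = s$unit_ids,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(sets_df, file.path(od, "comparison_sets.csv"), row.names = FALSE)
    write_report(report, file.path(od, "report.json"))
  }
  report
}

#' Deterministic statistics from a local copy of a deposited data set
#'
#' Runs the deterministic part of the pipeline (zone richness, shared
#' percentages, maximum per-cave richness, pairwise ANOSIM R, Mantel r) on
#' a directory holding \code{abundance.csv}, \code{units.csv} and
#' \code{species.csv} in the package's CSV formats — e.g. a local copy of a
#' published survey archive rearranged into those files. The R statistics do
#' not depend on the permutation stream, so they are reproducible
#' independent of the seed.
#'
#' @param dir Directory containing the three CSV files.
#' @param n_perm Permutations for the (seed-dependent) p-values.
#' @param seed Integer seed.
#' @return The [run_full()] report list.
#' @export
analyze_study_data <- function(dir, n_perm = 999L, seed = 1L) {
  paths <- file.path(dir, c("abundance.csv", "units.csv", "species.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    kb_format_error(sprintf("study data file(s) not found: %s",
                            paste(missing, collapse = ", ")))
  }
  run_full(pipeline_config(
    abundance_csv = paths[1L], metadata_csv = paths[2L], species_csv = paths[3L],
    n_perm_anosim = n_perm, n_perm_mantel = n_perm,
    n_null = 99L, seed = seed
  ))
}
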