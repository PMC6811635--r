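# Readers and writers for the tables, trees and reports the pipeline touches.
# All tabular formats are comma-separated UTF-8 with "." as decimal separator;
# the first row and first column carry labels.

#' Read a species-by-unit abundance matrix from CSV
#'
#' The file must have a header row of sampling-unit ids and a first column of
#' species ids; every other cell is a non-negative count (or a non-negative
#' real for already-normalized matrices).
#'
#' @param path Path to a CSV file.
#' @param normalized Logical; mark the matrix as effort-normalized rather
#'   than raw counts. Default \code{FALSE}.
#' @return A numeric matrix (species in rows, units in columns) with an
#'   attribute \code{normalized}.
#' @seealso [write_matrix_csv()], [normalize_abundance()]
#' @export
read_abundance_csv <- function(path, normalized = FALSE) {
  if (!file.exists(path)) kb_format_error(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) kb_format_error(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    kb_format_error(sprintf("'%s': need at least one species row and one unit column", path))
  }
  species_ids <- as.character(raw[[1L]])
  unit_ids <- colnames(raw)[-1L]
  if (anyDuplicated(species_ids)) {
    kb_format_error(sprintf(
      "duplicated species_id in '%s': %s", path,
      paste(unique(species_ids[duplicated(species_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(unit_ids)) {
    kb_format_error(sprintf(
      "duplicated unit_id in '%s': %s", path,
      paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", ")
    ))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!apply(raw[, -1L, drop = FALSE], 2L, function(col) {
      suppressWarnings(!anyNA(as.numeric(col)))
    }))
    kb_format_error(sprintf(
      "non-numeric abundance value in '%s' (column %s)", path,
      paste(unit_ids[bad], collapse = ", ")
    ))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    kb_format_error(sprintf(
      "missing abundance value in '%s' at species '%s', unit '%s'",
      path, species_ids[idx[1L]], unit_ids[idx[2L]]
    ))
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    kb_format_error(sprintf(
      "negative abundance in '%s' at species '%s', unit '%s'",
      path, species_ids[idx[1L]], unit_ids[idx[2L]]
    ))
  }
  dimnames(vals) <- list(species_ids, unit_ids)
  abundance_matrix(vals, normalized = normalized)
}

#' Construct and validate an abundance matrix
#'
#' @param values Numeric matrix, species in rows, sampling units in columns;
#'   both dimensions must be named with unique ids.
#' @param normalized Logical flag: are the values effort-normalized?
#' @return The validated matrix with attribute \code{normalized}.
#' @export
abundance_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    kb_format_error("abundance matrix must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    kb_format_error("abundance matrix must have species row names and unit column names")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    kb_format_error("abundance matrix row/column labels must be unique")
  }
  if (anyNA(values) || any(values < 0)) {
    kb_format_error("abundance matrix entries must be non-negative and non-missing")
  }
  attr(values, "normalized") <- isTRUE(normalized)
  values
}

#' Read sampling-unit metadata from CSV
#'
#' Required columns: \code{unit_id}, \code{cave_code}, \code{zone},
#' \code{depth_m}, \code{x}, \code{y}, \code{z}, \code{n_traps},
#' \code{passage_length_m}. An optional \code{stratum} column overrides the
#' stratum derived from \code{depth_m} via [assign_stratum()] — explicit
#' values win, which is how slope caves can be placed in deeper strata of the
#' horizontal analysis.
#'
#' @param path Path to a CSV file.
#' @return A \code{data.frame} of validated sampling units, one row per unit.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) kb_format_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_units(raw)
}

#' Validate a sampling-unit table
#'
#' @param units A data.frame with the columns documented in
#'   [read_metadata_csv()].
#' @return The validated (and stratum-completed) data.frame.
#' @export
validate_units <- function(units) {
  required <- c("unit_id", "cave_code", "zone", "depth_m", "x", "y", "z",
                "n_traps", "passage_length_m")
  missing <- setdiff(required, names(units))
  if (length(missing)) {
    kb_format_error(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  }
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) {
    kb_format_error(sprintf(
      "duplicated unit_id: %s",
      paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", ")
    ))
  }
  bad_zone <- setdiff(unique(units$zone), KB_ZONES)
  if (length(bad_zone)) {
    kb_format_error(sprintf(
      "unknown zone label(s) %s; valid zones are: %s",
      paste(sQuote(bad_zone), collapse = ", "), paste(KB_ZONES, collapse = ", ")
    ))
  }
  for (col in c("depth_m", "x", "y", "z", "n_traps", "passage_length_m")) {
    v <- suppressWarnings(as.numeric(units[[col]]))
    if (anyNA(v)) {
      kb_format_error(sprintf("non-numeric value in metadata column '%s'", col))
    }
    units[[col]] <- v
  }
  if (any(units$depth_m < 0)) kb_value_error("depth_m must be non-negative")
  if (any(units$n_traps < 1)) kb_value_error("n_traps must be >= 1 for every unit")
  if (any(units$passage_length_m <= 0)) kb_value_error("passage_length_m must be > 0")
  if (is.null(units$stratum)) {
    units$stratum <- NA_character_
  }
  derive <- is.na(units$stratum) | units$stratum == ""
  if (any(derive)) {
    units$stratum[derive] <- vapply(units$depth_m[derive], assign_stratum, character(1L))
  }
  bad_str <- setdiff(unique(units$stratum), KB_STRATA)
  if (length(bad_str)) {
    kb_format_error(sprintf(
      "unknown stratum label(s) %s; valid strata are: %s",
      paste(sQuote(bad_str), collapse = ", "), paste(KB_STRATA, collapse = ", ")
    ))
  }
  # Central-massif consistency: the entrance stratum belongs to the shallow
  # upper zone, deeper strata to the deep core. Slope caves are exempt (their
  # stratum places them in the massif-wide horizontal analysis).
  central <- units$zone %in% c("shallow_upper", "deep_core")
  mismatch <- central & ifelse(units$stratum == "0-50",
                               units$zone != "shallow_upper",
                               units$zone != "deep_core")
  if (any(mismatch)) {
    kb_value_error(sprintf(
      "zone/stratum mismatch for unit(s) %s: stratum '0-50' implies shallow_upper, deeper strata imply deep_core",
      paste(units$unit_id[mismatch], collapse = ", ")
    ))
  }
  rownames(units) <- NULL
  units
}

#' Read species metadata from CSV
#'
#' Required columns: \code{species_id}, \code{name}, \code{eco_class}
#' (\code{"obligate"} or \code{"non_obligate"}). Every species entering the
#' quantitative analyses must carry an ecological class.
#'
#' @param path Path to a CSV file.
#' @return A validated \code{data.frame} of species records.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) kb_format_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_species(raw)
}

#' Validate a species table
#' @param species data.frame with columns \code{species_id}, \code{name},
#'   \code{eco_class}.
#' @return The validated data.frame.
#' @export
validate_species <- function(species) {
  required <- c("species_id", "eco_class")
  missing <- setdiff(required, names(species))
  if (length(missing)) {
    kb_format_error(sprintf("species table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  species$species_id <- as.character(species$species_id)
  if (anyDuplicated(species$species_id)) {
    kb_format_error(sprintf(
      "duplicated species_id: %s",
      paste(unique(species$species_id[duplicated(species$species_id)]), collapse = ", ")
    ))
  }
  bad <- is.na(species$eco_class) | !(species$eco_class %in% KB_ECO_CLASSES)
  if (any(bad)) {
    kb_value_error(sprintf(
      "species %s lack a valid eco_class (must be one of: %s)",
      paste(species$species_id[bad], collapse = ", "),
      paste(KB_ECO_CLASSES, collapse = ", ")
    ))
  }
  if (is.null(species$name)) species$name <- species$species_id
  rownames(species) <- NULL
  species
}

#' Write a labelled matrix (abundance, incidence or dissimilarity) to CSV
#'
#' @param m A matrix with row and column names.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a UPGMA dendrogram as Newick
#'
#' Branch lengths are parent merge height minus child merge height, so the
#' path length from the root to any leaf equals the root height (the tree is
#' ultrametric). A write-then-read round trip reproduces topology and merge
#' heights to 1e-9.
#'
#' @param tree A dendrogram as returned by [upgma()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso [read_newick()]
#' @export
write_newick <- function(tree, path) {
  phy <- as_phylo_dendrogram(tree)
  if (is.null(phy$tip.label) || anyNA(phy$tip.label) || any(phy$tip.label == "")) {
    kb_format_error("dendrogram has unlabelled leaves; cannot write Newick")
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) kb_format_error(sprintf("file not found: %s", path))
  ape::read.tree(path)
}

#' Convert a UPGMA dendrogram to an ape phylo tree
#' @param tree A dendrogram as returned by [upgma()].
#' @return A \code{phylo} object whose node depths equal the merge heights.
#' @export
as_phylo_dendrogram <- function(tree) {
  if (!inherits(tree, "kb_dendrogram")) {
    kb_format_error("expected a dendrogram produced by upgma()")
  }
  # as.phylo.hclust halves hclust merge heights, which is exactly the
  # ultrametric convention used here (merge height = dissimilarity / 2).
  ape::as.phylo(tree$hclust)
}

#' Write a structured analysis report as JSON
#'
#' One machine-readable document holding every statistic together with its
#' replicate count, seed and p-value convention, plus a provenance header
#' (package version, creation time). Field-for-field recoverable with
#' [read_report()].
#'
#' @param results A named list of result objects (may be empty).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(results, path) {
  if (length(results) && is.null(names(results))) {
    kb_format_error("report results must be a named list")
  }
  doc <- list(
    provenance = list(
      package = "karstbeta",
      version = as.character(utils::packageVersion("karstbeta")),
      p_value_convention = "(count + 1) / (n_perm + 1)",
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    results = results
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) kb_format_error(sprintf("cannot write report to '%s'", path))
  invisible(path)
}

#' Read a structured analysis report
#' @param path Path to a JSON report written by [write_report()].
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) kb_format_error(sprintf("file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}
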