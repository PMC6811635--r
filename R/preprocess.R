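# From raw trap samples to the normalized, obligate-only incidence matrix.

#' Assign a depth stratum label
#'
#' The six vertical bands are 0-50, 50-100, 100-200, 200-330, 330-500 and
#' beyond 500 m below the cave entrance. Intervals are half-open
#' \code{[lower, upper)}, so a depth of exactly 50 m falls in "50-100";
#' ">500" is \code{[500, Inf)}. The entrance stratum "0-50" belongs to the
#' shallow upper zone of the massif, all deeper strata to the deep core.
#'
#' @param depth_m Depth in meters below the cave entrance (non-negative).
#' @return One of \code{"0-50"}, \code{"50-100"}, \code{"100-200"},
#'   \code{"200-330"}, \code{"330-500"}, \code{">500"}.
#' @examples
#' assign_stratum(75)   # "50-100"
#' assign_stratum(850)  # ">500"
#' @export
assign_stratum <- function(depth_m) {
  if (!is.numeric(depth_m) || length(depth_m) != 1L || is.na(depth_m)) {
    kb_value_error("depth_m must be a single number")
  }
  if (depth_m < 0) kb_value_error("depth_m must be non-negative")
  idx <- findInterval(depth_m, KB_STRATUM_BREAKS, rightmost.closed = FALSE)
  KB_STRATA[idx]
}

#' Zone implied by a stratum for central-massif units
#' @param stratum A stratum label.
#' @return \code{"shallow_upper"} for "0-50", \code{"deep_core"} otherwise.
#' @export
zone_of_stratum <- function(stratum) {
  if (!stratum %in% KB_STRATA) {
    kb_value_error(sprintf("unknown stratum '%s'", stratum))
  }
  if (stratum == "0-50") "shallow_upper" else "deep_core"
}

#' Pool seasonal trap samples into a raw abundance matrix
#'
#' Trapping is carried out in a spring/summer and a winter season; samples
#' from both are summed per (species, unit). Units or species present in the
#' reference tables but absent from the samples yield zero cells, so the
#' matrix dimensions are governed by \code{species_ids} and \code{unit_ids}.
#'
#' @param samples data.frame with columns \code{unit_id}, \code{season}
#'   (\code{"spring_summer"} or \code{"winter"}), \code{species_id},
#'   \code{count}. Each (unit, season, species) key must appear at most once:
#'   duplicates must be aggregated upstream.
#' @param species_ids Character vector of all species ids (row order).
#' @param unit_ids Character vector of all unit ids (column order).
#' @return A raw (unnormalized) abundance matrix.
#' @export
pool_seasons <- function(samples, species_ids, unit_ids) {
  required <- c("unit_id", "season", "species_id", "count")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    kb_format_error(sprintf("trap samples missing column(s): %s", paste(missing, collapse = ", ")))
  }
  bad_season <- setdiff(unique(samples$season), KB_SEASONS)
  if (length(bad_season)) {
    kb_value_error(sprintf(
      "unknown season label(s) %s; valid seasons: %s",
      paste(sQuote(bad_season), collapse = ", "), paste(KB_SEASONS, collapse = ", ")
    ))
  }
  unknown_u <- setdiff(unique(samples$unit_id), unit_ids)
  if (length(unknown_u)) {
    kb_reference_error(sprintf("trap samples reference unknown unit_id: %s",
                               paste(unknown_u, collapse = ", ")))
  }
  unknown_s <- setdiff(unique(samples$species_id), species_ids)
  if (length(unknown_s)) {
    kb_reference_error(sprintf("trap samples reference unknown species_id: %s",
                               paste(unknown_s, collapse = ", ")))
  }
  if (nrow(samples)) {
    if (anyNA(samples$count) || any(samples$count < 0) ||
        any(samples$count != floor(samples$count))) {
      kb_value_error("trap sample counts must be non-negative integers")
    }
    key <- paste(samples$unit_id, samples$season, samples$species_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- samples[duplicated(key), , drop = FALSE][1L, ]
      kb_value_error(sprintf(
        "duplicate trap sample for (unit %s, season %s, species %s); aggregate before pooling",
        dup$unit_id, dup$season, dup$species_id
      ))
    }
  }
  m <- matrix(0, length(species_ids), length(unit_ids),
              dimnames = list(species_ids, unit_ids))
  if (nrow(samples)) {
    i <- match(samples$species_id, species_ids)
    j <- match(samples$unit_id, unit_ids)
    for (k in seq_len(nrow(samples))) {
      m[i[k], j[k]] <- m[i[k], j[k]] + samples$count[k]
    }
  }
  abundance_matrix(m, normalized = FALSE)
}

#' Normalize pooled abundances by trapping effort
#'
#' Trap density cannot be held constant across cave passages, so raw pooled
#' counts are corrected to individuals per sampled trap per meter of passage:
#' each cell is divided by (number of traps x surveyed passage length) of its
#' sampling unit. Normalization never changes the zero pattern, so all
#' incidence-based results downstream are invariant to it.
#'
#' @param m A raw abundance matrix (species x units).
#' @param units Sampling-unit table (see [read_metadata_csv()]) supplying
#'   \code{n_traps} and \code{passage_length_m} for every column of \code{m}.
#' @return The normalized abundance matrix (attribute \code{normalized} set).
#' @export
normalize_abundance <- function(m, units) {
  if (isTRUE(attr(m, "normalized"))) {
    kb_value_error("matrix is already normalized")
  }
  idx <- match(colnames(m), units$unit_id)
  if (anyNA(idx)) {
    kb_reference_error(sprintf(
      "missing effort data for unit(s): %s",
      paste(colnames(m)[is.na(idx)], collapse = ", ")
    ))
  }
  effort <- units$n_traps[idx] * units$passage_length_m[idx]
  out <- sweep(m, 2L, effort, `/`)
  abundance_matrix(out, normalized = TRUE)
}

#' Restrict a matrix to obligate subterranean species
#'
#' All quantitative analyses run on obligate subterranean species
#' (troglobionts) only; non-obligate rows are removed, columns are untouched.
#'
#' @param m Abundance or incidence matrix with species row names.
#' @param species Species table (see [read_species_csv()]) classifying every
#'   row of \code{m}.
#' @return The matrix restricted to obligate species rows.
#' @export
filter_obligates <- function(m, species) {
  species <- validate_species(species)
  idx <- match(rownames(m), species$species_id)
  if (anyNA(idx)) {
    kb_reference_error(sprintf(
      "species without eco_class record: %s",
      paste(rownames(m)[is.na(idx)], collapse = ", ")
    ))
  }
  keep <- species$eco_class[idx] == "obligate"
  out <- m[keep, , drop = FALSE]
  attr(out, "normalized") <- attr(m, "normalized")
  out
}

#' Reduce an abundance matrix to presence/absence
#'
#' Beta-diversity analyses use only presence-absence data; any positive
#' abundance becomes 1. Optionally drops sampling units with no presences
#' (which carry no community information and would make Jaccard
#' dissimilarity undefined), with a warning naming them.
#'
#' @param m Non-negative abundance matrix.
#' @param drop_empty_units Drop all-zero columns? Default \code{FALSE}.
#' @return A binary incidence matrix (species x units).
#' @export
to_incidence <- function(m, drop_empty_units = FALSE) {
  if (anyNA(m) || any(m < 0)) kb_value_error("abundance matrix must be non-negative")
  inc <- (m > 0) + 0L
  storage.mode(inc) <- "integer"
  dimnames(inc) <- dimnames(m)
  if (drop_empty_units) {
    empty <- colSums(inc) == 0L
    if (any(empty)) {
      warning(sprintf("dropping empty sampling unit(s): %s",
                      paste(colnames(inc)[empty], collapse = ", ")),
              call. = FALSE)
      inc <- inc[, !empty, drop = FALSE]
    }
  }
  attr(inc, "normalized") <- NULL
  inc
}
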