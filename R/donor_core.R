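#' Extract a donor's core microbiota
#'
#' The core microbiota of a donor is the set of species whose relative
#' abundance strictly exceeds `threshold` in at least one of the donor's
#' samples. It serves as the donor-side reference set when assigning species
#' origins, standing in for the (unsequenced) individual FMT preparations.
#'
#' @param pm a [profile_matrix]; converted to relative abundance if needed.
#' @param design a [study_design] whose sample map identifies donor samples.
#' @param donor_id donor subject id.
#' @param threshold relative-abundance threshold as a proportion
#'   (default 0.001 = 0.1%); membership requires strict `>` in >= 1 sample.
#' @return An object of class `core_donor_set`: list with `donor_id`,
#'   `threshold`, `species` (character vector) and `n_samples_used`.
#' @export
extract_core_set <- function(pm, design, donor_id, threshold = 0.001) {
  stopifnot(inherits(design, "study_design"), length(threshold) == 1,
            threshold > 0)
  if (!donor_id %in% design$subjects$subject_id[design$subjects$role == "donor"])
    stop("unknown donor: ", donor_id)
  smp <- design$sample_map$sample_id[design$sample_map$subject_id == donor_id]
  smp <- intersect(smp, colnames(pm))
  if (length(smp) == 0) stop("donor has no samples in profile: ", donor_id)
  if (!is_relative(pm)) pm <- to_relative_abundance(pm)
  sub <- unclass(pm)[, smp, drop = FALSE]
  keep <- rownames(sub)[apply(sub > threshold, 1, any)]
  structure(list(donor_id = donor_id, threshold = threshold,
                 species = keep, n_samples_used = length(smp)),
            class = "core_donor_set")
}

#' @export
print.core_donor_set <- function(x, ...) {
  cat(sprintf("core_donor_set: donor %s, threshold %.4g%%, %d species (from %d samples)\n",
              x$donor_id, 100 * x$threshold, length(x$species),
              x$n_samples_used))
  invisible(x)
}

#' Core-set threshold sweep
#'
#' Recomputes a donor's core set over a grid of thresholds for sensitivity
#' analysis. Because membership is an existential over per-sample relative
#' abundances, the sets are nested: a higher threshold always yields a subset
#' of a lower one.
#'
#' @inheritParams extract_core_set
#' @param thresholds numeric vector of distinct positive proportions.
#' @return Named list (threshold as name) of [extract_core_set()] results,
#'   ordered by increasing threshold.
#' @export
core_threshold_sweep <- function(pm, design, donor_id,
                                 thresholds = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2)) {
  stopifnot(all(thresholds > 0), !anyDuplicated(thresholds))
  thresholds <- sort(thresholds)
  out <- lapply(thresholds, function(tau)
    extract_core_set(pm, design, donor_id, tau))
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' Write core sets as TSV plus JSON summary
#'
#' @param sets list of `core_donor_set` objects (possibly across donors and
#'   thresholds).
#' @param tsv_path output TSV (`donor_id`, `threshold`, `species_id`).
#' @param json_path optional JSON summary path (set sizes).
#' @return `tsv_path`, invisibly.
#' @export
write_core_sets <- function(sets, tsv_path, json_path = NULL) {
  if (inherits(sets, "core_donor_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(s) {
    if (length(s$species) == 0) return(NULL)
    data.frame(donor_id = s$donor_id, threshold = s$threshold,
               species_id = s$species, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(donor_id = character(), threshold = numeric(),
                       species_id = character())
  utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(sets, function(s)
      list(donor_id = s$donor_id, threshold = s$threshold,
           n_species = length(s$species), n_samples = s$n_samples_used))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
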