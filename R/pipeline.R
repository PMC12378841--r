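# End-to-end orchestration: simulate or ingest -> donor core sets ->
# categorisation -> count models -> abundance analyses, with a file manifest
# and a machine-readable summary.

#' Run the full succession-analysis pipeline
#'
#' Executes every stage on either a simulated study (when `profile_path` is
#' NULL) or profile + metadata files, writing all stage outputs to
#' `out_dir`: donor core sets, category assignments and counts per variant,
#' NB-GLMM results, abundance analyses, a manifest with content hashes, and
#' a JSON summary. Reruns with an identical config produce identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @param profile_path,metadata_path optional input files (TSV profile, CSV
#'   metadata); when NULL a synthetic study is generated.
#' @param schedule visit schedule (data.frame or YAML path).
#' @param sim_overrides named list of [sim_config()] overrides.
#' @param core_threshold donor core relative-abundance threshold.
#' @param variants categoriser variants to run (first one feeds the models).
#' @param shared_policy shared-species policy for origin assignment.
#' @param time_basis,spline_df,covariates,min_week,quad_order model settings,
#'   see [fit_category_models()].
#' @param detect_min presence threshold, see [call_presence()].
#' @return invisible list with all stage objects plus `manifest` and
#'   `summary`.
#' @export
run_pipeline <- function(out_dir, seed = 1, profile_path = NULL,
                         metadata_path = NULL, schedule = default_schedule(),
                         sim_overrides = list(), core_threshold = 0.001,
                         variants = "base",
                         shared_policy = "recipient_priority",
                         time_basis = "spline", spline_df = 3,
                         covariates = c("donor", "sex"), min_week = 0,
                         quad_order = 7, detect_min = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(schedule)) schedule <- read_schedule(schedule)

  if (is.null(profile_path)) {
    cfg <- do.call(sim_config, c(list(seed = seed, schedule = schedule),
                                 sim_overrides))
    sim <- simulate_study(cfg)
    pm <- sim$profile; design <- sim$design; taxonomy <- sim$taxonomy
    write_profile_table(pm, file.path(out_dir, "profile.tsv"))
  } else {
    if (!file.exists(profile_path))
      stop("profile file not found: ", profile_path)
    if (is.null(metadata_path) || !file.exists(metadata_path))
      stop("metadata file not found: ", metadata_path %||% "<missing>")
    pm <- read_profile_table(profile_path)
    design <- read_metadata(metadata_path, schedule)
    taxonomy <- character()
    sim <- NULL
  }

  rel <- to_relative_abundance(pm)
  presence <- call_presence(rel, design, detect_min)
  donor_ids <- design$subjects$subject_id[design$subjects$role == "donor"]
  cores <- lapply(donor_ids, function(d)
    extract_core_set(rel, design, d, core_threshold))
  names(cores) <- donor_ids
  write_core_sets(cores, file.path(out_dir, "core_sets.tsv"),
                  file.path(out_dir, "core_sets.json"))

  assignments <- list(); count_tabs <- list()
  for (v in variants) {
    ca <- categorize_study(presence, cores, design, v, shared_policy)
    assignments[[v]] <- ca
    count_tabs[[v]] <- count_by_category(ca)
    write_category_table(ca, file.path(out_dir,
                                       sprintf("categories_%s.tsv", v)))
    utils::write.table(count_tabs[[v]],
                       file.path(out_dir, sprintf("counts_%s.tsv", v)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  famdist <- family_category_distribution(assignments[[1]], taxonomy)
  utils::write.table(famdist, file.path(out_dir, "family_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  models <- fit_category_models(count_tabs[[1]], design,
                                time_basis = time_basis, df = spline_df,
                                covariates = covariates, min_week = min_week,
                                quad_order = quad_order)
  utils::write.table(models$results, file.path(out_dir, "model_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fitjson <- lapply(models$fits, function(f)
    list(coefficients = as.list(f$coefficients), se = as.list(f$se),
         theta = f$theta, sigma2_u = f$sigma2, loglik = f$loglik,
         converged = f$converged, dropped = f$dropped))
  jsonlite::write_json(fitjson, file.path(out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ab <- abundance_records(rel, design, assignments[[1]])
  traj <- category_abundance_comparison(ab)
  fate <- tryCatch(baseline_abundance_by_fate(ab, assignments[[1]], design),
                   error = function(e) NULL)
  prepost <- pre_post_log_difference(ab, design)
  utils::write.table(traj, file.path(out_dir, "abundance_trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prepost$diffs, file.path(out_dir, "prepost_diffs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = seed,
    n_recipients = length(recipients(design)),
    core_sizes = lapply(cores, function(s) length(s$species)),
    variants = variants,
    core_threshold = core_threshold,
    n_assignment_rows = vapply(assignments, nrow, numeric(1)),
    model_results = models$results,
    mean_prepost_diff = prepost$mean_diff,
    fate_test_p = if (!is.null(fate) && !is.null(fate$fate_test))
      fate$fate_test$p else NA
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(out_dir, full.names = TRUE), character())
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(profile = pm, design = design, presence = presence,
                 cores = cores, assignments = assignments,
                 counts = count_tabs, family_distribution = famdist,
                 models = models, abundance = ab, trajectories = traj,
                 baseline_fate = fate, prepost = prepost, sim = sim,
                 manifest = manifest, summary = summary))
}

#' Human-readable run report
#'
#' Formats the per-category headline Wald table (with significance stars),
#' skipped categories, and — when several runs are supplied — a sensitivity
#' comparison across variants or thresholds.
#'
#' @param models one result of [fit_category_models()], or a named list of
#'   them (e.g. one per variant or threshold).
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly if written.
#' @export
write_report <- function(models, path = NULL) {
  if (!is.null(models$results)) models <- list(run = models)
  lines <- character()
  for (nm in names(models)) {
    m <- models[[nm]]
    lines <- c(lines, sprintf("== %s (time: %s, df %d) ==", nm,
                              m$time_basis, m$spline_df))
    r <- m$results
    for (cc in unique(r$category)) {
      rc <- r[r$category == cc, ]
      flag <- if (!all(rc$converged)) "  [NOT CONVERGED]" else ""
      lines <- c(lines, sprintf("%s%s", cc, flag))
      for (i in seq_len(nrow(rc))) {
        est <- if (is.na(rc$estimate[i])) "" else
          sprintf(" est=%+.3f", rc$estimate[i])
        lines <- c(lines, sprintf(
          "  %-20s%s chisq=%.2f df=%d p=%.3g %s", rc$term_group[i], est,
          rc$chisq[i], rc$df[i], rc$p[i], rc$stars[i]))
      }
    }
    if (length(m$skipped) > 0)
      lines <- c(lines, paste("skipped (too few observations):",
                              paste(m$skipped, collapse = ", ")))
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
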