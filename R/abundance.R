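# Abundance-level analyses: category abundance trajectories, baseline
# abundance by eventual species fate, and pre/post log-abundance differences.
# Inference uses linear mixed models (lme4) with a patient random intercept;
# p-values are Wald normal approximations on the fixed effects.

#' Join relative abundances onto a category assignment
#'
#' @param pm a [profile_matrix]; converted to relative abundance if needed.
#' @param design a [study_design].
#' @param ca category assignment table from [categorize_study()].
#' @return data.frame of abundance records: `recipient`, `species`,
#'   `timepoint`, `week`, `origin`, `category`, `abundance`,
#'   `log_abundance` (natural log; NA where the abundance is zero).
#' @export
abundance_records <- function(pm, design, ca) {
  if (!is_relative(pm)) pm <- to_relative_abundance(pm)
  sm <- design$sample_map
  sm <- sm[!is.na(sm$timepoint), ]
  skey <- paste(sm$subject_id, sm$timepoint)
  samp <- sm$sample_id[match(paste(ca$recipient, ca$timepoint), skey)]
  ab <- unclass(pm)[cbind(match(ca$species, rownames(pm)),
                          match(samp, colnames(pm)))]
  out <- ca[, c("recipient", "species", "timepoint", "week", "origin",
                "category")]
  out$abundance <- ab
  out$log_abundance <- ifelse(ab > 0, log(ab), NA_real_)
  out
}

lmm_fit_safe <- function(formula, data) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  suppressMessages(suppressWarnings(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE, control = ctrl),
             error = function(e) NULL)))
}

lmm_wald <- function(fit) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- b / se
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Compare log-abundances between two categories over time
#'
#' At each timepoint, fits `log_abundance ~ category + (1 | recipient)` to
#' species currently assigned to either category, and reports the log-ratio
#' (category B relative to category A), its standard error and a Wald
#' p-value. Because abundances enter on the natural log scale, the estimate
#' is a proportional difference.
#'
#' @param ab abundance records from [abundance_records()].
#' @param pair character vector of two category names (A = reference).
#' @param per_timepoint if `FALSE`, a single longitudinal model is fitted
#'   instead of one per timepoint.
#' @param min_obs minimum observations per category per timepoint.
#' @return data.frame per timepoint: `timepoint`, `week`, `n_a`, `n_b`,
#'   `estimate`, `se`, `p`, `stars`; skipped timepoints carried in the
#'   `skipped` attribute.
#' @export
category_abundance_comparison <- function(ab,
                                          pair = c("Resident",
                                                   "Recipient transient"),
                                          per_timepoint = TRUE, min_obs = 3) {
  stopifnot(length(pair) == 2)
  d <- ab[!is.na(ab$category) & ab$category %in% pair &
            !is.na(ab$log_abundance), , drop = FALSE]
  d$category <- factor(d$category, levels = pair)
  if (!per_timepoint) {
    fit <- lmm_fit_safe(log_abundance ~ category + (1 | recipient), d)
    if (is.null(fit)) stop("longitudinal abundance model failed")
    w <- lmm_wald(fit)
    row <- w[grepl("^category", w$term), ]
    return(data.frame(timepoint = "all", week = NA_real_,
                      n_a = sum(d$category == pair[1]),
                      n_b = sum(d$category == pair[2]),
                      estimate = row$estimate, se = row$se, p = row$p,
                      stars = star_code(row$p), stringsAsFactors = FALSE))
  }
  tps <- unique(d[, c("timepoint", "week")])
  tps <- tps[order(tps$week), ]
  out <- list(); skipped <- character()
  for (i in seq_len(nrow(tps))) {
    dt <- d[d$timepoint == tps$timepoint[i], ]
    na <- sum(dt$category == pair[1]); nb <- sum(dt$category == pair[2])
    if (na < min_obs || nb < min_obs) {
      skipped <- c(skipped, tps$timepoint[i]); next
    }
    fit <- lmm_fit_safe(log_abundance ~ category + (1 | recipient), dt)
    if (is.null(fit)) { skipped <- c(skipped, tps$timepoint[i]); next }
    w <- lmm_wald(fit)
    row <- w[grepl("^category", w$term), ]
    out[[i]] <- data.frame(timepoint = tps$timepoint[i], week = tps$week[i],
                           n_a = na, n_b = nb, estimate = row$estimate,
                           se = row$se, p = row$p, stars = star_code(row$p),
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(timepoint = character(), week = numeric(), n_a = integer(),
               n_b = integer(), estimate = numeric(), se = numeric(),
               p = numeric(), stars = character())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Eventual fate of each species in each recipient
#'
#' Collapses a species' category series into a single fate: `resident`
#' (stable category at every categorised timepoint), `transient` (ever
#' assigned an intermittent category), or `lost` (ever assigned a loss
#' category without ever being transient). Species never categorised get NA.
#'
#' @param ca category assignment table from [categorize_study()].
#' @return data.frame `recipient`, `species`, `origin`, `fate`.
#' @export
species_fates <- function(ca) {
  cats <- ecological_categories()
  tr <- as.vector(cats[, "transient"]); lo <- as.vector(cats[, "loss"])
  key <- paste(ca$recipient, ca$species, sep = "\r")
  ever_tr <- tapply(ca$category %in% tr, key, any)
  ever_lo <- tapply(ca$category %in% lo, key, any)
  any_cat <- tapply(!is.na(ca$category), key, any)
  u <- !duplicated(key)
  fate <- ifelse(!any_cat[key[u]], NA_character_,
          ifelse(ever_tr[key[u]], "transient",
          ifelse(ever_lo[key[u]], "lost", "resident")))
  data.frame(recipient = ca$recipient[u], species = ca$species[u],
             origin = ca$origin[u], fate = fate, stringsAsFactors = FALSE)
}

#' Baseline abundance by eventual species fate
#'
#' Tests whether species with higher pre-FMT relative abundance are more
#' likely to persist. For recipient-derived species, the pre-FMT log-abundance
#' is modelled as `log_abundance ~ fate * response + (1 | recipient)`; the
#' fate effect (joint Wald over fate levels) and the fate-by-response
#' interaction are reported alongside group summaries.
#'
#' @param ab abundance records from [abundance_records()].
#' @param ca category assignment table (same run as `ab`).
#' @param response named character vector recipient -> response label, or a
#'   [study_design] to take the labels from; NULL fits a fate-only model.
#' @param origin which origin's species to analyse (default recipient).
#' @param pre_weeks weeks counting as pre-FMT reference (default <= 0; the
#'   latest such sample with a nonzero abundance is used per species).
#' @return list with `data` (per-species baseline log-abundance and fate),
#'   `summary` (group means), `wald` (fixed-effect table), `fate_test` and
#'   `interaction_test` (joint Wald rows), `fit` (the lmer object).
#' @export
baseline_abundance_by_fate <- function(ab, ca, response = NULL,
                                       origin = "recipient",
                                       pre_weeks = 0) {
  fates <- species_fates(ca[ca$origin == origin, , drop = FALSE])
  pre <- ab[ab$origin == origin & ab$week <= pre_weeks &
              !is.na(ab$log_abundance), , drop = FALSE]
  if (nrow(pre) == 0) stop("no pre-FMT abundance records")
  # latest pre-FMT sample with nonzero abundance, per recipient x species
  pre <- pre[order(pre$recipient, pre$species, -pre$week), ]
  pre <- pre[!duplicated(paste(pre$recipient, pre$species)), ]
  d <- merge(pre[, c("recipient", "species", "log_abundance")], fates,
             by = c("recipient", "species"))
  d <- d[!is.na(d$fate), , drop = FALSE]
  d$fate <- factor(d$fate, levels = c("resident", "transient", "lost"))
  d <- droplevels(d)
  if (inherits(response, "study_design"))
    response <- stats::setNames(response$subjects$response,
                                response$subjects$subject_id)
  d$response <- if (is.null(response)) NA_character_
                else unname(response[d$recipient])
  has_resp <- length(unique(stats::na.omit(d$response))) >= 2
  summary_tab <- if (has_resp)
    stats::aggregate(log_abundance ~ fate + response, data = d, FUN = mean)
  else stats::aggregate(log_abundance ~ fate, data = d, FUN = mean)
  fml <- if (has_resp) log_abundance ~ fate * response + (1 | recipient)
         else log_abundance ~ fate + (1 | recipient)
  fit <- lmm_fit_safe(fml, d)
  if (is.null(fit)) stop("baseline-by-fate mixed model failed")
  w <- lmm_wald(fit)
  V <- as.matrix(stats::vcov(fit))
  joint <- function(pattern) {
    idx <- grepl(pattern, w$term)
    if (!any(idx)) return(NULL)
    b <- w$estimate[idx]
    Vi <- solve(V[idx, idx, drop = FALSE])
    stat <- drop(t(b) %*% Vi %*% b)
    data.frame(chisq = stat, df = sum(idx),
               p = stats::pchisq(stat, sum(idx), lower.tail = FALSE))
  }
  list(data = d, summary = summary_tab, wald = w,
       fate_test = joint("^fate[^:]*$"),
       interaction_test = joint(":"), fit = fit)
}

#' Pre/post log-abundance differences for resident species
#'
#' For every eligible recipient (completed the FMT course and has at least
#' one post-FMT sample) and every recipient-derived species present at both
#' the pre-FMT reference sample and the last available post-FMT sample,
#' computes `ln(post) - ln(pre)`. On the log scale these differences are
#' proportional changes. A linear mixed model `diff ~ response +
#' (1 | recipient)` tests for a responder/non-responder difference.
#'
#' @param ab abundance records from [abundance_records()].
#' @param design a [study_design].
#' @param completed_week recipients must have an observed sample at or after
#'   this week to count as having completed the FMT course (default 4, the
#'   week of the fourth weekly FMT).
#' @param pre_week week of the preferred pre-FMT reference sample (default 0,
#'   falling back to the earliest pre-FMT sample when absent).
#' @return list with `diffs` (per-species table with `diff`), `wald`
#'   (fixed-effect tests from the LMM, or NULL if it cannot be fit),
#'   `mean_diff`, `excluded` (recipient ids), `fit`.
#' @export
pre_post_log_difference <- function(ab, design, completed_week = 4,
                                    pre_week = 0) {
  resp_map <- stats::setNames(design$subjects$response,
                              design$subjects$subject_id)
  rec_weeks <- tapply(ab$week, ab$recipient, function(w) sort(unique(w)))
  out <- list(); excluded <- character()
  for (r in names(rec_weeks)) {
    wk <- rec_weeks[[r]]
    post_wk <- wk[wk > 0]
    if (length(post_wk) == 0 || max(wk) < completed_week) {
      excluded <- c(excluded, r); next
    }
    pre_wk <- if (pre_week %in% wk) pre_week else {
      cand <- wk[wk <= 0]
      if (length(cand) == 0) { excluded <- c(excluded, r); next }
      max(cand)
    }
    last_wk <- max(post_wk)
    d <- ab[ab$recipient == r & ab$origin == "recipient", ]
    pre <- d[d$week == pre_wk, c("species", "abundance")]
    post <- d[d$week == last_wk, c("species", "abundance")]
    m <- merge(pre, post, by = "species", suffixes = c("_pre", "_post"))
    m <- m[m$abundance_pre > 0 & m$abundance_post > 0, , drop = FALSE]
    if (nrow(m) == 0) next
    out[[r]] <- data.frame(recipient = r, species = m$species,
                           pre_abundance = m$abundance_pre,
                           post_abundance = m$abundance_post,
                           pre_week = pre_wk, post_week = last_wk,
                           diff = log(m$abundance_post) -
                                  log(m$abundance_pre),
                           response = unname(resp_map[r]),
                           stringsAsFactors = FALSE)
  }
  diffs <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(recipient = character(), species = character(),
               pre_abundance = numeric(), post_abundance = numeric(),
               pre_week = numeric(), post_week = numeric(), diff = numeric(),
               response = character())
  rownames(diffs) <- NULL
  fit <- NULL; wald <- NULL
  if (nrow(diffs) > 0 &&
      length(unique(stats::na.omit(diffs$response))) >= 2) {
    dd <- diffs[diffs$response %in% c("responder", "non_responder"), ]
    dd$response <- factor(dd$response,
                          levels = c("non_responder", "responder"))
    fit <- lmm_fit_safe(diff ~ response + (1 | recipient), dd)
    if (!is.null(fit)) wald <- lmm_wald(fit)
  }
  list(diffs = diffs, wald = wald, mean_diff = mean(diffs$diff),
       excluded = unique(excluded), fit = fit)
}
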