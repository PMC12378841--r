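# Orchestrates the count models: one NB-GLMM per ecological category (or a
# single combined model with category interactions), time entered as a
# natural spline or linearly, responder main effect and responder-by-time
# interaction, donor and sex as default covariates.

build_model_data <- function(counts, design, min_week = 0) {
  counts <- counts[, intersect(names(counts),
                               c("recipient", "timepoint", "week",
                                 "category", "n")), drop = FALSE]
  subs <- design$subjects[design$subjects$role == "recipient",
                          c("subject_id", "donor_id", "response", "sex",
                            "pretreatment", "age")]
  df <- merge(counts, subs, by.x = "recipient", by.y = "subject_id")
  df <- df[df$week >= min_week, , drop = FALSE]
  df <- df[df$response %in% c("responder", "non_responder"), , drop = FALSE]
  df$response <- factor(df$response, levels = c("non_responder", "responder"))
  df$donor <- factor(df$donor_id)
  df$sex <- factor(df$sex)
  df$pretreatment <- factor(df$pretreatment)
  df[order(df$recipient, df$week, df$category), , drop = FALSE]
}

time_columns <- function(df, time_basis, spline_df) {
  if (time_basis == "linear") {
    tb <- matrix(df$week, ncol = 1, dimnames = list(NULL, "t1"))
    spline_df <- 1
  } else {
    tb <- spline_basis(df$week, df = spline_df)
  }
  list(cols = tb, df = spline_df)
}

usable_covariates <- function(df, covariates) {
  covariates[vapply(covariates, function(v)
    length(unique(stats::na.omit(df[[v]]))) >= 2, logical(1))]
}

headline_wald <- function(fit, tnames) {
  resp <- "responseresponder"
  inter <- paste0(resp, ":", tnames)
  groups <- list(intercept_responders = resp, slope = tnames,
                 slope_responders = inter)
  out <- lapply(names(groups), function(g) {
    tg <- groups[[g]]
    if (!all(tg %in% names(fit$coefficients)))
      return(data.frame(term_group = g, estimate = NA_real_, se = NA_real_,
                        chisq = NA_real_, df = NA_integer_, p = NA_real_,
                        stars = NA_character_, stringsAsFactors = FALSE))
    w <- wald_group_test(fit, tg)
    est <- if (length(tg) == 1) unname(fit$coefficients[tg]) else NA_real_
    se <- if (length(tg) == 1) unname(fit$se[tg]) else NA_real_
    data.frame(term_group = g, estimate = est, se = se, chisq = w$chisq,
               df = w$df, p = w$p, stars = w$stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit count models for every ecological category
#'
#' For each category, fits a negative-binomial GLMM of the per-recipient
#' species count on time (spline or linear), treatment response and their
#' interaction, with donor and sex as covariates and a random intercept per
#' patient, then reports Wald tests for the three headline terms: "intercept
#' responders" (baseline difference between responders and non-responders),
#' "slope" (overall time trend) and "slope responders" (divergence of the
#' trend between groups). In `combined` mode a single model with
#' category-by-time-by-response interactions is fitted and per-category
#' contrasts are reported.
#'
#' @param counts category count table from [count_by_category()].
#' @param design a [study_design].
#' @param time_basis `"spline"` (natural cubic, `df` columns) or `"linear"`.
#' @param df spline degrees of freedom (default 3).
#' @param covariates subject-level covariates to adjust for (default donor
#'   and sex; pretreatment and age can be added).
#' @param mode `"per_category"` (default) or `"combined"`.
#' @param min_week restrict modelling to weeks >= this value (default 0,
#'   i.e. since the first FMT); use `-Inf` to include baseline.
#' @param quad_order quadrature order for the marginal likelihood.
#' @param min_obs categories with fewer rows are skipped with a warning.
#' @param ... passed to [nb_glmm_fit()].
#' @return list with `fits` (per category), `results` (tidy Wald table with
#'   columns category, term_group, estimate, se, chisq, df, p, stars,
#'   converged), `skipped`, and the settings used.
#' @export
fit_category_models <- function(counts, design,
                                time_basis = c("spline", "linear"), df = 3,
                                covariates = c("donor", "sex"),
                                mode = c("per_category", "combined"),
                                min_week = 0, quad_order = 7, min_obs = 10,
                                ...) {
  time_basis <- match.arg(time_basis)
  mode <- match.arg(mode)
  dat <- build_model_data(counts, design, min_week)
  if (nrow(dat) == 0) stop("no modelling rows after filtering")
  tc <- time_columns(dat, time_basis, df)
  dat <- cbind(dat, tc$cols)
  tnames <- colnames(tc$cols)
  if (mode == "combined") return(fit_combined_model(dat, tnames, covariates,
                                                    quad_order, ...))
  cats <- unique(dat$category)
  fits <- list(); skipped <- character(); res <- list()
  for (cc in cats) {
    d <- dat[dat$category == cc, , drop = FALSE]
    if (nrow(d) < min_obs || all(d$n == 0)) {
      skipped <- c(skipped, cc)
      warning("skipping category '", cc, "': too few usable observations")
      next
    }
    covs <- usable_covariates(d, covariates)
    fml <- stats::as.formula(paste(
      "n ~ response * (", paste(tnames, collapse = " + "), ")",
      if (length(covs) > 0) paste("+", paste(covs, collapse = " + ")) else ""))
    fit <- tryCatch(nb_glmm(fml, d, patient = "recipient",
                            quad_order = quad_order, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, cc)
      warning("category '", cc, "' failed to fit: ", conditionMessage(fit))
      next
    }
    fit$fitted_mu <- exp(drop(stats::model.matrix(
      stats::delete.response(stats::terms(fml)), d) %*% fit$coefficients))
    fit$data <- d
    fits[[cc]] <- fit
    hw <- headline_wald(fit, tnames)
    hw <- cbind(category = cc, hw, converged = fit$converged)
    res[[cc]] <- hw
  }
  results <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(category = character(), term_group = character(),
               estimate = numeric(), se = numeric(), chisq = numeric(),
               df = integer(), p = numeric(), stars = character(),
               converged = logical())
  rownames(results) <- NULL
  list(fits = fits, results = results, skipped = skipped,
       time_basis = time_basis, spline_df = tc$df, covariates = covariates,
       mode = "per_category", min_week = min_week)
}

contrast_wald <- function(fit, L) {
  est <- drop(L %*% fit$coefficients)
  V <- L %*% fit$vcov %*% t(L)
  stat <- tryCatch(max(0, drop(t(est) %*% solve(V) %*% est)),
                   error = function(e) NA_real_)
  p <- stats::pchisq(stat, nrow(L), lower.tail = FALSE)
  list(estimate = if (nrow(L) == 1) est else NA_real_,
       se = if (nrow(L) == 1) sqrt(diag(V)) else NA_real_,
       chisq = stat, df = nrow(L), p = p, stars = star_code(p))
}

fit_combined_model <- function(dat, tnames, covariates, quad_order, ...) {
  dat$category <- factor(dat$category)
  covs <- usable_covariates(dat, covariates)
  fml <- stats::as.formula(paste(
    "n ~ category * response * (", paste(tnames, collapse = " + "), ")",
    if (length(covs) > 0) paste("+", paste(covs, collapse = " + ")) else ""))
  fit <- nb_glmm(fml, dat, patient = "recipient", quad_order = quad_order,
                 ...)
  cn <- names(fit$coefficients)
  ref <- levels(dat$category)[1]
  res <- list()
  for (cc in levels(dat$category)) {
    pre <- paste0("category", cc, ":")
    pick <- function(base_terms) {
      # main-effect terms plus this category's interaction with them
      L <- matrix(0, nrow = length(base_terms), ncol = length(cn),
                  dimnames = list(NULL, cn))
      for (i in seq_along(base_terms)) {
        L[i, base_terms[i]] <- 1
        extra <- paste0(pre, base_terms[i])
        if (cc != ref && extra %in% cn) L[i, extra] <- 1
      }
      L
    }
    groups <- list(
      intercept_responders = pick("responseresponder"),
      slope = pick(tnames),
      slope_responders = pick(paste0("responseresponder:", tnames)))
    for (g in names(groups)) {
      cw <- contrast_wald(fit, groups[[g]])
      res[[paste(cc, g)]] <- data.frame(
        category = cc, term_group = g, estimate = cw$estimate, se = cw$se,
        chisq = cw$chisq, df = cw$df, p = cw$p, stars = cw$stars,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(fits = list(combined = fit), results = results,
       skipped = character(), time_basis = if (length(tnames) > 1) "spline"
       else "linear", spline_df = length(tnames), covariates = covariates,
       mode = "combined", min_week = min(dat$week))
}
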