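weeks9 <- c(0, 1, 2, 3, 4, 5, 7, 11, 14)

test_that("natural spline basis behaves as specified", {
  w <- rep(weeks9, 4)
  # df = 1 spans the same space as centred linear time
  b1 <- spline_basis(w, df = 1)
  expect_equal(abs(cor(b1[, 1], w)), 1, tolerance = 1e-12)
  # linear extrapolation beyond the boundary knots
  b <- spline_basis(weeks9, df = 3)
  grid <- seq(20, 40, by = 1)
  bx <- splines::ns(grid, knots = attr(b, "knots"),
                    Boundary.knots = attr(b, "Boundary.knots"))
  for (j in 1:3) {
    d2 <- diff(bx[, j], differences = 2)
    expect_true(all(abs(d2) < 1e-10))
  }
  # permutation equivariance
  set.seed(8)
  perm <- sample(length(w))
  bp <- spline_basis(w[perm], df = 3)
  expect_equal(bp, spline_basis(w, df = 3)[perm, ], ignore_attr = TRUE)
  expect_error(spline_basis(c(1, 2), df = 3), "distinct")
})

test_that("marginal log-likelihood has the right limits and matches dense integration", {
  set.seed(42)
  npat <- 5
  X <- cbind(1, rnorm(npat * 3))
  pid <- rep(seq_len(npat), each = 3)
  beta <- c(1.1, 0.4)
  sim <- simulate_category_counts(beta, 2, 0.3, X, pid, seed = 9)
  y <- sim$y
  # sigma2 = 0 equals the fixed-effects NB log-likelihood
  expect_equal(nb_glmm_loglik(beta, 2, 0, y, X, pid),
               sum(dnbinom(y, size = 2, mu = exp(X %*% beta), log = TRUE)),
               tolerance = 1e-12)
  # theta -> infinity approaches the Poisson log-likelihood
  ysim <- simulate_category_counts(beta, 1e8, 0, X, pid, seed = 10)$y
  expect_equal(nb_glmm_loglik(beta, 1e8, 0, ysim, X, pid),
               sum(dpois(ysim, exp(X %*% beta), log = TRUE)),
               tolerance = 1e-4)
  # AGQ at order 25 agrees with dense numerical integration
  dense_ll <- function(beta, theta, sigma2) {
    sum(vapply(seq_len(npat), function(i) {
      idx <- pid == i
      f <- function(u) vapply(u, function(uu) {
        mu <- exp(drop(X[idx, , drop = FALSE] %*% beta) + uu)
        exp(sum(dnbinom(y[idx], size = theta, mu = mu, log = TRUE)) +
              dnorm(uu, 0, sqrt(sigma2), log = TRUE))
      }, numeric(1))
      log(integrate(f, -12, 12, rel.tol = 1e-12)$value)
    }, numeric(1)))
  }
  for (par in list(c(1.1, 0.4, 2, 0.3), c(0.5, -0.3, 0.7, 1.2))) {
    expect_equal(
      nb_glmm_loglik(par[1:2], par[3], par[4], y, X, pid, quad_order = 25),
      dense_ll(par[1:2], par[3], par[4]), tolerance = 1e-8)
  }
  expect_error(nb_glmm_loglik(beta, 2, 0.3, y + 0.5, X, pid), "integer")
})

test_that("fit reduces to plain NB regression when the random effect is off", {
  skip_if_not_installed("MASS")
  set.seed(14)
  n <- 150
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- simulate_category_counts(c(1.5, 0.6), 1.5, 0, X, seq_len(n),
                                seed = 2)$y
  fit <- nb_glmm_fit(y, X, patient = seq_len(n), sigma2_fixed = 0)
  ref <- MASS::glm.nb(y ~ x, data = data.frame(y = y, x = X[, 2]))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("fit agrees with an independent NB-GLMM implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(77)
  npat <- 40; nt <- 6
  X <- cbind(`(Intercept)` = 1, t = rep(seq_len(nt) - 1, npat))
  pid <- rep(seq_len(npat), each = nt)
  y <- simulate_category_counts(c(2.5, -0.15), 3, 0.2, X, pid, seed = 5)$y
  fit <- nb_glmm_fit(y, X, pid)
  d <- data.frame(y = y, t = X[, 2], pid = pid)
  ref <- glmmTMB::glmmTMB(y ~ t + (1 | pid), data = d,
                          family = glmmTMB::nbinom2)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(fit$sigma2,
               unname(glmmTMB::VarCorr(ref)$cond$pid[1]), tolerance = 0.02)
  expect_equal(fit$theta, glmmTMB::sigma(ref), tolerance = 0.02)
  # refitting the same data gives identical estimates
  fit2 <- nb_glmm_fit(y, X, pid)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_error(nb_glmm_fit(rep(0, 10), cbind(1, rnorm(10)), 1:10),
               "all counts are zero")
})

test_that("Wald group tests match their quadratic-form definition", {
  # zero coefficients give statistic 0 and p = 1
  fake <- list(coefficients = c(a = 0, b = 1), se = c(a = 1, b = 1),
               vcov = diag(2) |> `dimnames<-`(list(c("a", "b"),
                                                   c("a", "b"))))
  w0 <- wald_group_test(fake, "a")
  expect_equal(w0$chisq, 0)
  expect_equal(w0$p, 1)
  # df = 1: p equals the two-sided normal p-value of z = beta / se
  set.seed(31)
  X <- cbind(`(Intercept)` = 1, x = rnorm(120))
  y <- simulate_category_counts(c(1.8, 0.25), 2, 0, X, 1:120, seed = 4)$y
  fit <- nb_glmm_fit(y, X, 1:120, sigma2_fixed = 0)
  w <- wald_group_test(fit, "x")
  z <- fit$coefficients["x"] / fit$se["x"]
  expect_equal(w$p, unname(2 * pnorm(-abs(z))), tolerance = 1e-12)
  # multi-df group equals the explicit quadratic form
  b <- c(0.3, -0.2, 0.15)
  V <- crossprod(matrix(c(0.5, 0.1, 0, 0.2, 0.4, 0.05, 0, 0.1, 0.3), 3))
  nm <- c("t1", "t2", "t3")
  fake3 <- list(coefficients = setNames(b, nm),
                vcov = `dimnames<-`(V, list(nm, nm)))
  w3 <- wald_group_test(fake3, nm)
  expect_equal(w3$chisq, drop(t(b) %*% solve(V) %*% b), tolerance = 1e-10)
  expect_equal(w3$df, 3)
  expect_error(wald_group_test(fit, "nope"), "not in fit")
})

test_that("joint slope Wald statistic is invariant to affine time rescaling", {
  set.seed(55)
  npat <- 30; nt <- 9
  wk <- rep(weeks9, npat)
  pid <- rep(seq_len(npat), each = nt)
  X <- cbind(1, wk / 10)
  y <- simulate_category_counts(c(2.2, -0.4), 3, 0.15, X, pid, seed = 6)$y
  d <- data.frame(n = y, week = wk, recipient = pid)
  fit_with <- function(w) {
    b <- spline_basis(w, df = 3)
    XX <- cbind(`(Intercept)` = 1, b)
    f <- nb_glmm_fit(y, XX, pid)
    wald_group_test(f, c("t1", "t2", "t3"))$chisq
  }
  c1 <- fit_with(wk)
  c2 <- fit_with(3 * wk - 4)
  expect_equal(c1, c2, tolerance = 0.01)
})

test_that("category model orchestration fits, skips and reports", {
  sim <- simulate_study(tiny_sim_config(seed = 5))
  run <- categorize_sim(sim)
  cnt <- count_by_category(run$ca)
  suppressWarnings(
    mods <- fit_category_models(cnt, run$design, time_basis = "linear",
                                min_obs = 12))
  expect_true(all(c("category", "term_group", "p", "stars") %in%
                    names(mods$results)))
  expect_true(all(mods$results$term_group %in%
                    c("intercept_responders", "slope", "slope_responders")))
  # every fitted category reports exactly the three headline rows
  expect_true(all(table(mods$results$category) == 3))
  # skipped + fitted covers the categories present in the counts
  fitted_or_skipped <- union(names(mods$fits), mods$skipped)
  expect_setequal(fitted_or_skipped, unique(cnt$category))
  # report renders without error and mentions each fitted category
  rep_lines <- write_report(mods)
  for (cc in names(mods$fits)) expect_true(any(grepl(cc, rep_lines,
                                                     fixed = TRUE)))
})

test_that("combined-mode contrasts agree with per-category fits on balanced data", {
  # two categories simulated from the same NB-GLMM family
  set.seed(19)
  npat <- 60; nt <- 5
  wk <- rep(0:4, npat)
  pid <- rep(sprintf("R%02d", seq_len(npat)), each = nt)
  resp <- rep(rep(c("non_responder", "responder"), each = nt * npat / 2))
  base <- data.frame(recipient = pid, week = wk, response = resp,
                     stringsAsFactors = FALSE)
  Xr <- cbind(1, as.integer(base$response == "responder"), wk,
              as.integer(base$response == "responder") * wk)
  d1 <- base; d1$category <- "catA"
  d1$n <- simulate_category_counts(c(3, 0.5, -0.1, 0.05), 5, 0.1, Xr,
                                   pid, seed = 1)$y
  d2 <- base; d2$category <- "catB"
  d2$n <- simulate_category_counts(c(2, -0.3, 0.1, -0.05), 5, 0.1, Xr,
                                   pid, seed = 2)$y
  cnt <- rbind(d1, d2)
  cnt$timepoint <- paste0("t", cnt$week)
  subs <- unique(data.frame(subject_id = base$recipient, role = "recipient",
                            donor_id = "D", response = base$response,
                            sex = "female", pretreatment = "placebo",
                            age = 50, stringsAsFactors = FALSE))
  subs <- rbind(subs, data.frame(subject_id = "D", role = "donor",
                                 donor_id = NA, response = "unknown",
                                 sex = NA, pretreatment = NA, age = NA))
  sm <- data.frame(sample_id = paste(cnt$recipient, cnt$timepoint),
                   subject_id = cnt$recipient, timepoint = cnt$timepoint)
  sm <- unique(sm)
  design <- study_design(subs, sm,
                         data.frame(timepoint = paste0("t", 0:4), week = 0:4))
  per <- fit_category_models(cnt, design, time_basis = "linear",
                             covariates = character(0))
  comb <- fit_category_models(cnt, design, time_basis = "linear",
                              covariates = character(0), mode = "combined")
  for (cc in c("catA", "catB")) {
    for (tg in c("intercept_responders", "slope")) {
      ep <- per$results$estimate[per$results$category == cc &
                                   per$results$term_group == tg]
      ec <- comb$results$estimate[comb$results$category == cc &
                                    comb$results$term_group == tg]
      expect_equal(ec, ep, tolerance = 0.15,
                   label = paste("combined", cc, tg))
    }
  }
})
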