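# Negative-binomial GLMM with a single patient-level random intercept,
# fitted by maximising the marginal likelihood with adaptive Gauss-Hermite
# quadrature. NB2 parameterisation: var = mu + mu^2 / theta.

nb_ll_terms <- function(y, eta, theta) {
  mu <- exp(eta)
  lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
    theta * (log(theta) - log(theta + mu)) + y * (eta - log(theta + mu))
}

# d/du and d2/du2 of sum_j log NB(y_j | exp(eta_j + u), theta)
nb_ll_du <- function(y, mu, theta) y - (y + theta) * mu / (theta + mu)
nb_ll_d2u <- function(y, mu, theta) -(y + theta) * theta * mu / (theta + mu)^2

group_sum <- function(x, idx, n) {
  as.vector(rowsum(x, idx, reorder = TRUE))
}

# Per-patient posterior modes of the random intercept (vectorised Newton).
nb_modes <- function(y, eta, theta, sigma2, pid, npat, tol = 1e-10,
                     maxit = 100) {
  u <- numeric(npat)
  for (it in seq_len(maxit)) {
    mu <- exp(eta + u[pid])
    g1 <- group_sum(nb_ll_du(y, mu, theta), pid, npat) - u / sigma2
    g2 <- group_sum(nb_ll_d2u(y, mu, theta), pid, npat) - 1 / sigma2
    step <- g1 / g2
    u <- u - step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta + u[pid])
  h <- -(group_sum(nb_ll_d2u(y, mu, theta), pid, npat) - 1 / sigma2)
  list(u = u, h = h)
}

#' Marginal log-likelihood of the NB-GLMM
#'
#' Computes the marginal log-likelihood of counts under a negative-binomial
#' (NB2) model with log link, fixed effects `beta` and a patient-level
#' Gaussian random intercept with variance `sigma2`, integrating the random
#' effect out by adaptive Gauss-Hermite quadrature centred and scaled at each
#' patient's posterior mode. `quad_order = 1` is the Laplace approximation;
#' `sigma2 = 0` reduces to the fixed-effects NB log-likelihood.
#'
#' @param beta fixed-effect coefficient vector (length = `ncol(X)`).
#' @param theta NB2 dispersion (> 0); the variance is `mu + mu^2 / theta`.
#' @param sigma2 random-intercept variance (>= 0).
#' @param y non-negative integer counts.
#' @param X design matrix.
#' @param patient patient index (factor or vector) aligned with `y`.
#' @param quad_order number of quadrature nodes (>= 1).
#' @return scalar marginal log-likelihood.
#' @export
nb_glmm_loglik <- function(beta, theta, sigma2, y, X, patient,
                           quad_order = 7) {
  stopifnot(quad_order >= 1, theta > 0, sigma2 >= 0)
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers")
  if (!all(is.finite(c(beta, theta, sigma2))))
    stop("non-finite parameters")
  eta <- drop(X %*% beta)
  pid <- as.integer(factor(patient))
  npat <- max(pid)
  if (sigma2 == 0) return(sum(nb_ll_terms(y, eta, theta)))
  md <- nb_modes(y, eta, theta, sigma2, pid, npat)
  gh <- pracma::gaussHermite(quad_order)
  s <- sqrt(2 / md$h)                      # per-patient quadrature scale
  lw <- matrix(NA_real_, npat, quad_order)
  for (k in seq_len(quad_order)) {
    uk <- md$u + s * gh$x[k]
    cond <- group_sum(nb_ll_terms(y, eta + uk[pid], theta), pid, npat)
    lw[, k] <- log(gh$w[k]) + gh$x[k]^2 + cond +
      stats::dnorm(uk, 0, sqrt(sigma2), log = TRUE)
  }
  m <- apply(lw, 1, max)
  sum(m + log(rowSums(exp(lw - m))) + log(s))
}

drop_aliased <- function(X) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(list(X = X, dropped = character()))
  keep <- qrX$pivot[seq_len(qrX$rank)]
  list(X = X[, sort(keep), drop = FALSE],
       dropped = colnames(X)[setdiff(seq_len(ncol(X)), sort(keep))])
}

# deterministic, RNG-stream-preserving jitter directions
jitter_start <- function(p0, k) {
  if (k == 1) return(p0)
  p0 + 0.25 * sin(seq_along(p0) * 2.3 + 1.7 * k)
}

#' Fit the NB-GLMM by adaptive Gauss-Hermite quadrature
#'
#' Maximises [nb_glmm_loglik()] over the fixed effects, log dispersion and log
#' random-intercept standard deviation jointly (quasi-Newton), restarting from
#' jittered initial values and keeping the best likelihood. Standard errors
#' come from the observed information (numerical Hessian) at the optimum.
#' Rank-deficient design columns are dropped with a warning recorded in the
#' fit.
#'
#' @param y non-negative integer counts.
#' @param X design matrix with column names.
#' @param patient patient identifier vector aligned with `y`.
#' @param quad_order quadrature order (1 = Laplace; default 7).
#' @param sigma2_fixed fix the random-intercept variance (e.g. 0 for a plain
#'   NB regression) instead of estimating it.
#' @param theta_fixed fix the NB dispersion instead of estimating it.
#' @param restarts number of jittered starts (deterministic; default 5).
#' @param reltol optimiser relative tolerance.
#' @return object of class `nb_glmm`: list with `coefficients`, `se`, `vcov`
#'   (fixed-effect block), `theta`, `sigma2`, `loglik`, `converged`,
#'   `dropped`, `quad_order`, `nobs`, `npatients`, `vcov_all`, `par_all`.
#' @export
nb_glmm_fit <- function(y, X, patient, quad_order = 7, sigma2_fixed = NULL,
                        theta_fixed = NULL, restarts = 5, reltol = 1e-10) {
  y <- as.numeric(y)
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers")
  if (all(y == 0))
    stop("all counts are zero; a count model cannot be fit to this category")
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  da <- drop_aliased(X)
  if (length(da$dropped) > 0)
    warning("dropping aliased columns: ", paste(da$dropped, collapse = ", "))
  X <- da$X
  p <- ncol(X)
  pid <- as.integer(factor(patient))

  est_theta <- is.null(theta_fixed)
  est_sigma <- is.null(sigma2_fixed)

  # starting values: Poisson GLM for beta, moment estimate for theta
  pois <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  b0 <- pois$coefficients
  b0[!is.finite(b0)] <- 0
  mu0 <- pmax(exp(drop(X %*% b0)), 1e-8)
  excess <- mean(((y - mu0)^2 - mu0) / mu0^2)
  th0 <- if (excess > 1e-3) min(max(1 / excess, 0.05), 100) else 50
  p0 <- c(unname(b0),
          if (est_theta) log(th0),
          if (est_sigma) log(0.4))

  unpack <- function(par) {
    beta <- par[seq_len(p)]
    i <- p
    theta <- if (est_theta) exp(par[(i <- i + 1)]) else theta_fixed
    sigma2 <- if (est_sigma) exp(2 * par[(i <- i + 1)]) else sigma2_fixed
    list(beta = beta, theta = theta, sigma2 = sigma2)
  }
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
    pr <- unpack(par)
    ll <- tryCatch(
      nb_glmm_loglik(pr$beta, pr$theta, pr$sigma2, y, X, pid, quad_order),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  one_fit <- function(start) tryCatch(
    stats::optim(start, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = reltol)),
    error = function(e) NULL)
  best <- one_fit(jitter_start(p0, 1))
  # a converged first start needs only one jittered confirmation run
  n_more <- if (!is.null(best) && best$convergence == 0) min(1, restarts - 1)
            else max(0, restarts - 1)
  for (k in seq_len(n_more) + 1) {
    fit <- one_fit(jitter_start(p0, k))
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) stop("NB-GLMM optimisation failed from every start")

  pr <- unpack(best$par)
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vcov_all <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA_real_, length(best$par),
                                                  length(best$par)))
  else matrix(NA_real_, length(best$par), length(best$par))
  vcov_beta <- vcov_all[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vcov_beta), 0))

  structure(list(
    coefficients = stats::setNames(pr$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = vcov_beta,
    theta = pr$theta,
    sigma2 = pr$sigma2,
    loglik = -best$value,
    # a usable fit needs both optimiser convergence and a proper
    # (finite, positive-definite) observed information
    converged = best$convergence == 0 && all(is.finite(se)),
    dropped = da$dropped,
    quad_order = quad_order,
    nobs = length(y),
    npatients = max(pid),
    par_all = best$par,
    vcov_all = vcov_all
  ), class = "nb_glmm")
}

#' Formula interface to the NB-GLMM fitter
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `n ~ response * t1 + donor + sex`.
#' @param data data.frame containing the model variables.
#' @param patient name of the patient-id column in `data`.
#' @param ... passed to [nb_glmm_fit()].
#' @return an `nb_glmm` fit (with `formula` and `xlevels` recorded).
#' @export
nb_glmm <- function(formula, data, patient = "recipient", ...) {
  vars <- intersect(unique(c(all.vars(formula), patient)), names(data))
  sub <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  mf <- stats::model.frame(formula, sub)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- nb_glmm_fit(y, X, sub[[patient]], ...)
  fit$formula <- formula
  fit
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat(sprintf("nb_glmm: %d obs, %d patients, logLik %.3f%s\n", x$nobs,
              x$npatients, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  theta = %.4g, sigma2_u = %.4g\n", x$theta, x$sigma2))
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "NS")))
}

#' Wald test on a group of coefficients
#'
#' Chi-square Wald statistic `b' V^{-1} b` for a named coefficient group,
#' using the estimated covariance of the fixed effects. For a single
#' coefficient this equals `(beta / se)^2`.
#'
#' @param fit an `nb_glmm` fit (or any list with `coefficients` and `vcov`).
#' @param term_group character vector of coefficient names.
#' @return data.frame with `terms`, `chisq`, `df`, `p`, `stars`.
#' @export
wald_group_test <- function(fit, term_group) {
  miss <- setdiff(term_group, names(fit$coefficients))
  if (length(miss) > 0)
    stop("coefficients not in fit: ", paste(miss, collapse = ", "))
  b <- fit$coefficients[term_group]
  V <- fit$vcov[term_group, term_group, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance for term group"))
  stat <- max(0, drop(t(b) %*% Vi %*% b))
  df <- length(b)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(terms = paste(term_group, collapse = "+"),
             chisq = stat, df = df, p = p, stars = star_code(p),
             stringsAsFactors = FALSE)
}

#' Natural cubic spline basis for the time variable
#'
#' Natural cubic spline with `df` columns, interior knots at quantiles of the
#' observed weeks, and linear extrapolation beyond the boundary knots. With
#' `df = 1` the basis spans the same space as (centred) linear time.
#'
#' @param weeks numeric vector of times (weeks since first FMT).
#' @param df degrees of freedom (columns), >= 1.
#' @param boundary optional boundary knots (defaults to the data range).
#' @return matrix with `df` columns named `t1..tdf`, carrying the knot
#'   attributes needed to re-evaluate the basis at new times.
#' @export
spline_basis <- function(weeks, df = 3, boundary = NULL) {
  stopifnot(df >= 1)
  if (length(unique(weeks)) < df + 1)
    stop("need at least df + 1 distinct time values for a df-column spline")
  b <- if (is.null(boundary)) splines::ns(weeks, df = df)
       else splines::ns(weeks, df = df, Boundary.knots = boundary)
  colnames(b) <- paste0("t", seq_len(df))
  b
}
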