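# Gamma-Poisson shrinker: observed counts a_i ~ Poisson(lambda_i * E_i)
# with lambda_i drawn from a two-component gamma mixture
#   w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)
# (shape/rate). Marginally a_i is a mixture of negative binomials; the
# prior is fitted by maximizing the marginal likelihood, and each pair's
# posterior is again a two-component gamma mixture.

mgps_expected <- function(tables) {
  n <- tables$a + tables$b + tables$c + tables$d
  (tables$a + tables$b) * (tables$a + tables$c) / n
}

# log marginal P(a | E) for one NB component, shape alpha, rate beta:
# dnbinom(a, size = alpha, prob = beta / (beta + E))
log_nb <- function(a, e, alpha, beta) {
  dnbinom(a, size = alpha, prob = beta / (beta + e), log = TRUE)
}

mgps_loglik <- function(theta, a, e) {
  alpha1 <- exp(theta[1]); beta1 <- exp(theta[2])
  alpha2 <- exp(theta[3]); beta2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  if (!all(is.finite(c(alpha1, beta1, alpha2, beta2)))) return(-Inf)
  ll <- suppressWarnings(
    logsumexp2(log(w) + log_nb(a, e, alpha1, beta1),
               log1p(-w) + log_nb(a, e, alpha2, beta2)))
  if (anyNA(ll)) return(-Inf)
  sum(ll)
}

mgps_starts <- function() {
  # fixed multi-starts: (alpha1, beta1, alpha2, beta2, w)
  list(c(0.2, 0.1, 2, 4, 1 / 3),
       c(1, 1, 1, 1, 0.5),
       c(0.5, 0.5, 5, 5, 0.2),
       c(2, 2, 0.2, 0.2, 0.8),
       c(0.1, 0.05, 10, 10, 0.1))
}

#' Fit the gamma-mixture prior of the gamma-Poisson shrinker
#'
#' Maximizes the marginal likelihood of the observed pair counts under
#' `a_i ~ Poisson(lambda_i E_i)`, `lambda_i ~ w Gamma(alpha1, beta1) +
#' (1-w) Gamma(alpha2, beta2)` (shape/rate parameterization; the
#' marginal is a two-component negative-binomial mixture). Expected
#' counts use the row-by-column convention `E = (a+b)(a+c)/N`.
#' Optimization is quasi-Newton (BFGS) on log parameters (logit for
#' `w`) from five fixed starting points; deterministic given data.
#'
#' @param tables tibble of 2x2 tables (`a`, `b`, `c`, `d`) for all
#'   drug-event pairs, or a tibble already carrying `a` and `expected`.
#' @param min_pairs minimum number of pairs required.
#' @param components 2 for the usual mixture; 1 fits a single gamma
#'   prior (`w` reported as 1).
#' @return an `mgps_prior`: list with `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `w`, `log_marginal_likelihood`, `n_pairs`, `convergence`.
#' @export
fit_mgps_prior <- function(tables, min_pairs = 2, components = 2) {
  if ("expected" %in% names(tables)) {
    a <- tables$a; e <- tables$expected
  } else {
    a <- tables$a; e <- mgps_expected(tables)
  }
  keep <- !is.na(a) & !is.na(e) & e > 0
  a <- a[keep]; e <- e[keep]
  if (length(a) < min_pairs) {
    abort("need at least two drug-event pairs with positive expected counts")
  }
  if (components == 1) {
    obj <- function(th) {
      alpha <- exp(th[1]); beta <- exp(th[2])
      if (!all(is.finite(c(alpha, beta)))) return(Inf)
      ll <- suppressWarnings(sum(log_nb(a, e, alpha, beta)))
      if (is.nan(ll)) Inf else -ll
    }
    fits <- lapply(mgps_starts(), function(s) {
      tryCatch(optim(log(s[1:2]), obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
               error = function(err) NULL)
    })
    fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
    if (length(fits) == 0) abort("gamma prior fit failed from every start")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    return(structure(list(
      alpha1 = exp(best$par[1]), beta1 = exp(best$par[2]),
      alpha2 = 1, beta2 = 1, w = 1,
      log_marginal_likelihood = -best$value,
      n_pairs = length(a), convergence = best$convergence
    ), class = "mgps_prior"))
  }
  fits <- lapply(mgps_starts(), function(s) {
    theta0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    tryCatch(
      optim(theta0, function(th) -mgps_loglik(th, a, e), method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(err) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0) {
    abort("gamma-mixture prior fit failed from every starting point")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  th <- best$par
  w <- stats::plogis(th[5])
  if (w < 1e-6 || w > 1 - 1e-6) {
    warn("mixture weight at boundary; clipped to [1e-6, 1 - 1e-6]")
    w <- min(max(w, 1e-6), 1 - 1e-6)
  }
  structure(list(
    alpha1 = exp(th[1]), beta1 = exp(th[2]),
    alpha2 = exp(th[3]), beta2 = exp(th[4]), w = w,
    log_marginal_likelihood = -best$value,
    n_pairs = length(a),
    convergence = best$convergence
  ), class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("Gamma-Poisson shrinker prior (two-component gamma mixture)\n")
  cat(sprintf("  component 1: Gamma(shape %.4g, rate %.4g), weight %.4g\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(shape %.4g, rate %.4g), weight %.4g\n",
              x$alpha2, x$beta2, 1 - x$w))
  cat(sprintf("  log marginal likelihood %.4f over %d pairs\n",
              x$log_marginal_likelihood, x$n_pairs))
  invisible(x)
}

#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble(term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
         estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w))
}

#' @export
glance.mgps_prior <- function(x, ...) {
  tibble(log_marginal_likelihood = x$log_marginal_likelihood,
         n_pairs = x$n_pairs, convergence = x$convergence)
}

# Posterior mixture for one pair: component j is
# Gamma(alpha_j + a, beta_j + E) with weight Q_j proportional to
# w_j * NB_j(a | E).
mgps_posterior <- function(a, e, prior) {
  lq1 <- log(prior$w) + log_nb(a, e, prior$alpha1, prior$beta1)
  lq2 <- log1p(-prior$w) + log_nb(a, e, prior$alpha2, prior$beta2)
  norm <- logsumexp2(lq1, lq2)
  list(q1 = exp(lq1 - norm), q2 = exp(lq2 - norm),
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

mixture_cdf <- function(x, post, i) {
  post$q1[i] * pgamma(x, post$shape1[i], rate = post$rate1[i]) +
    post$q2[i] * pgamma(x, post$shape2[i], rate = post$rate2[i])
}

# percentile of the posterior mixture by bisection on the CDF
mixture_quantile <- function(p, post, i, tol = 1e-8) {
  m1 <- post$shape1[i] / post$rate1[i]
  m2 <- post$shape2[i] / post$rate2[i]
  v <- post$q1[i] * (m1^2 / post$shape1[i] + m1^2) +
    post$q2[i] * (m2^2 / post$shape2[i] + m2^2)
  mean_mix <- post$q1[i] * m1 + post$q2[i] * m2
  sd_mix <- sqrt(max(v - mean_mix^2, 0))
  hi <- mean_mix + 10 * sd_mix + 1
  while (mixture_cdf(hi, post, i) < p) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (mixture_cdf(mid, post, i) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Empirical Bayes geometric mean (EBGM) with posterior percentiles
#'
#' For each pair, the posterior over the reporting-rate ratio lambda is
#' a two-component gamma mixture; EBGM is the posterior geometric mean
#' `exp(E[log lambda | a])`, computed in closed form through the
#' digamma function, and EBGM05/EBGM95 are the 5th/95th posterior
#' percentiles found by bisection on the mixture CDF. The signal rule
#' is `EBGM05 > ebgm05_min`.
#'
#' @param tables tibble of 2x2 tables (`a`, `b`, `c`, `d`).
#' @param prior an `mgps_prior` from [fit_mgps_prior()].
#' @inheritParams ror_estimate
#' @return a tibble as in [ror_estimate()] with `conf_low` = EBGM05 and
#'   `conf_high` = EBGM95, plus an `expected` column.
#' @export
ebgm_estimate <- function(tables, prior,
                          thresholds = signal_thresholds()) {
  stopifnot(inherits(prior, "mgps_prior"))
  a <- tables$a
  e <- mgps_expected(tables)
  ok <- is.finite(e) & e > 0 & is.finite(a)
  post <- mgps_posterior(ifelse(ok, a, 1), ifelse(ok, e, 1), prior)
  elog <- post$q1 * (digamma(post$shape1) - log(post$rate1)) +
    post$q2 * (digamma(post$shape2) - log(post$rate2))
  point <- ifelse(ok, exp(elog), NA_real_)
  qtl <- function(p) {
    vapply(seq_along(a), function(i) {
      if (!ok[i]) NA_real_ else mixture_quantile(p, post, i)
    }, numeric(1))
  }
  lo <- qtl(0.05)
  hi <- qtl(0.95)
  sig <- lo > thresholds$ebgm05_min
  new_estimate(tables, "EBGM", point, lo, hi, tibble(expected = e), sig,
               NA_character_)
}
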