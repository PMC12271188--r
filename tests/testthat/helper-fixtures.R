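# Hand-built ICSR fixtures: mk_report() gives one fully-populated report;
# override any field. mk_reports() binds several into an icsr_tbl.

mk_report <- function(primary_id = 1, case_id = as.character(primary_id),
                      receipt_date = as.Date("2020-06-01"),
                      event_date = as.Date("2020-03-01"),
                      sex = "male", age_years = 50, weight_kg = 70,
                      country = "US", occupation = "MD",
                      outcomes = "HO",
                      drug = "DRUG X", role = "PS",
                      therapy_start = as.Date("2020-01-01"),
                      therapy_end = as.Date(NA),
                      reactions = "osteoporosis") {
  tibble::tibble(
    primary_id = primary_id, case_id = case_id,
    receipt_date = receipt_date, event_date = event_date,
    event_date_imputed = FALSE,
    sex = sex, age_years = age_years, weight_kg = weight_kg,
    country = country, occupation = occupation,
    outcomes = list(outcomes),
    drug_names = list(drug),
    drug_roles = list(role),
    drug_starts = list(rep(therapy_start,
                           length(drug))[seq_along(drug)]),
    drug_ends = list(rep(therapy_end, length(drug))[seq_along(drug)]),
    reactions = list(reactions)
  )
}

mk_reports <- function(...) {
  new_icsr_tbl(dplyr::bind_rows(...))
}

# Independent Pearson chi-square from first principles (expected cells).
oracle_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Independent two-sided Fisher exact p by hypergeometric enumeration:
# sum of probabilities of all tables with the same margins whose
# probability does not exceed the observed table's.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Marginal likelihood of one pair under the gamma-mixture prior by
# numeric quadrature over lambda (independent of the negative-binomial
# closed form used in the package).
oracle_marginal <- function(a, e, alpha1, beta1, alpha2, beta2, w) {
  f <- function(lam) {
    stats::dpois(a, lam * e) *
      (w * stats::dgamma(lam, alpha1, rate = beta1) +
         (1 - w) * stats::dgamma(lam, alpha2, rate = beta2))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
}

# Profile-likelihood grid oracle for the Weibull MLE: for fixed shape
# the scale MLE is (mean(t^shape))^(1/shape); refine the shape grid.
oracle_weibull <- function(t, lo = 0.2, hi = 8, iters = 4, n_grid = 200) {
  prof <- function(shape) {
    scale <- mean(t^shape)^(1 / shape)
    sum(stats::dweibull(t, shape, scale, log = TRUE))
  }
  for (i in seq_len(iters)) {
    grid <- seq(lo, hi, length.out = n_grid)
    ll <- vapply(grid, prof, numeric(1))
    j <- which.max(ll)
    lo <- grid[max(1, j - 1)]; hi <- grid[min(n_grid, j + 1)]
  }
  shape <- (lo + hi) / 2
  c(shape = shape, scale = mean(t^shape)^(1 / shape))
}

tiny_sim_config <- function(n = 500, seed = 1,
                            planted_rr = c("DRUG X|osteoporosis" = 10),
                            ...) {
  faers_sim_config(
    n_reports = n,
    drugs = tibble::tibble(name = c("DRUG X", "OTHER"),
                           share = c(0.3, 0.7)),
    events = tibble::tibble(
      pt = c("osteoporosis", "bone loss", "headache", "nausea"),
      rate = c(0.02, 0.01, 0.3, 0.2)),
    planted_rr = planted_rr,
    tto = list(`DRUG X` = c(shape = 1.2, scale = 400)),
    seed = seed, ...)
}
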