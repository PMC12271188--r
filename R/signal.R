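#' Conventional signal-criterion thresholds
#'
#' The consensus criteria used throughout pharmacovigilance: ROR lower
#' 95% bound > 1 with at least 3 cases; PRR >= 2 with chi-square >= 4 and
#' at least 3 cases; IC025 > 0; EBGM05 > 2. All are configurable.
#'
#' @param z normal quantile for ROR/PRR Wald intervals (1.96 for 95%).
#' @param min_a minimum case count for ROR/PRR signals.
#' @param ror_low ROR signal bound on the interval's lower end.
#' @param prr_min,chi2_min PRR point and chi-square thresholds.
#' @param ic025_min IC lower-credibility-bound threshold.
#' @param ebgm05_min EBGM 5th-percentile threshold.
#' @param continuity apply the Haldane-Anscombe +0.5 correction to all
#'   cells of the 2x2 table before ROR/PRR estimation.
#' @param yates use Yates' continuity correction in the Pearson
#'   chi-square (off by default; the chi2 >= 4 criterion is stated for
#'   the uncorrected statistic).
#' @return a list of thresholds, class `signal_thresholds`.
#' @export
signal_thresholds <- function(z = 1.96, min_a = 3, ror_low = 1,
                              prr_min = 2, chi2_min = 4, ic025_min = 0,
                              ebgm05_min = 2, continuity = FALSE,
                              yates = FALSE) {
  structure(list(z = z, min_a = min_a, ror_low = ror_low,
                 prr_min = prr_min, chi2_min = chi2_min,
                 ic025_min = ic025_min, ebgm05_min = ebgm05_min,
                 continuity = continuity, yates = yates),
            class = "signal_thresholds")
}

#' Build 2x2 contingency tables from pair counts
#'
#' For each drug-event pair: `a` = reports with the drug (primary
#' suspect) and the event, `b` = drug without the event, `c` = event
#' without the drug, `d` = neither, derived from the sufficient
#' statistics of [count_pt_pairs()].
#'
#' @param pair_counts tibble with `a`, `n_event`, `n_drug`, `n_total`
#'   (and optionally `drug`, `pt`).
#' @return a tibble with `a`, `b`, `c`, `d`, `n_total` (id columns
#'   retained).
#' @export
build_contingency <- function(pair_counts) {
  out <- as_tibble(pair_counts)
  if (all(c("b", "c", "d") %in% names(out))) {
    # already a contingency table; normalize types and pass through
    for (col in c("a", "b", "c", "d")) out[[col]] <- as.double(out[[col]])
    out$n_total <- out$a + out$b + out$c + out$d
    if (any(out$a < 0 | out$b < 0 | out$c < 0 | out$d < 0, na.rm = TRUE)) {
      abort("inconsistent totals: a contingency cell is negative")
    }
    return(out[intersect(c("drug", "pt", "a", "b", "c", "d", "n_total"),
                         names(out))])
  }
  out$a <- as.double(out$a)  # doubles: cell products overflow integers
  out$b <- as.double(out$n_drug) - out$a
  out$c <- as.double(out$n_event) - out$a
  out$d <- as.double(out$n_total) - out$a - out$b - out$c
  if (any(out$a < 0 | out$b < 0 | out$c < 0 | out$d < 0)) {
    abort("inconsistent totals: a derived contingency cell is negative")
  }
  keep <- intersect(c("drug", "pt", "a", "b", "c", "d", "n_total"),
                    names(out))
  out[keep]
}

new_estimate <- function(tables, method, point, lo, hi, extra = NULL,
                         is_signal, reason) {
  id <- tables[intersect(c("drug", "pt"), names(tables))]
  out <- bind_cols(id, tibble(
    method = method, a = tables$a, point = point,
    conf_low = lo, conf_high = hi))
  if (!is.null(extra)) out <- bind_cols(out, extra)
  out$is_signal <- is_signal & !is.na(point)
  out$reason <- reason
  out
}

#' Reporting odds ratio with Wald interval
#'
#' ROR = ad/bc with the log-scale Wald interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell
#' makes the estimate undefined; it is returned as `NA` with a
#' machine-readable reason unless `continuity` requests the
#' Haldane-Anscombe +0.5 correction. The signal rule is
#' `conf_low > ror_low` with `a >= min_a`.
#'
#' @param tables tibble with columns `a`, `b`, `c`, `d` (one row per
#'   drug-event pair; `drug`/`pt` columns are carried through).
#' @param thresholds a [signal_thresholds()] list.
#' @return a tibble with `method`, `a`, `point`, `conf_low`,
#'   `conf_high`, `is_signal`, `reason`.
#' @export
ror_estimate <- function(tables, thresholds = signal_thresholds()) {
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  if (thresholds$continuity) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  point <- ifelse(zero, NA_real_, (a * d) / (b * c))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  lo <- exp(log(point) - thresholds$z * se)
  hi <- exp(log(point) + thresholds$z * se)
  sig <- !is.na(lo) & lo > thresholds$ror_low & tables$a >= thresholds$min_a
  reason <- ifelse(zero, "zero cell", NA_character_)
  new_estimate(tables, "ROR", point, lo, hi, NULL, sig, reason)
}

pearson_chi2 <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Proportional reporting ratio with chi-square
#'
#' PRR = (a/(a+b)) / (c/(c+d)) with log-scale Wald interval using
#' `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, plus the Pearson
#' chi-square of the 2x2 table. The signal rule is `point >= prr_min`,
#' `chi2 >= chi2_min` and `a >= min_a`.
#'
#' @inheritParams ror_estimate
#' @return a tibble as in [ror_estimate()] plus a `chi2` column.
#' @export
prr_estimate <- function(tables, thresholds = signal_thresholds()) {
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  if (thresholds$continuity) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  bad <- a == 0 | c == 0 | (a + b) == 0 | (c + d) == 0
  point <- ifelse(bad, NA_real_, (a / (a + b)) / (c / (c + d)))
  se <- ifelse(bad, NA_real_,
               sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)))
  lo <- exp(log(point) - thresholds$z * se)
  hi <- exp(log(point) + thresholds$z * se)
  chi2 <- pearson_chi2(tables$a, tables$b, tables$c, tables$d,
                       yates = thresholds$yates)
  sig <- !is.na(point) & point >= thresholds$prr_min &
    chi2 >= thresholds$chi2_min & tables$a >= thresholds$min_a
  reason <- ifelse(bad, "zero cell", NA_character_)
  new_estimate(tables, "PRR", point, lo, hi, tibble(chi2 = chi2), sig,
               reason)
}

#' Information component with credibility bounds
#'
#' The shrunken observed-to-expected statistic
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/N`, and the
#' closed-form credibility bounds
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2.0 (a+0.5)^(-3/2)` and
#' `IC975 = IC + 2.4 (a+0.5)^(-1/2) + 0.5 (a+0.5)^(-3/2)`. Defined for
#' `a = 0`. The signal rule is `IC025 > ic025_min`.
#'
#' @inheritParams ror_estimate
#' @return a tibble as in [ror_estimate()] plus an `expected` column.
#' @export
ic_estimate <- function(tables, thresholds = signal_thresholds()) {
  a <- tables$a
  n <- tables$a + tables$b + tables$c + tables$d
  e <- (tables$a + tables$b) * (tables$a + tables$c) / n
  point <- log2((a + 0.5) / (e + 0.5))
  s <- (a + 0.5)^(-0.5)
  s3 <- (a + 0.5)^(-1.5)
  lo <- point - 3.3 * s - 2.0 * s3
  hi <- point + 2.4 * s + 0.5 * s3
  sig <- lo > thresholds$ic025_min
  new_estimate(tables, "IC", point, lo, hi, tibble(expected = e), sig,
               NA_character_)
}

#' P-value of a 2x2 table
#'
#' Pearson chi-square (1 df, no continuity correction) when every
#' expected cell is at least 5, otherwise the two-sided Fisher exact
#' test.
#'
#' @param tables tibble with `a`, `b`, `c`, `d`.
#' @return numeric vector of p-values.
#' @export
pvalue_2x2 <- function(tables) {
  vapply(seq_len(nrow(tables)), function(i) {
    m <- matrix(c(tables$a[i], tables$b[i], tables$c[i], tables$d[i]),
                nrow = 2, byrow = TRUE)
    if (sum(m) == 0 || anyNA(m)) return(NA_real_)
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    if (all(expd >= 5)) {
      chi2 <- pearson_chi2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
      unname(pchisq(chi2, df = 1, lower.tail = FALSE))
    } else {
      unname(fisher.test(m)$p.value)
    }
  }, numeric(1))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`, order-preserving, idempotent for fixed `m`
#' once capped.
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of tests; defaults to `length(p)` and must be at
#'   least that.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  if (m < length(p)) abort("m must be at least the number of tests")
  pmin(1, m * p)
}

#' Consensus signal evaluation
#'
#' A drug-event pair is flagged when at least one method's criterion is
#' met; per-method flags are reported alongside.
#'
#' @param estimates long tibble of method estimates (rows from
#'   [ror_estimate()], [prr_estimate()], [ic_estimate()],
#'   [ebgm_estimate()] bound together), with `drug`, `pt`, `method`,
#'   `is_signal`.
#' @return a tibble with one row per pair: per-method flag columns
#'   (`signal_ror`, ...) and `consensus`.
#' @export
evaluate_signals <- function(estimates) {
  wide <- tidyr::pivot_wider(
    estimates[c("drug", "pt", "a", "method", "is_signal")],
    names_from = "method", values_from = "is_signal",
    names_prefix = "signal_")
  names(wide) <- tolower(names(wide))
  flag_cols <- grep("^signal_", names(wide), value = TRUE)
  flags <- as.matrix(wide[flag_cols])
  wide$consensus <- rowSums(flags, na.rm = TRUE) > 0 & wide$a > 0
  wide
}

#' Full signal table for one drug
#'
#' Runs all four disproportionality methods on the pair counts of one
#' drug, adds the 2x2 p-value with Bonferroni correction, and the
#' consensus flag -- one row per event, mirroring the usual published
#' layout (N, ROR (CI), PRR (chi2), EBGM (EBGM05), IC (IC025), p).
#'
#' @param pair_counts output of [count_pt_pairs()] (optionally with an
#'   [aggregate_smq()] row bound on).
#' @param prior an [fit_mgps_prior()] object for the EBGM column; when
#'   `NULL` a prior is fitted to `pair_counts` itself (only sensible
#'   when many pairs are supplied).
#' @param thresholds a [signal_thresholds()] list.
#' @param bonferroni_m number of tests for the correction; default the
#'   number of rows.
#' @return a tibble, one row per event.
#' @export
signal_table <- function(pair_counts, prior = NULL,
                         thresholds = signal_thresholds(),
                         bonferroni_m = NULL) {
  tab <- build_contingency(pair_counts)
  if (is.null(prior)) prior <- fit_mgps_prior(tab)
  e_ror <- ror_estimate(tab, thresholds)
  e_prr <- prr_estimate(tab, thresholds)
  e_ic <- ic_estimate(tab, thresholds)
  e_ebgm <- ebgm_estimate(tab, prior, thresholds)
  p <- pvalue_2x2(tab)
  m <- bonferroni_m %||% nrow(tab)
  out <- tibble(
    drug = tab$drug %||% NA_character_,
    event = tab$pt %||% NA_character_,
    n = as.integer(tab$a),
    ror = e_ror$point, ror_low = e_ror$conf_low,
    ror_high = e_ror$conf_high,
    prr = e_prr$point, chi2 = e_prr$chi2,
    ebgm = e_ebgm$point, ebgm05 = e_ebgm$conf_low,
    ic = e_ic$point, ic025 = e_ic$conf_low,
    p_value = p,
    p_adjusted = bonferroni_adjust(p, m),
    signal_ror = e_ror$is_signal,
    signal_prr = e_prr$is_signal,
    signal_ic = e_ic$is_signal,
    signal_ebgm = e_ebgm$is_signal
  )
  out$consensus <- (out$signal_ror | out$signal_prr | out$signal_ic |
                      out$signal_ebgm) & out$n > 0
  out
}
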