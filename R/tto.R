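#' Time to onset of an adverse event
#'
#' Duration in whole days from the earliest therapy start of the
#' primary-suspect drug to the event date. Reports missing either date
#' and durations <= 0 (the Weibull support is positive) are excluded
#' and counted by reason.
#'
#' @param reports a deduplicated, primary-suspect-filtered `icsr_tbl`.
#' @param drug_name drug whose therapy start anchors the interval.
#' @param smq optional [smq_definition()]; when given, only reports
#'   carrying at least one member PT contribute.
#' @return a tibble with `primary_id` and `tto_days`; exclusion counts
#'   are attached as attribute `"tto_exclusions"` (tibble `reason`,
#'   `n`).
#' @export
compute_tto <- function(reports, drug_name, smq = NULL) {
  target <- normalize_drug_name(drug_name)
  if (!is.null(smq)) {
    hit <- vapply(reports$reactions,
                  function(x) any(x %in% smq$member_pts), logical(1))
    reports <- vctrs::vec_slice(reports, hit)
  }
  dl <- icsr_drug_long(reports)
  dl <- dl[dl$drug_name %in% target & dl$role_code == "PS" &
             !is.na(dl$therapy_start), ]
  first <- if (nrow(dl) == 0) {
    tibble(primary_id = numeric(), start = as.Date(character()))
  } else {
    summarise(group_by(dl, .data$primary_id),
              start = min(.data$therapy_start), .groups = "drop")
  }
  start <- as.Date(first$start[match(reports$primary_id,
                                     first$primary_id)],
                   origin = "1970-01-01")
  days <- as.numeric(reports$event_date - start)
  excl <- tibble(
    reason = c("missing therapy start", "missing event date",
               "nonpositive duration"),
    n = c(sum(is.na(start)),
          sum(!is.na(start) & is.na(reports$event_date)),
          sum(!is.na(days) & days <= 0))
  )
  keep <- !is.na(days) & days > 0
  out <- tibble(primary_id = reports$primary_id[keep],
                tto_days = days[keep])
  attr(out, "tto_exclusions") <- excl
  out
}

weibull_loglik <- function(logpar, t) {
  shape <- exp(logpar[1]); scale <- exp(logpar[2])
  if (!is.finite(shape) || !is.finite(scale)) return(-Inf)
  ll <- suppressWarnings(
    sum(dweibull(t, shape = shape, scale = scale, log = TRUE)))
  if (is.nan(ll)) -Inf else ll
}

#' Weibull maximum-likelihood fit for onset times
#'
#' Fits shape (beta) and scale (alpha, days) by maximizing the Weibull
#' log-likelihood with BFGS on the log-parameter scale; 95% Wald
#' confidence intervals come from the observed information on that
#' scale (delta method, z = 1.96). The failure curve is classified from
#' the shape CI: entirely below 1 is an early-failure (decreasing
#' hazard) pattern, entirely above 1 wear-out (increasing hazard),
#' otherwise random (hazard compatible with constant).
#'
#' @param durations positive onset times in days (n >= 3, not all
#'   equal).
#' @param conf_level confidence level for the Wald intervals.
#' @return a `tto_weibull` object; see [tidy.tto_weibull()] and
#'   [glance.tto_weibull()].
#' @export
weibull_mle <- function(durations, conf_level = 0.95) {
  t <- as.numeric(durations)
  if (length(t) < 3) abort("need at least 3 positive durations")
  if (any(is.na(t) | t <= 0)) abort("durations must be positive and non-missing")
  if (length(unique(t)) == 1) {
    abort("degenerate sample: all durations identical; shape is unbounded")
  }
  z <- -stats::qnorm((1 - conf_level) / 2)
  start <- c(0, log(mean(t)))
  fit <- optim(start, function(p) -weibull_loglik(p, t), method = "BFGS",
               hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    abort(paste0("Weibull fit did not converge (optim code ",
                 fit$convergence, ")"))
  }
  vc <- tryCatch(solve(fit$hessian), error = function(err) {
    abort("Weibull fit: observed information is singular")
  })
  se_log <- sqrt(pmax(diag(vc), 0))
  est <- exp(fit$par)
  shape_ci <- est[1] * exp(c(-1, 1) * z * se_log[1])
  scale_ci <- est[2] * exp(c(-1, 1) * z * se_log[2])
  out <- structure(list(
    shape = est[1], scale = est[2],
    shape_ci = shape_ci, scale_ci = scale_ci,
    n = length(t), log_likelihood = -fit$value,
    conf_level = conf_level,
    vcov_log = vc, durations = t
  ), class = "tto_weibull")
  out$failure_class <- classify_failure(out)
  out
}

#' Classify the failure curve from the shape-parameter CI
#'
#' `early` when the shape CI lies entirely below 1 (risk decreasing
#' over time), `wear_out` when entirely above 1 (risk increasing), and
#' `random` when the CI includes 1 (events keep occurring at a roughly
#' constant hazard).
#'
#' @param fit a `tto_weibull` object, or a numeric `c(low, high)` shape
#'   CI.
#' @return one of `"early"`, `"random"`, `"wear_out"`.
#' @export
classify_failure <- function(fit) {
  ci <- if (inherits(fit, "tto_weibull")) fit$shape_ci else as.numeric(fit)
  if (length(ci) != 2 || anyNA(ci)) abort("need a finite shape CI")
  if (ci[2] < 1) "early" else if (ci[1] > 1) "wear_out" else "random"
}

#' @export
print.tto_weibull <- function(x, ...) {
  cat(sprintf(
    "Weibull onset model (n = %d): shape %.3f (%.3f-%.3f), scale %.1f d (%.1f-%.1f)\n",
    x$n, x$shape, x$shape_ci[1], x$shape_ci[2],
    x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  failure pattern: %s; log-likelihood %.2f\n",
              x$failure_class, x$log_likelihood))
  invisible(x)
}

#' Tidy a Weibull onset fit
#'
#' @param x a `tto_weibull` object.
#' @param ... unused.
#' @return one row per parameter with estimate and CI.
#' @export
tidy.tto_weibull <- function(x, ...) {
  tibble(term = c("shape", "scale"),
         estimate = c(x$shape, x$scale),
         conf_low = c(x$shape_ci[1], x$scale_ci[1]),
         conf_high = c(x$shape_ci[2], x$scale_ci[2]))
}

#' @rdname tidy.tto_weibull
#' @export
glance.tto_weibull <- function(x, ...) {
  tibble(n = x$n, log_likelihood = x$log_likelihood,
         shape = x$shape, scale = x$scale,
         failure_class = x$failure_class,
         mean_days = mean(x$durations), median_days = median(x$durations))
}

#' @rdname tidy.tto_weibull
#' @param object a `tto_weibull` object.
#' @export
autoplot.tto_weibull <- function(object, ...) {
  df <- tibble(tto_days = object$durations)
  grid <- tibble(x = seq(1, max(df$tto_days), length.out = 400))
  grid$density <- dweibull(grid$x, object$shape, object$scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tto_days)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(
      x = "time to onset (days)", y = "density",
      title = sprintf("Weibull fit: shape %.2f, scale %.0f d (%s)",
                      object$shape, object$scale, object$failure_class))
}

#' Compare two onset-time distributions
#'
#' Two-sided Mann-Whitney U test. With both samples of size 8 or fewer
#' the p-value is exact by full enumeration of rank assignments
#' (midranks for ties); larger samples use the normal approximation
#' with tie correction. A log-rank alternative (all events observed,
#' no censoring) is available.
#'
#' @param x,y numeric duration samples.
#' @param method `"wilcoxon"` (default) or `"logrank"`.
#' @return the two-sided p-value.
#' @export
compare_tto <- function(x, y, method = c("wilcoxon", "logrank")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  if (method == "logrank") {
    if (!requireNamespace("survival", quietly = TRUE)) {
      abort("the log-rank option needs the survival package")
    }
    df <- data.frame(time = c(x, y),
                     grp = rep(1:2, c(length(x), length(y))))
    sd1 <- survival::survdiff(survival::Surv(time, rep(1, nrow(df))) ~ grp,
                              data = df)
    return(unname(pchisq(sd1$chisq, df = 1, lower.tail = FALSE)))
  }
  n1 <- length(x); n2 <- length(y)
  if (n1 <= 8 && n2 <= 8) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (n1 + n2 + 1) / 2
    dev <- abs(w_obs - mu)
    sets <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    mean(abs(w_all - mu) >= dev - 1e-9)
  } else {
    suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
}

#' Summary statistics for onset times
#'
#' Mean, SD, median and the shares of events per onset window using the
#' half-open day intervals [0, 30), [30, 90), [90, 180), [180, 365),
#' [365, Inf).
#'
#' @param durations positive onset times in days.
#' @return a one-row tibble.
#' @export
tto_summary <- function(durations) {
  t <- as.numeric(durations)
  brk <- c(0, 30, 90, 180, 365, Inf)
  lab <- c("d0_29", "d30_89", "d90_179", "d180_364", "d365_plus")
  cnt <- table(cut(t, breaks = brk, right = FALSE, labels = lab))
  shares <- as.list(as.numeric(cnt) / length(t))
  names(shares) <- paste0("share_", lab)
  bind_cols(tibble(n = length(t), mean_days = mean(t), sd_days = sd(t),
                   median_days = median(t)),
            as_tibble(shares))
}
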