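tbl1 <- function(a, b, c, d, drug = "D", pt = "evt") {
  tibble::tibble(drug = drug, pt = pt, a = a,
                 n_event = a + c, n_drug = a + b, n_total = a + b + c + d)
}

test_that("contingency construction reproduces hand arithmetic", {
  ct <- build_contingency(tbl1(10, 90, 100, 9900))
  expect_equal(unlist(ct[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 90, 100, 9900))
  # degenerate single-pair dataset: everything is the target pair
  ct0 <- build_contingency(tibble::tibble(a = 5, n_event = 5, n_drug = 5,
                                          n_total = 5))
  expect_equal(unlist(ct0[c("b", "c", "d")], use.names = FALSE),
               c(0, 0, 0))
  bad <- tibble::tibble(a = 10, n_event = 5, n_drug = 20, n_total = 100)
  expect_error(build_contingency(bad), "negative")
})

test_that("contingency cells agree with a brute-force double loop", {
  cfg <- tiny_sim_config(n = 300, seed = 13)
  reps <- deduplicate_reports(simulate_faers(cfg)$reports)
  smq <- smq_definition(c("osteoporosis", "bone loss", "headache"))
  ct <- build_contingency(count_pt_pairs(reps, "DRUG X", smq))
  for (i in seq_along(smq$member_pts)) {
    pt <- smq$member_pts[i]
    has_drug <- vapply(seq_len(nrow(reps)), function(r) {
      any(reps$drug_names[[r]] == "DRUG X" &
            reps$drug_roles[[r]] == "PS")
    }, logical(1))
    has_evt <- vapply(reps$reactions, function(x) pt %in% x, logical(1))
    expect_equal(ct$a[i], sum(has_drug & has_evt))
    expect_equal(ct$b[i], sum(has_drug & !has_evt))
    expect_equal(ct$c[i], sum(!has_drug & has_evt))
    expect_equal(ct$d[i], sum(!has_drug & !has_evt))
  }
})

test_that("ROR matches hand arithmetic and flags correctly", {
  e <- ror_estimate(build_contingency(tbl1(10, 10, 10, 10)))
  expect_equal(e$point, 1)
  expect_true(e$conf_low < 1 && e$conf_high > 1)
  expect_false(e$is_signal)

  e2 <- ror_estimate(build_contingency(tbl1(10, 90, 100, 9900)))
  expect_equal(e2$point, 11)
  expect_equal(e2$conf_low, exp(log(11) - 1.96 * sqrt(0.121212121)),
               tolerance = 1e-8)
  expect_equal(round(c(e2$conf_low, e2$conf_high), 2), c(5.56, 21.76))
  expect_true(e2$is_signal)
})

test_that("a zero cell yields an undefined ROR with a reason, not a crash", {
  e <- ror_estimate(build_contingency(tbl1(0, 100, 10, 9890)))
  expect_true(is.na(e$point))
  expect_equal(e$reason, "zero cell")
  expect_false(e$is_signal)
  # explicit continuity mode resolves it
  e2 <- ror_estimate(build_contingency(tbl1(0, 100, 10, 9890)),
                     signal_thresholds(continuity = TRUE))
  expect_equal(e2$point, (0.5 * 9890.5) / (100.5 * 10.5), tolerance = 1e-12)
})

test_that("PRR point, chi-square and interval match hand arithmetic", {
  e <- prr_estimate(build_contingency(tbl1(10, 10, 10, 10)))
  expect_equal(e$point, 1)
  expect_equal(e$chi2, 0)
  e2 <- prr_estimate(build_contingency(tbl1(10, 90, 100, 9900)))
  expect_equal(e2$point, 10)
  expect_equal(e2$chi2, 74.45, tolerance = 1e-3)
  se <- sqrt(1 / 10 - 1 / 100 + 1 / 100 - 1 / 10000)
  expect_equal(e2$conf_low, 10 * exp(-1.96 * se), tolerance = 1e-10)
  expect_true(e2$is_signal)
})

test_that("ROR/PRR/chi-square agree with direct formula evaluation on random tables", {
  withr::local_seed(101)
  n <- 1000
  tabs <- tibble::tibble(a = rpois(n, 20) + 1, b = rpois(n, 200) + 1,
                         c = rpois(n, 100) + 1, d = rpois(n, 5000) + 1)
  tabs$n_event <- tabs$a + tabs$c
  tabs$n_drug <- tabs$a + tabs$b
  tabs$n_total <- tabs$a + tabs$b + tabs$c + tabs$d
  ct <- build_contingency(tabs)
  r <- ror_estimate(ct); p <- prr_estimate(ct); ic <- ic_estimate(ct)
  with(tabs, {
    expect_equal(r$point, a * d / (b * c), tolerance = 1e-12)
    expect_equal(p$point, (a / (a + b)) / (c / (c + d)), tolerance = 1e-12)
    chi_direct <- mapply(oracle_chi2, a, b, c, d)
    expect_equal(p$chi2, chi_direct, tolerance = 1e-10)
    e_direct <- (a + b) * (a + c) / (a + b + c + d)
    expect_equal(ic$point, log2((a + 0.5) / (e_direct + 0.5)),
                 tolerance = 1e-12)
  })
})

test_that("ROR and PRR intervals are log-symmetric about the point", {
  withr::local_seed(77)
  n <- 200
  tabs <- tibble::tibble(a = rpois(n, 15) + 1, b = rpois(n, 300) + 1,
                         c = rpois(n, 80) + 1, d = rpois(n, 8000) + 1)
  tabs$n_event <- tabs$a + tabs$c
  tabs$n_drug <- tabs$a + tabs$b
  tabs$n_total <- tabs$a + tabs$b + tabs$c + tabs$d
  ct <- build_contingency(tabs)
  for (est in list(ror_estimate(ct), prr_estimate(ct))) {
    expect_equal(sqrt(est$conf_low * est$conf_high), est$point,
                 tolerance = 1e-10)
  }
})

test_that("IC matches the closed-form credibility approximation", {
  e <- ic_estimate(build_contingency(tbl1(10, 90, 100, 9900)))
  expect_equal(e$point, log2(10.5 / (1.089109 + 0.5)), tolerance = 1e-5)
  expect_equal(e$point, 2.724, tolerance = 1e-3)
  expect_equal(e$conf_low, 1.647, tolerance = 1e-3)
  # defined at a = 0
  e0 <- ic_estimate(build_contingency(tbl1(0, 100, 50, 9850)))
  expect_true(is.finite(e0$point))
  expect_false(e0$is_signal)
  # shrinkage: for a > E the shrunken IC sits strictly below log2(a/E)
  e2 <- ic_estimate(build_contingency(tbl1(40, 60, 100, 9800)))
  expect_lt(e2$point, log2(40 / e2$expected))
  # null association at large a: observed equals expected
  big <- tbl1(1000, 9000, 9000, 81000)
  en <- ic_estimate(build_contingency(big))
  expect_equal(en$point, 0, tolerance = 0.01)
})

test_that("2x2 p-values switch between Pearson and Fisher appropriately", {
  expect_equal(pvalue_2x2(build_contingency(tbl1(10, 10, 10, 10))), 1)
  # all expected cells >= 5: Pearson, no continuity correction
  p_chi <- pvalue_2x2(build_contingency(tbl1(40, 160, 360, 1440 + 8000)))
  expect_equal(p_chi, pchisq(oracle_chi2(40, 160, 360, 9440), 1,
                             lower.tail = FALSE), tolerance = 1e-12)
  # the classic sparse-corner table has min expected ~1.09: Fisher applies
  p_sparse <- pvalue_2x2(build_contingency(tbl1(10, 90, 100, 9900)))
  expect_equal(p_sparse, oracle_fisher(10, 90, 100, 9900),
               tolerance = 1e-9)
  expect_lt(p_sparse, 1e-6)
  # small expected cells: Fisher exact, checked against full enumeration
  small <- list(c(3, 7, 1, 9), c(1, 4, 2, 3), c(5, 1, 1, 5), c(4, 2, 2, 12))
  for (s in small) {
    got <- pvalue_2x2(build_contingency(tbl1(s[1], s[2], s[3], s[4])))
    expect_equal(got, oracle_fisher(s[1], s[2], s[3], s[4]),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni correction multiplies, caps, preserves order, idempotent", {
  expect_equal(bonferroni_adjust(0.03, m = 1), 0.03)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), m = 10), c(0.1, 1))
  p <- c(0.001, 0.005, 0.02, 0.3)
  adj <- bonferroni_adjust(p, m = 20)
  expect_true(all(diff(adj) >= 0))
  # capped values are a fixed point of re-adjustment
  expect_equal(bonferroni_adjust(rep(1, 4), m = 20), rep(1, 4))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("consensus is the OR of per-method flags and needs a > 0", {
  # strong association: every method should flag it
  strong <- tbl1(207, 1627, 300, 100000)
  st <- signal_table(strong, prior = structure(
    list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, w = 0.5),
    class = "mgps_prior"))
  expect_true(st$consensus)
  expect_true(st$signal_ror && st$signal_prr)

  # a = 1 with interval straddling 1: no signal
  weak <- tbl1(1, 1800, 500, 150000)
  weak$n_event <- 1 + 2000  # widen background so ROR ~ 0.4
  weak <- build_contingency(weak)
  stw <- signal_table(weak, prior = structure(
    list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, w = 0.5),
    class = "mgps_prior"))
  expect_false(stw$consensus)

  # a = 0 is never a signal regardless of the other cells
  zero <- tbl1(0, 100, 1, 100000)
  stz <- signal_table(zero, prior = structure(
    list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, w = 0.5),
    class = "mgps_prior"))
  expect_false(stz$consensus)

  est <- dplyr::bind_rows(
    ror_estimate(build_contingency(strong)),
    prr_estimate(build_contingency(strong)),
    ic_estimate(build_contingency(strong)))
  ev <- evaluate_signals(est)
  expect_true(ev$consensus)
})
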