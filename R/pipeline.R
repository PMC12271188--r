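#' Study configuration for the full analysis
#'
#' @param drugs character vector of target drug names (at least one).
#' @param smq an [smq_definition()]; defaults to the bundled
#'   osteoporosis query.
#' @param age_cutoff_years age split for subgroup analysis: younger
#'   (`< cutoff`) vs older (`>= cutoff`); default 60.
#' @param sex_strata run male/female subgroups.
#' @param bonferroni_m number of tests for the correction; `NULL` means
#'   the number of drug-event pairs tested in the run.
#' @param thresholds a [signal_thresholds()] list.
#' @param seed integer seed for any resampling step.
#' @return a `study_config` list.
#' @export
study_config <- function(drugs, smq = NULL, age_cutoff_years = 60,
                         sex_strata = TRUE, bonferroni_m = NULL,
                         thresholds = signal_thresholds(), seed = 1L) {
  if (length(drugs) < 1) abort("config needs at least one drug")
  if (age_cutoff_years <= 0) abort("age_cutoff_years must be positive")
  structure(list(
    drugs = normalize_drug_name(drugs),
    smq = smq %||% osteoporosis_smq(),
    age_cutoff_years = age_cutoff_years,
    sex_strata = isTRUE(sex_strata),
    bonferroni_m = bonferroni_m,
    thresholds = thresholds,
    seed = as.integer(seed)
  ), class = "study_config")
}

band_table <- function(values, breaks, labels) {
  cut(values, breaks = breaks, labels = labels, right = FALSE)
}

demo_block <- function(reports, block) {
  n_tot <- nrow(reports)
  lev_n <- switch(
    block,
    sex = {
      v <- factor(reports$sex, levels = c("female", "male", "unknown"))
      table(v)
    },
    age = {
      b <- band_table(reports$age_years, c(0, 18, 65, 85.0001, Inf),
                      c("<18", "18-64.9", "65-85", ">85"))
      c(table(b), "missing" = sum(is.na(reports$age_years)))
    },
    weight = {
      b <- band_table(reports$weight_kg, c(0, 50, 100.0001, Inf),
                      c("<50 kg", "50-100 kg", ">100 kg"))
      c(table(b), "missing" = sum(is.na(reports$weight_kg)))
    },
    outcome = {
      codes <- c("CA", "DE", "DS", "HO", "LT", "OT", "RI")
      cnt <- vapply(codes, function(cd) {
        sum(vapply(reports$outcomes, function(o) cd %in% o, logical(1)))
      }, numeric(1))
      c(cnt, "missing" = sum(lengths(reports$outcomes) == 0))
    },
    occupation = {
      occ <- c(CN = "Consumer", HP = "Health professional", LW = "Lawyer",
               MD = "Physician", OT = "Other health-professional",
               PH = "Pharmacist", RN = "Registered nurse")
      v <- reports$occupation
      cnt <- vapply(names(occ), function(cd) sum(v %in% cd), numeric(1))
      names(cnt) <- unname(occ)
      c(cnt, "missing" = sum(is.na(v) | !(v %in% names(occ))))
    }
  )
  tibble(block = block, category = names(lev_n),
         n = as.integer(lev_n),
         pct = if (n_tot > 0) round(100 * as.integer(lev_n) / n_tot, 1)
         else NA_real_)
}

#' Descriptive summary of a report collection
#'
#' Counts and percentages (one decimal, of the column total including
#' missing) for sex, age bands (<18, 18-64.9, 65-85, >85), weight bands
#' (<50, 50-100, >100 kg), outcome codes and reporter occupation, for
#' all reports of a drug and for the subset carrying at least one SMQ
#' member PT -- the layout of a baseline-characteristics table.
#'
#' @param reports a deduplicated `icsr_tbl`; either already restricted
#'   to the drug of interest, or pass `drug` to restrict here.
#' @param drug optional drug name; when given, reports are first
#'   filtered with [filter_primary_suspect()].
#' @param smq optional [smq_definition()] defining the event-restricted
#'   column.
#' @return a tibble with `block`, `category`, `n_all`, `pct_all` and,
#'   when `smq` is given, `n_smq`, `pct_smq`.
#' @export
summarize_demographics <- function(reports, drug = NULL, smq = NULL) {
  if (!is.null(drug)) reports <- filter_primary_suspect(reports, drug)
  blocks <- c("sex", "age", "weight", "outcome", "occupation")
  all_tab <- bind_rows(lapply(blocks, function(b) demo_block(reports, b)))
  all_tab <- rename(all_tab, n_all = "n", pct_all = "pct")
  if (is.null(smq)) return(all_tab)
  hit <- vapply(reports$reactions,
                function(x) any(x %in% smq$member_pts), logical(1))
  sub <- vctrs::vec_slice(reports, hit)
  sub_tab <- bind_rows(lapply(blocks, function(b) demo_block(sub, b)))
  all_tab$n_smq <- sub_tab$n
  all_tab$pct_smq <- sub_tab$pct
  all_tab
}

#' Split reports into demographic strata
#'
#' `axis = "sex"` yields male and female strata (sex-unknown reports
#' drop out of the strata but stay in any overall analysis);
#' `axis = "age"` yields younger (`age < cutoff`) and older
#' (`age >= cutoff`) strata, age-missing reports dropping out. Strata
#' are disjoint.
#'
#' @param reports an `icsr_tbl`.
#' @param axis `"sex"` or `"age"`.
#' @param age_cutoff_years split point for the age axis (default 60;
#'   the cutoff itself falls in the older stratum).
#' @return a named list of `icsr_tbl`s.
#' @export
stratify_reports <- function(reports, axis = c("sex", "age"),
                             age_cutoff_years = 60) {
  axis <- match.arg(axis)
  if (axis == "sex") {
    list(male = new_icsr_tbl(vctrs::vec_slice(reports,
                                              reports$sex == "male")),
         female = new_icsr_tbl(vctrs::vec_slice(reports,
                                                reports$sex == "female")))
  } else {
    a <- reports$age_years
    list(younger = new_icsr_tbl(
           vctrs::vec_slice(reports, !is.na(a) & a < age_cutoff_years)),
         older = new_icsr_tbl(
           vctrs::vec_slice(reports, !is.na(a) & a >= age_cutoff_years)))
  }
}

smq_subgroup_rows <- function(reports, drug, config, prior) {
  smq <- config$smq
  strata <- c(
    stratify_reports(reports, "sex"),
    stratify_reports(reports, "age",
                     age_cutoff_years = config$age_cutoff_years)
  )
  labels <- c(male = "SMQ-MALE", female = "SMQ-FEMALE",
              younger = "SMQ-YOUNGER", older = "SMQ-OLDER")
  keep <- if (config$sex_strata) names(labels) else c("younger", "older")
  rows <- lapply(keep, function(nm) {
    # stratum-internal 2x2: numerator and background both restricted
    pc <- count_pt_pairs(strata[[nm]], drug, smq)
    aggregate_smq(pc, label = labels[[nm]])
  })
  bind_rows(rows)
}

#' Run the complete signal-detection study
#'
#' End-to-end orchestration over FAERS-style input files: read all
#' quarters in `input_dir` (file sets `DEMO*.txt`, `DRUG*.txt`, ...),
#' deduplicate, fit the empirical-Bayes prior across every observed
#' (primary-suspect drug, PT) pair, then per target drug write a
#' demographics table, PT-level and SMQ-level signal tables (the SMQ
#' table carrying overall plus male/female/younger/older subgroup rows
#' computed on stratum-internal 2x2 tables), an onset-time table, and a
#' run log with dedup and exclusion counts. Output is deterministic
#' given inputs and config.
#'
#' @param input_dir directory with the quarterly files.
#' @param config a [study_config()].
#' @param output_dir directory for the TSV outputs (created).
#' @return invisibly, a list of the result tibbles.
#' @export
run_faers_analysis <- function(input_dir, config, output_dir) {
  stopifnot(inherits(config, "study_config"))
  stems <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")
  sets <- lapply(stems, function(s) {
    sort(list.files(input_dir, pattern = paste0("^", s, ".*\\.txt$"),
                    full.names = TRUE))
  })
  names(sets) <- stems
  if (any(lengths(sets) == 0)) {
    abort(paste0("stage ingest: no ", stems[lengths(sets) == 0][1],
                 "*.txt file in ", input_dir))
  }
  if (length(unique(lengths(sets))) != 1) {
    abort("stage ingest: unequal numbers of quarterly files per table")
  }
  quarters <- lapply(seq_along(sets$DEMO), function(i) {
    read_faers_quarter(sets$DEMO[i], sets$DRUG[i], sets$REAC[i],
                       sets$THER[i], sets$OUTC[i])
  })
  raw <- new_icsr_tbl(bind_rows(quarters))
  parse_log <- bind_rows(lapply(quarters, attr, "parse_log"))
  reports <- deduplicate_reports(raw)
  dedup_log <- attr(reports, "dedup_log")

  all_pairs <- all_pair_counts(reports)
  prior <- fit_mgps_prior(build_contingency(all_pairs))
  m_default <- nrow(all_pairs)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf(
    "# faersignal %s | config hash %s",
    as.character(utils::packageVersion("faersignal")),
    rlang::hash(config))
  emit <- function(df, path) {
    body <- readr::format_tsv(df)
    writeLines(c(hdr, sub("\n$", "", body)), path)
  }

  results <- list(parse_log = parse_log, dedup_log = dedup_log,
                  prior = prior)
  run_log <- list(tibble(step = "reports_after_dedup",
                         detail = "", n = nrow(reports)),
                  tibble(step = paste0("dedup_", dedup_log$stage),
                         detail = "removed", n = dedup_log$removed),
                  tibble(step = "parse_skipped", detail = "",
                         n = nrow(parse_log)))

  for (drug in config$drugs) {
    slug <- tolower(gsub("[^A-Za-z0-9]+", "_", drug))
    ps <- withCallingHandlers(
      filter_primary_suspect(reports, drug),
      warning = function(w) {
        run_log[[length(run_log) + 1]] <<-
          tibble(step = "warning", detail = conditionMessage(w), n = 0)
        invokeRestart("muffleWarning")
      })

    demo_tab <- summarize_demographics(ps, smq = config$smq)
    emit(demo_tab, file.path(output_dir,
                             paste0(slug, "_demographics.tsv")))

    pt_counts <- count_pt_pairs(reports, drug, config$smq)
    pt_tab <- signal_table(pt_counts, prior = prior,
                           thresholds = config$thresholds,
                           bonferroni_m = config$bonferroni_m %||%
                             m_default)
    emit(pt_tab, file.path(output_dir, paste0(slug, "_pt_signals.tsv")))

    smq_rows <- bind_rows(
      aggregate_smq(pt_counts),
      smq_subgroup_rows(reports, drug, config, prior))
    smq_tab <- signal_table(smq_rows, prior = prior,
                            thresholds = config$thresholds,
                            bonferroni_m = config$bonferroni_m %||%
                              m_default)
    emit(smq_tab, file.path(output_dir, paste0(slug, "_smq_signals.tsv")))

    tto <- compute_tto(ps, drug, config$smq)
    excl <- attr(tto, "tto_exclusions")
    tto_tab <- if (nrow(tto) >= 3 &&
                   length(unique(tto$tto_days)) > 1) {
      fit <- weibull_mle(tto$tto_days)
      bind_cols(tibble(drug = drug), tto_summary(tto$tto_days),
                tibble(scale = fit$scale, scale_low = fit$scale_ci[1],
                       scale_high = fit$scale_ci[2],
                       shape = fit$shape, shape_low = fit$shape_ci[1],
                       shape_high = fit$shape_ci[2],
                       failure_class = fit$failure_class,
                       n_excluded = sum(excl$n)))
    } else {
      tibble(drug = drug, n = nrow(tto), n_excluded = sum(excl$n))
    }
    emit(tto_tab, file.path(output_dir, paste0(slug, "_tto.tsv")))

    run_log[[length(run_log) + 1]] <- tibble(
      step = paste0("tto_excluded_", slug),
      detail = excl$reason, n = excl$n)

    results[[slug]] <- list(demographics = demo_tab, pt_signals = pt_tab,
                            smq_signals = smq_tab, tto = tto_tab,
                            tto_days = tto$tto_days)
  }
  if (length(config$drugs) >= 2) {
    pairs <- utils::combn(config$drugs, 2, simplify = FALSE)
    cmp <- bind_rows(lapply(pairs, function(pr) {
      s1 <- results[[tolower(gsub("[^A-Za-z0-9]+", "_", pr[1]))]]$tto_days
      s2 <- results[[tolower(gsub("[^A-Za-z0-9]+", "_", pr[2]))]]$tto_days
      tibble(drug_1 = pr[1], drug_2 = pr[2],
             n_1 = length(s1), n_2 = length(s2),
             p_value = if (length(s1) > 0 && length(s2) > 0)
               compare_tto(s1, s2) else NA_real_)
    }))
    emit(cmp, file.path(output_dir, "tto_comparison.tsv"))
    results$tto_comparison <- cmp
  }
  emit(bind_rows(run_log), file.path(output_dir, "run_log.tsv"))
  invisible(results)
}
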