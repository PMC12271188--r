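#' Configuration for the synthetic report generator
#'
#' Describes a synthetic spontaneous-reporting universe with known
#' ground truth: drug market shares, per-PT background reporting rates,
#' planted reporting-rate ratios rho for chosen (drug, PT) pairs,
#' per-drug Weibull onset-time parameters, a demographic mix with
#' missingness, and rates of injected duplicate reports. The default
#' scenario mirrors a two-drug antiviral study: a rarely reported
#' first-generation drug and a ~16x more reported successor, 10 bone-related PTs plus 50
#' background PTs, planted rate ratios of the magnitude seen for
#' osteoporosis signals, and onset distributions near Weibull(1.07,
#' 1332) and Weibull(1.29, 2288) days.
#'
#' @param n_reports number of base reports (before duplicate injection).
#' @param drugs tibble with `name`, `share` (shares sum to 1).
#' @param events tibble with `pt`, `rate` (background probability that a
#'   report carries the PT).
#' @param planted_rr named numeric vector of rate ratios; names are
#'   `"DRUG|pt"`.
#' @param tto named list mapping drug name to `c(shape, scale)` of the
#'   Weibull onset distribution (days).
#' @param demographics list: `sex_mix` (named probs for female, male,
#'   unknown), `age_mean`, `age_sd`, `age_missing`, `weight_mean`,
#'   `weight_sd`, `weight_missing`, `event_date_missing`,
#'   `therapy_date_missing`.
#' @param concomitant_rate probability a report also lists one
#'   concomitant drug.
#' @param duplicate_rate fraction re-emitted as case-version duplicates
#'   (same case, higher primary_id, later receipt).
#' @param six_field_dup_rate fraction re-emitted as redundancy
#'   duplicates (new case, identical six-field key, later receipt).
#' @param seed integer seed; every draw derives from it.
#' @return a validated `faers_sim_config` list.
#' @export
faers_sim_config <- function(
    n_reports = 20000,
    drugs = NULL, events = NULL, planted_rr = NULL, tto = NULL,
    demographics = NULL, concomitant_rate = 0.3,
    duplicate_rate = 0.05, six_field_dup_rate = 0.02, seed = 1L) {
  if (is.null(drugs)) {
    # target drugs are a small slice of the reporting universe, as in a
    # real spontaneous-report database; their relative imbalance mirrors
    # a rare first-generation drug vs a widely reported successor
    drugs <- tibble(
      name = c("ADEFOVIR", "TENOFOVIR", paste0("BACKGROUND-", 1:4)),
      share = c(0.005, 0.08, 0.40, 0.28, 0.15, 0.085))
  }
  if (is.null(events)) {
    osteo <- osteoporosis_smq()$member_pts
    # fixed scenario construction, independent of `seed`
    bg <- tibble(pt = sprintf("background pt %02d", 1:50),
                 rate = withr::with_seed(990001,
                                         round(runif(50, 0.002, 0.03), 4)))
    events <- bind_rows(
      tibble(pt = osteo,
             rate = c(0.0012, 0.0002, 0.0006, 0.0002, 0.0015, 0.0045,
                      0.0004, 0.0003, 0.0002, 0.0002)),
      bg)
  }
  if (is.null(planted_rr)) {
    planted_rr <- c(
      "ADEFOVIR|osteoporosis" = 38, "ADEFOVIR|bone density decreased" = 11,
      "TENOFOVIR|bone density decreased" = 150, "TENOFOVIR|bone loss" = 180,
      "TENOFOVIR|osteopenia" = 80, "TENOFOVIR|osteoporosis" = 55,
      "TENOFOVIR|osteoporotic fracture" = 20)
  }
  if (is.null(tto)) {
    tto <- list(ADEFOVIR = c(shape = 1.07, scale = 1331.68),
                TENOFOVIR = c(shape = 1.29, scale = 2287.95))
  }
  demographics <- utils::modifyList(list(
    sex_mix = c(female = 0.26, male = 0.62, unknown = 0.12),
    age_mean = 58, age_sd = 15, age_missing = 0.32,
    weight_mean = 70, weight_sd = 15, weight_missing = 0.88,
    event_date_missing = 0.15, therapy_date_missing = 0.25
  ), demographics %||% list())

  drugs$name <- normalize_drug_name(drugs$name)
  events$pt <- normalize_pt(events$pt)
  cfg <- structure(list(
    n_reports = as.integer(n_reports), drugs = as_tibble(drugs),
    events = as_tibble(events), planted_rr = planted_rr, tto = tto,
    demographics = demographics, concomitant_rate = concomitant_rate,
    duplicate_rate = duplicate_rate,
    six_field_dup_rate = six_field_dup_rate, seed = as.integer(seed)
  ), class = "faers_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  d <- cfg$demographics
  ok <- cfg$n_reports > 0 &&
    abs(sum(cfg$drugs$share) - 1) < 1e-8 && all(cfg$drugs$share >= 0) &&
    all(cfg$events$rate > 0 & cfg$events$rate < 1) &&
    all(is.finite(cfg$planted_rr) & cfg$planted_rr >= 0) &&
    cfg$duplicate_rate >= 0 && cfg$duplicate_rate < 1 &&
    cfg$six_field_dup_rate >= 0 && cfg$six_field_dup_rate < 1 &&
    abs(sum(d$sex_mix) - 1) < 1e-8
  if (!ok) abort("invalid synthetic-data configuration")
  bad <- names(cfg$planted_rr)[!sub("\\|.*", "", names(cfg$planted_rr))
                               %in% cfg$drugs$name]
  if (length(bad) > 0) {
    abort(paste0("planted_rr names an unknown drug: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

#' Generate synthetic individual case safety reports
#'
#' Draws `n_reports` reports from the configured universe: the
#' primary-suspect drug by market share; each PT independently with
#' probability `rate * rho(drug, pt)` capped at 0.99 (a report that draws
#' no event gets the filler PT `"drug ineffective"` so every report
#' carries a reaction while the study PTs keep their exact rates);
#' demographics and missingness per config; therapy start uniform over
#' 2004-01-01 to 2024-09-30; event date = start + a Weibull onset draw
#' rounded up to whole days (exponential with 500-day mean for drugs
#' without configured onset parameters); receipt shortly after the
#' event. Duplicates are then injected per [inject_duplicates()].
#' Fully reproducible from `config$seed`.
#'
#' @param config a [faers_sim_config()].
#' @return a list: `reports` (an `icsr_tbl`, duplicates included),
#'   `manifest` (planted parameters and injected-duplicate ledger).
#' @export
simulate_faers <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_faers_impl(config))
}

simulate_faers_impl <- function(cfg) {
  n <- cfg$n_reports
  dg <- cfg$drugs
  ev <- cfg$events
  dem <- cfg$demographics
  j <- nrow(ev)

  drug_idx <- sample.int(nrow(dg), n, replace = TRUE, prob = dg$share)
  drug <- dg$name[drug_idx]

  # per-(drug, pt) event probability: rate * rho, capped
  pmat <- matrix(rep(ev$rate, each = nrow(dg)), nrow = nrow(dg))
  if (length(cfg$planted_rr) > 0) {
    key <- strsplit(names(cfg$planted_rr), "|", fixed = TRUE)
    for (k in seq_along(key)) {
      di <- match(normalize_drug_name(key[[k]][1]), dg$name)
      ji <- match(normalize_pt(key[[k]][2]), ev$pt)
      if (!is.na(di) && !is.na(ji)) {
        pmat[di, ji] <- pmat[di, ji] * cfg$planted_rr[k]
      }
    }
  }
  pmat <- pmin(pmat, 0.99)

  hits <- matrix(runif(n * j), n, j) < pmat[drug_idx, , drop = FALSE]
  # a report must carry at least one reaction; event-less reports get a
  # filler PT so the configured rates of the study PTs stay exact
  none <- !rowSums(hits)
  w <- which(hits, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  long_row <- c(w[, 1], which(none))
  long_pt <- c(ev$pt[w[, 2]], rep("drug ineffective", sum(none)))
  o <- order(long_row)
  reactions <- vctrs::vec_split(long_pt[o], long_row[o])$val

  sex <- sample(names(dem$sex_mix), n, replace = TRUE, prob = dem$sex_mix)
  age <- round(pmin(pmax(rnorm(n, dem$age_mean, dem$age_sd), 0.1), 100), 1)
  age[runif(n) < dem$age_missing] <- NA_real_
  weight <- round(pmax(rnorm(n, dem$weight_mean, dem$weight_sd), 2), 1)
  weight[runif(n) < dem$weight_missing] <- NA_real_
  country <- sample(c("US", "CN", "JP", "FR", NA), n, replace = TRUE,
                    prob = c(0.45, 0.25, 0.15, 0.1, 0.05))
  occupation <- sample(c("MD", "CN", "OT", "PH", "HP", NA), n,
                       replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1))

  day0 <- as.Date("2004-01-01")
  day1 <- as.Date("2024-09-30")
  start <- day0 + floor(runif(n, 0, as.numeric(day1 - day0) + 1))
  shape <- rep(1, n); scale <- rep(721.35, n)  # exp. mean ~500 d default
  for (nm in names(cfg$tto)) {
    i <- drug == normalize_drug_name(nm)
    shape[i] <- cfg$tto[[nm]][["shape"]]
    scale[i] <- cfg$tto[[nm]][["scale"]]
  }
  onset <- pmax(1, ceiling(rweibull(n, shape, scale)))
  event_date <- start + onset
  receipt <- event_date + floor(runif(n, 1, 181))
  event_date[runif(n) < dem$event_date_missing] <- NA
  start[runif(n) < dem$therapy_date_missing] <- NA

  conc <- runif(n) < cfg$concomitant_rate
  conc_drug <- dg$name[sample.int(nrow(dg), n, replace = TRUE,
                                  prob = dg$share)]
  n_conc <- sum(conc)
  dl_row <- c(seq_len(n), which(conc))
  dl_name <- c(drug, conc_drug[conc])
  dl_role <- rep(c("PS", "C"), c(n, n_conc))
  dl_start <- c(start, rep(as.Date(NA), n_conc))
  o <- order(dl_row, dl_role == "C")  # PS entry first within a report
  dl_row <- dl_row[o]
  drug_names <- vctrs::vec_split(dl_name[o], dl_row)$val
  drug_roles <- vctrs::vec_split(dl_role[o], dl_row)$val
  drug_starts <- vctrs::vec_split(dl_start[o], dl_row)$val
  drug_ends <- vctrs::vec_split(rep(as.Date(NA), length(dl_row)),
                                dl_row)$val

  out_codes <- sample(c("OT", "HO", "DE", "DS", "LT", "CA", "RI", ""),
                      n, replace = TRUE,
                      prob = c(0.5, 0.2, 0.05, 0.02, 0.01, 0.01, 0.005,
                               0.205))
  outcomes <- as.list(out_codes)
  outcomes[out_codes == ""] <- list(character(0))

  base <- new_icsr_tbl(tibble(
    primary_id = 10000000 + seq_len(n),
    case_id = as.character(20000000 + seq_len(n)),
    receipt_date = receipt,
    event_date = event_date,
    event_date_imputed = FALSE,
    sex = sex, age_years = age, weight_kg = weight,
    country = country, occupation = occupation,
    outcomes = outcomes,
    drug_names = drug_names, drug_roles = drug_roles,
    drug_starts = drug_starts, drug_ends = drug_ends,
    reactions = reactions
  ))

  inj <- inject_duplicates(base, config = cfg)
  manifest <- list(
    seed = cfg$seed, n_reports = n,
    drugs = cfg$drugs, events = cfg$events,
    planted_rr = as.list(cfg$planted_rr), tto = cfg$tto,
    duplicate_rate = cfg$duplicate_rate,
    six_field_dup_rate = cfg$six_field_dup_rate,
    duplicates = inj$manifest
  )
  list(reports = inj$reports, manifest = manifest)
}

#' Inject duplicate reports
#'
#' Re-emits a fraction of reports as case-version duplicates (same
#' `case_id`, higher `primary_id`, receipt 30 days later -- emulating a
#' follow-up version of the same case) and a fraction as redundancy
#' duplicates (new `case_id` and `primary_id` but identical six-field
#' key, receipt 60 days later -- emulating independent resubmission).
#' [deduplicate_reports()] must remove exactly the injected copies'
#' losers.
#'
#' @param reports base `icsr_tbl`.
#' @param config a [faers_sim_config()] (only the two rates are used).
#' @return list: `reports` (base plus duplicates), `manifest` (tibble
#'   `kind`, `source_primary_id`, `dup_primary_id`).
#' @export
inject_duplicates <- function(reports, config) {
  n <- nrow(reports)
  n_ver <- round(config$duplicate_rate * n)
  n_red <- round(config$six_field_dup_rate * n)
  if (n_ver + n_red == 0) {
    return(list(reports = reports,
                manifest = tibble(kind = character(),
                                  source_primary_id = numeric(),
                                  dup_primary_id = numeric())))
  }
  pick <- sample.int(n, min(n_ver + n_red, n))
  ver_i <- pick[seq_len(min(n_ver, length(pick)))]
  red_i <- setdiff(pick, ver_i)[seq_len(min(n_red, length(pick) - length(ver_i)))]
  top <- max(reports$primary_id)

  ver <- vctrs::vec_slice(reports, ver_i)
  if (nrow(ver) > 0) {
    ver$primary_id <- top + seq_len(nrow(ver))
    ver$receipt_date <- ver$receipt_date + 30
    # follow-up versions may update a free field; the six-field key may
    # change, stage 1 must still collapse them via case_id
    ver$weight_kg <- ifelse(is.na(ver$weight_kg), 75, ver$weight_kg + 1)
  }
  red <- vctrs::vec_slice(reports, red_i)
  if (nrow(red) > 0) {
    red$primary_id <- top + nrow(ver) + seq_len(nrow(red))
    red$case_id <- paste0("R", red$case_id)
    red$receipt_date <- red$receipt_date + 60
  }
  manifest <- bind_rows(
    tibble(kind = "version",
           source_primary_id = reports$primary_id[ver_i],
           dup_primary_id = ver$primary_id),
    tibble(kind = "redundancy",
           source_primary_id = reports$primary_id[red_i],
           dup_primary_id = red$primary_id)
  )
  out <- bind_rows(reports, ver, red)
  out <- arrange(out, .data$primary_id)
  list(reports = new_icsr_tbl(out), manifest = manifest)
}

#' Write an `icsr_tbl` as FAERS-style quarterly ASCII files
#'
#' Emits the five `'$'`-delimited tables (`DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `THER.txt`, `OUTC.txt`) in the post-2012 column dialect
#' that [read_faers_quarter()] consumes; reading them back round-trips
#' every populated field.
#'
#' @param reports an `icsr_tbl`.
#' @param dir output directory (created if needed).
#' @param suffix optional file-name suffix (e.g. `"24Q3"`).
#' @return the five file paths, invisibly.
#' @export
write_faers_quarter <- function(reports, dir, suffix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- function(stem) file.path(dir, paste0(stem, suffix, ".txt"))
  sex_code <- c(female = "F", male = "M", unknown = "")
  demo <- tibble(
    primaryid = format(reports$primary_id, scientific = FALSE, trim = TRUE),
    caseid = reports$case_id,
    fda_dt = format_faers_date(reports$receipt_date),
    event_dt = format_faers_date(reports$event_date),
    age = ifelse(is.na(reports$age_years), "",
                 format(reports$age_years, trim = TRUE, digits = 10)),
    age_cod = ifelse(is.na(reports$age_years), "", "YR"),
    sex = unname(sex_code[reports$sex]),
    wt = ifelse(is.na(reports$weight_kg), "",
                format(reports$weight_kg, trim = TRUE, digits = 10)),
    wt_cod = ifelse(is.na(reports$weight_kg), "", "KG"),
    reporter_country = ifelse(is.na(reports$country), "",
                              reports$country),
    occp_cod = ifelse(is.na(reports$occupation), "", reports$occupation)
  )
  dl <- icsr_drug_long(reports)
  dl <- group_by(dl, .data$primary_id)
  dl <- mutate(dl, drug_seq = row_number())
  dl <- ungroup(dl)
  drug <- tibble(
    primaryid = format(dl$primary_id, scientific = FALSE, trim = TRUE),
    drug_seq = dl$drug_seq,
    drugname = dl$drug_name,
    role_cod = dl$role_code
  )
  ther <- tibble(
    primaryid = drug$primaryid,
    dsg_drug_seq = dl$drug_seq,
    start_dt = format_faers_date(dl$therapy_start),
    end_dt = format_faers_date(dl$therapy_end)
  )
  ther <- ther[nzchar(ther$start_dt) | nzchar(ther$end_dt), ]
  rl <- icsr_reaction_long(reports)
  reac <- tibble(
    primaryid = format(rl$primary_id, scientific = FALSE, trim = TRUE),
    pt = rl$pt
  )
  ol <- tibble(
    primary_id = rep(reports$primary_id, lengths(reports$outcomes)),
    outc_cod = vctrs::list_unchop(reports$outcomes, ptype = character())
  )
  outc <- tibble(
    primaryid = format(ol$primary_id, scientific = FALSE, trim = TRUE),
    outc_cod = ol$outc_cod
  )
  paths <- c(fn("DEMO"), fn("DRUG"), fn("REAC"), fn("THER"), fn("OUTC"))
  readr::write_delim(demo, paths[1], delim = "$")
  readr::write_delim(drug, paths[2], delim = "$")
  readr::write_delim(reac, paths[3], delim = "$")
  readr::write_delim(ther, paths[4], delim = "$")
  readr::write_delim(outc, paths[5], delim = "$")
  invisible(paths)
}

#' Generate and write a complete synthetic quarter
#'
#' Convenience wrapper: [simulate_faers()] then [write_faers_quarter()]
#' plus a `manifest.json` recording every planted parameter and
#' injected duplicate.
#'
#' @inheritParams simulate_faers
#' @param dir output directory.
#' @return the simulation list (`reports`, `manifest`), invisibly.
#' @export
simulate_faers_files <- function(config, dir) {
  sim <- simulate_faers(config)
  write_faers_quarter(sim$reports, dir)
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", Date = "ISO8601")
  invisible(sim)
}
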