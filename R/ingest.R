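#' Read one quarter of FAERS-style ASCII tables
#'
#' Reads the five `'$'`-delimited tables of a quarterly extract (post-2012
#' column set) and assembles one [new_icsr_tbl()] row per demographic
#' record. Rows that cannot be joined or parsed are counted in a parse log,
#' never silently dropped: orphan DRUG/REAC/THER/OUTC rows (a `primaryid`
#' with no DEMO row) and DEMO rows with no reaction are logged with file,
#' line number and reason.
#'
#' @param demo_path,drug_path,reac_path,ther_path,outc_path paths to the
#'   DEMO, DRUG, REAC, THER and OUTC tables.
#' @return an `icsr_tbl`; the parse log is attached as attribute
#'   `"parse_log"` (a tibble with columns `file`, `line`, `reason`).
#' @seealso [write_parse_log()], [deduplicate_reports()]
#' @export
#' @examples
#' dir <- tempfile(); sim <- simulate_faers_files(
#'   faers_sim_config(n_reports = 50, seed = 1), dir)
#' reports <- read_faers_quarter(
#'   file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
#'   file.path(dir, "REAC.txt"), file.path(dir, "THER.txt"),
#'   file.path(dir, "OUTC.txt"))
#' nrow(reports)
read_faers_quarter <- function(demo_path, drug_path, reac_path,
                               ther_path, outc_path) {
  paths <- c(DEMO = demo_path, DRUG = drug_path, REAC = reac_path,
             THER = ther_path, OUTC = outc_path)
  for (p in paths) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  read1 <- function(p) {
    readr::read_delim(p, delim = "$", col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE,
      na = character())
  }
  demo <- read1(paths[["DEMO"]])
  drug <- read1(paths[["DRUG"]])
  reac <- read1(paths[["REAC"]])
  ther <- read1(paths[["THER"]])
  outc <- read1(paths[["OUTC"]])

  log <- list()
  note <- function(file, line, reason) {
    log[[length(log) + 1]] <<- tibble(file = file, line = line,
                                      reason = reason)
  }

  # data row i sits on physical line i + 1 (header is line 1)
  bad_id <- is.na(suppressWarnings(as.numeric(demo$primaryid)))
  if (any(bad_id)) {
    note(basename(paths[["DEMO"]]), which(bad_id) + 1L,
         "unparseable primaryid")
    demo <- demo[!bad_id, ]
  }
  known <- demo$primaryid
  orphan <- function(tab, file) {
    miss <- !(tab$primaryid %in% known)
    if (any(miss)) note(file, which(miss) + 1L, "primaryid not in DEMO")
    tab[!miss, ]
  }
  drug <- orphan(drug, basename(paths[["DRUG"]]))
  reac <- orphan(reac, basename(paths[["REAC"]]))
  ther <- orphan(ther, basename(paths[["THER"]]))
  outc <- orphan(outc, basename(paths[["OUTC"]]))

  # a report with no reaction row cannot enter analysis
  no_reac <- !(demo$primaryid %in% reac$primaryid)
  if (any(no_reac)) {
    note(basename(paths[["DEMO"]]), which(no_reac) + 1L,
         "no REAC row for report")
    demo <- demo[!no_reac, ]
  }

  ids <- demo$primaryid
  ev <- parse_faers_date(demo$event_dt)

  drug_long <- tibble(
    primary_id = drug$primaryid,
    drug_seq = drug$drug_seq,
    drug_name = normalize_drug_name(drug$drugname),
    role_code = toupper(stringr::str_trim(drug$role_cod))
  )
  ther_long <- tibble(
    primary_id = ther$primaryid,
    drug_seq = ther$dsg_drug_seq,
    therapy_start = strip_date(parse_faers_date(ther$start_dt)),
    therapy_end = strip_date(parse_faers_date(ther$end_dt))
  )
  drug_long <- left_join(drug_long, ther_long,
                         by = c("primary_id", "drug_seq"))
  drug_long$drug_seq <- NULL

  reac_long <- tibble(primary_id = reac$primaryid,
                      pt = normalize_pt(reac$pt))
  outc_long <- tibble(primary_id = outc$primaryid,
                      code = toupper(stringr::str_trim(outc$outc_cod)))

  sex_raw <- toupper(stringr::str_trim(demo$sex %||% demo$gndr_cod))
  out <- tibble(
    primary_id = as.numeric(ids),
    case_id = stringr::str_trim(demo$caseid),
    receipt_date = strip_date(parse_faers_date(demo$fda_dt)),
    event_date = strip_date(ev),
    event_date_imputed = attr(ev, "imputed"),
    sex = dplyr::case_when(sex_raw == "F" ~ "female",
                           sex_raw == "M" ~ "male",
                           TRUE ~ "unknown"),
    age_years = age_to_years(demo$age, demo$age_cod),
    weight_kg = suppressWarnings(as.numeric(demo$wt)),
    country = dplyr::na_if(stringr::str_trim(demo$reporter_country), ""),
    occupation = dplyr::na_if(stringr::str_trim(demo$occp_cod), ""),
    outcomes = split_by_id(outc_long, ids, col = "code"),
    drug_names = split_by_id(drug_long, ids, col = "drug_name"),
    drug_roles = split_by_id(drug_long, ids, col = "role_code"),
    drug_starts = split_by_id(drug_long, ids, col = "therapy_start"),
    drug_ends = split_by_id(drug_long, ids, col = "therapy_end"),
    reactions = lapply(split_by_id(reac_long, ids, col = "pt"),
                       function(x) unique(x[!is.na(x)]))
  )
  out$weight_kg[!is.na(out$weight_kg) & out$weight_kg < 0] <- NA_real_

  parse_log <- if (length(log) > 0) bind_rows(log) else
    tibble(file = character(), line = integer(), reason = character())
  out <- new_icsr_tbl(out)
  attr(out, "parse_log") <- parse_log
  out
}

#' Write a parse log as TSV
#'
#' @param reports an `icsr_tbl` from [read_faers_quarter()].
#' @param path output path.
#' @return the log tibble, invisibly.
#' @export
write_parse_log <- function(reports, path) {
  log <- attr(reports, "parse_log") %||%
    tibble(file = character(), line = integer(), reason = character())
  readr::write_tsv(log, path)
  invisible(log)
}

# Six-field redundancy key: event date, age, sex, reaction set, drug-name
# set, country. Missing fields enter as an explicit sentinel.
six_field_key <- function(reports) {
  paste(
    key_chr(format(reports$event_date, "%Y%m%d")),
    key_chr(reports$age_years),
    key_chr(reports$sex),
    vapply(reports$reactions,
           function(x) paste(sort(x), collapse = "|"), character(1)),
    vapply(reports$drug_names,
           function(x) paste(sort(unique(x)), collapse = "|"),
           character(1)),
    key_chr(reports$country),
    sep = "\x02"
  )
}

#' Remove duplicate reports
#'
#' Two-stage deduplication of spontaneous reports. Stage 1 applies the
#' latest-version rule: among reports sharing a `case_id`, only the one
#' with the greatest `primary_id` (the most recent version) is kept.
#' Stage 2 removes redundant resubmissions: among the survivors, groups
#' identical on the six-field key -- event date, age, sex, the set of
#' reaction PTs, the set of drug names, and country -- are collapsed to
#' the record with the latest receipt date (ties broken by greatest
#' `primary_id`). Missing key fields are explicit sentinels, so two
#' reports missing the same field can still be judged duplicates.
#'
#' The operation is idempotent, never increases the report count, and
#' never alters a surviving record. Output is sorted by `primary_id`.
#'
#' @param reports an `icsr_tbl`.
#' @return the deduplicated `icsr_tbl`, with attribute `"dedup_log"`
#'   (tibble of `stage`, `removed`).
#' @export
deduplicate_reports <- function(reports) {
  n0 <- nrow(reports)
  if (n0 == 0) {
    out <- reports
    attr(out, "dedup_log") <- tibble(
      stage = c("case_version", "six_field"), removed = c(0L, 0L))
    return(out)
  }
  # stage 1: keep greatest primary_id per case_id
  case <- key_chr(reports$case_id)
  ord <- order(case, -reports$primary_id)
  keep1 <- !duplicated(case[ord])
  s1 <- vctrs::vec_slice(reports, sort(ord[keep1]))
  n1 <- nrow(s1)

  # stage 2: collapse identical six-field keys to latest receipt date
  key <- six_field_key(s1)
  rd <- s1$receipt_date
  rd_num <- ifelse(is.na(rd), -Inf, as.numeric(rd))
  ord2 <- order(key, -rd_num, -s1$primary_id)
  keep2 <- !duplicated(key[ord2])
  out <- vctrs::vec_slice(s1, sort(ord2[keep2]))
  out <- arrange(out, .data$primary_id)

  out <- new_icsr_tbl(out)
  attr(out, "parse_log") <- attr(reports, "parse_log")
  attr(out, "dedup_log") <- tibble(
    stage = c("case_version", "six_field"),
    removed = c(n0 - n1, n1 - nrow(out))
  )
  out
}

#' Restrict to reports naming a drug as primary suspect
#'
#' Keeps exactly the reports that carry `drug_name` with role code `PS`.
#' Reports where the drug appears only as secondary suspect, concomitant
#' or interacting are excluded.
#'
#' @param reports an `icsr_tbl`.
#' @param drug_name drug name; normalized (uppercase, squished) before
#'   exact matching.
#' @return the filtered `icsr_tbl`; empty with a warning when the drug is
#'   never primary suspect.
#' @export
filter_primary_suspect <- function(reports, drug_name) {
  target <- normalize_drug_name(drug_name)
  if (nrow(reports) == 0) return(reports)
  long <- icsr_drug_long(reports, dates = FALSE)
  hit_ids <- unique(long$primary_id[long$drug_name %in% target &
                                      long$role_code == "PS"])
  out <- vctrs::vec_slice(reports, reports$primary_id %in% hit_ids)
  if (nrow(out) == 0) {
    warn(paste0("no report names ", target, " as primary suspect"))
  }
  new_icsr_tbl(out)
}
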