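#' Individual case safety report tables
#'
#' The pipeline's central container is an `icsr_tbl`: a tibble with one row
#' per individual case safety report (ICSR) and list columns for the
#' report's drugs and reactions. All user-facing verbs take an `icsr_tbl`
#' first and return one (or a plain tibble of results), so analyses chain
#' with the pipe.
#'
#' Columns:
#' \describe{
#'   \item{primary_id}{report version identifier, unique after deduplication}
#'   \item{case_id}{case identifier shared by versions of one case}
#'   \item{receipt_date, event_date}{`Date`; `event_date` may be `NA`}
#'   \item{event_date_imputed}{`TRUE` when a partial date was completed to
#'     the 1st of the month/year}
#'   \item{sex}{`"male"`, `"female"` or `"unknown"`}
#'   \item{age_years, weight_kg}{non-negative, `NA` when unreported}
#'   \item{country}{reporter country code, `NA` when unreported}
#'   \item{occupation}{reporter occupation code (`MD`, `CN`, `PH`, ...)}
#'   \item{outcomes}{list of outcome code sets (`CA`, `DE`, `DS`, `HO`,
#'     `LT`, `OT`, `RI`)}
#'   \item{drug_names, drug_roles, drug_starts, drug_ends}{parallel list
#'     columns describing the report's drug entries: normalized names,
#'     role codes (`PS`/`SS`/`C`/`I`) and therapy start/end dates}
#'   \item{reactions}{list of character vectors of normalized (lowercase)
#'     MedDRA preferred terms}
#' }
#'
#' @param x a data frame with the columns above.
#' @return `new_icsr_tbl()` returns `x` with class `icsr_tbl` prepended.
#' @export
new_icsr_tbl <- function(x) {
  needed <- c("primary_id", "case_id", "receipt_date", "event_date",
              "event_date_imputed", "sex", "age_years", "weight_kg",
              "country", "occupation", "outcomes", "drug_names",
              "drug_roles", "drug_starts", "drug_ends", "reactions")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("icsr_tbl is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_age <- !is.na(x$age_years) & x$age_years < 0
  bad_wt <- !is.na(x$weight_kg) & x$weight_kg < 0
  if (any(bad_age) || any(bad_wt)) {
    abort("age_years and weight_kg must be non-negative when present")
  }
  x <- as_tibble(x)
  class(x) <- unique(c("icsr_tbl", class(x)))
  x
}

#' @rdname new_icsr_tbl
#' @export
is_icsr_tbl <- function(x) inherits(x, "icsr_tbl")

# Long view of the drug list columns: one row per (report, drug entry).
# Therapy dates are skipped when the caller only needs names and roles;
# flattening Date lists element-wise is the single hottest operation on
# database-scale collections.
icsr_drug_long <- function(reports, dates = TRUE) {
  n_each <- lengths(reports$drug_names)
  flat_chr <- function(x) as.character(unlist(x, use.names = FALSE))
  flat_date <- function(x) {
    v <- unlist(x, use.names = FALSE)
    as.Date(if (is.null(v)) numeric(0) else as.numeric(v),
            origin = "1970-01-01")
  }
  out <- tibble(
    primary_id = rep(reports$primary_id, n_each),
    drug_name = flat_chr(reports$drug_names),
    role_code = flat_chr(reports$drug_roles)
  )
  if (dates) {
    out$therapy_start <- flat_date(reports$drug_starts)
    out$therapy_end <- flat_date(reports$drug_ends)
  }
  out
}

# Long view of the reactions list column: one row per (report, PT).
icsr_reaction_long <- function(reports) {
  r <- reports$reactions
  tibble(
    primary_id = rep(reports$primary_id, lengths(r)),
    pt = vctrs::list_unchop(r, ptype = character())
  )
}

#' @export
print.icsr_tbl <- function(x, ...) {
  cat(sprintf("# ICSR collection: %d reports\n", nrow(x)))
  NextMethod()
}
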