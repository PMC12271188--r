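#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n row_number across
#'   first distinct count rename if_else slice_max
#' @importFrom tibble tibble as_tibble
#' @importFrom stats optim pchisq dnbinom pgamma qgamma rweibull dweibull
#'   rnorm runif rbinom digamma setNames chisq.test fisher.test wilcox.test
#'   median sd quantile
NULL

# Normalize a drug name: uppercase, trim, collapse internal whitespace.
# Matching is exact after normalization; no ingredient/brand mapping.
normalize_drug_name <- function(x) {
  x <- stringr::str_squish(toupper(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  x
}

# Normalize a MedDRA preferred term: lowercase, trim, collapse whitespace.
normalize_pt <- function(x) {
  x <- stringr::str_squish(tolower(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Parse FAERS-style numeric dates
#'
#' Dates in quarterly ASCII files are `YYYYMMDD` integers; partial dates
#' (`YYYYMM`, `YYYY`) occur when the reporter did not supply a day or month.
#' Partial dates are completed to the first of the month/year so downstream
#' day arithmetic is deterministic; the returned vector carries an
#' `"imputed"` attribute flagging completed values.
#'
#' @param x character or numeric vector of raw date fields.
#' @return a `Date` vector with a logical `"imputed"` attribute.
#' @keywords internal
parse_faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  imputed <- !is.na(x) & nchar(x) < 8L
  x8 <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    nchar(x) == 8L ~ x,
    nchar(x) == 6L ~ paste0(x, "01"),
    nchar(x) == 4L ~ paste0(x, "0101"),
    TRUE ~ NA_character_
  )
  out <- as.Date(x8, format = "%Y%m%d")
  imputed[is.na(out)] <- FALSE
  attr(out, "imputed") <- imputed
  out
}

strip_date <- function(d) {
  attributes(d) <- list(class = "Date")
  d
}

format_faers_date <- function(d) {
  ifelse(is.na(d), "", format(d, "%Y%m%d"))
}

# FAERS age unit codes -> years. Unknown code or unparseable value -> NA.
age_to_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(stringr::str_trim(as.character(unit)))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
            DY = 1 / 365.25, HR = 1 / 8766)
  m <- unname(mult[unit])
  m[is.na(unit) | !nzchar(unit)] <- 1  # bare ages are years in practice
  out <- age * m
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

# Split a long table into a list column aligned with `ids`; ids absent from
# `long` get a zero-row/zero-length element.
split_by_id <- function(long, ids, col = NULL) {
  key <- vctrs::vec_group_loc(long$primary_id)
  idx <- key$loc[match(ids, key$key)]
  empty <- integer(0)
  idx[vapply(idx, is.null, logical(1))] <- list(empty)
  values <- long[[col]]
  lapply(idx, function(i) values[i])
}

# Sentinel-aware key component: missing values become an explicit token so
# two reports missing the same field can still match.
key_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "\x01NA"
  x
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}
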