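#' Load a standardized MedDRA query (SMQ) definition
#'
#' An SMQ here is a named, ordered set of preferred terms (PTs) standing
#' for one medical condition. Definitions are plain text (one PT per line,
#' `#` comments allowed) or a JSON array of strings. PTs are normalized to
#' lowercase; order is preserved; case-insensitive duplicates are a
#' configuration error.
#'
#' @param path path to the definition file.
#' @param name SMQ name; default is the file name without extension.
#' @return an `smq_definition`: list with `name` and `member_pts`.
#' @export
load_smq <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("SMQ file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    lines <- readr::read_lines(path)
    lines <- stringr::str_trim(lines)
    lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  pts <- normalize_pt(raw)
  pts <- pts[!is.na(pts)]
  if (length(pts) == 0) abort("SMQ definition lists no preferred terms")
  if (anyDuplicated(pts)) {
    abort(paste0("duplicate PT after case normalization: ",
                 paste(unique(pts[duplicated(pts)]), collapse = ", ")))
  }
  smq_definition(pts, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' @rdname load_smq
#' @param member_pts character vector of PTs.
#' @export
smq_definition <- function(member_pts, name = "smq") {
  pts <- normalize_pt(member_pts)
  if (length(pts) == 0 || anyDuplicated(pts) || anyNA(pts)) {
    abort("member_pts must be a non-empty set, unique after lowercasing")
  }
  structure(list(name = name, member_pts = pts), class = "smq_definition")
}

#' The bundled osteoporosis SMQ (10 preferred terms)
#'
#' Bone-loss related PTs covering decreased bone density and formation,
#' osteopenia, the osteoporosis diagnoses and osteoporotic fracture.
#'
#' @return an `smq_definition` with 10 members.
#' @export
osteoporosis_smq <- function() {
  load_smq(system.file("extdata", "osteoporosis_smq.txt",
                       package = "faersignal"),
           name = "osteoporosis")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("SMQ '%s': %d preferred terms\n", x$name,
              length(x$member_pts)))
  cat(paste0("  ", x$member_pts, collapse = "\n"), "\n")
  invisible(x)
}

#' Count drug-event pairs for the members of an SMQ
#'
#' For each member PT, counts `a` = reports where `drug_name` is primary
#' suspect and the PT is among the reactions, together with the sufficient
#' statistics for every 2x2 contingency table: the per-PT total over all
#' drugs (`n_event`), the drug's total report count (`n_drug`) and the
#' grand total (`n_total`). A report carrying several member PTs
#' contributes to each PT's count.
#'
#' @param reports a deduplicated `icsr_tbl` (the full background, all
#'   drugs).
#' @param drug_name target drug (normalized before matching).
#' @param smq an `smq_definition`.
#' @return a tibble with columns `drug`, `pt`, `a`, `n_event`, `n_drug`,
#'   `n_total`, one row per member PT in definition order.
#' @export
count_pt_pairs <- function(reports, drug_name, smq) {
  target <- normalize_drug_name(drug_name)
  pts <- smq$member_pts
  rl <- icsr_reaction_long(reports)
  dl <- icsr_drug_long(reports, dates = FALSE)
  ps_ids <- unique(dl$primary_id[dl$drug_name %in% target &
                                   dl$role_code == "PS"])
  n_drug <- length(ps_ids)
  n_total <- nrow(reports)
  ev_tot <- table(factor(rl$pt[rl$pt %in% pts], levels = pts))
  rl_ps <- rl[rl$primary_id %in% ps_ids, ]
  a_cnt <- table(factor(rl_ps$pt[rl_ps$pt %in% pts], levels = pts))
  tibble(
    drug = target,
    pt = pts,
    a = as.integer(a_cnt),
    n_event = as.integer(ev_tot),
    n_drug = n_drug,
    n_total = n_total
  )
}

#' Aggregate PT-level pair counts to the SMQ level
#'
#' The default convention is the PT-row sum: the SMQ-level `a` (and
#' event background `n_event`) is the sum over member PTs, so a report
#' carrying k member PTs contributes k. The alternative
#' `"unique_report"` convention counts each report once if it carries at
#' least one member PT; it needs the report collection to recount.
#'
#' @param pt_counts output of [count_pt_pairs()] for one drug.
#' @param method `"pt_sum"` (default) or `"unique_report"`.
#' @param reports required for `method = "unique_report"`.
#' @param smq required for `method = "unique_report"`.
#' @param label row label for the aggregate, default `"SMQ-TOTAL"`.
#' @return a one-row tibble with the same columns as `pt_counts`.
#' @export
aggregate_smq <- function(pt_counts, method = c("pt_sum", "unique_report"),
                          reports = NULL, smq = NULL,
                          label = "SMQ-TOTAL") {
  method <- match.arg(method)
  if (method == "pt_sum") {
    tibble(
      drug = pt_counts$drug[1],
      pt = label,
      a = sum(pt_counts$a),
      n_event = sum(pt_counts$n_event),
      n_drug = pt_counts$n_drug[1],
      n_total = pt_counts$n_total[1]
    )
  } else {
    if (is.null(reports) || is.null(smq)) {
      abort("unique_report aggregation needs `reports` and `smq`")
    }
    target <- pt_counts$drug[1]
    rl <- icsr_reaction_long(reports)
    dl <- icsr_drug_long(reports, dates = FALSE)
    ps_ids <- unique(dl$primary_id[dl$drug_name %in% target &
                                     dl$role_code == "PS"])
    hit_ids <- unique(rl$primary_id[rl$pt %in% smq$member_pts])
    tibble(
      drug = target,
      pt = label,
      a = sum(ps_ids %in% hit_ids),
      n_event = length(hit_ids),
      n_drug = length(ps_ids),
      n_total = nrow(reports)
    )
  }
}

#' Pair counts for every observed drug-event combination
#'
#' One row per (primary-suspect drug, PT) pair present in the data,
#' with the same sufficient-statistic columns as [count_pt_pairs()].
#' This is the input for fitting the empirical-Bayes prior across the
#' whole dataset ([fit_mgps_prior()]).
#'
#' @param reports a deduplicated `icsr_tbl`.
#' @return a tibble with `drug`, `pt`, `a`, `n_drug`, `n_event`,
#'   `n_total`.
#' @export
all_pair_counts <- function(reports) {
  rl <- icsr_reaction_long(reports)
  dl <- icsr_drug_long(reports, dates = FALSE)
  ps <- distinct(dl[dl$role_code == "PS", c("primary_id", "drug_name")])
  pairs <- inner_join(ps, rl, by = "primary_id",
                      relationship = "many-to-many")
  pair_n <- count(pairs, .data$drug_name, .data$pt, name = "a")
  drug_n <- count(ps, .data$drug_name, name = "n_drug")
  ev_n <- count(distinct(rl), .data$pt, name = "n_event")
  out <- left_join(pair_n, drug_n, by = "drug_name")
  out <- left_join(out, ev_n, by = "pt")
  out$n_total <- nrow(reports)
  rename(out, drug = "drug_name")
}
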