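test_that("an empty DEMO file yields an empty collection with nothing skipped", {
  dir <- withr::local_tempdir()
  empty <- mk_reports(mk_report())[0, ]
  write_faers_quarter(new_icsr_tbl(empty), dir)
  out <- read_faers_quarter(
    file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
    file.path(dir, "REAC.txt"), file.path(dir, "THER.txt"),
    file.path(dir, "OUTC.txt"))
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "parse_log")), 0)
})

test_that("generator output round-trips through the reader field for field", {
  for (seed in c(3, 11)) {
    cfg <- tiny_sim_config(n = 200, seed = seed)
    sim <- simulate_faers(cfg)
    dir <- withr::local_tempdir()
    write_faers_quarter(sim$reports, dir)
    back <- read_faers_quarter(
      file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
      file.path(dir, "REAC.txt"), file.path(dir, "THER.txt"),
      file.path(dir, "OUTC.txt"))
    orig <- sim$reports
    expect_equal(back$primary_id, orig$primary_id)
    expect_equal(back$case_id, orig$case_id)
    expect_equal(back$receipt_date, orig$receipt_date)
    expect_equal(back$event_date, orig$event_date)
    expect_equal(back$sex, orig$sex)
    expect_equal(back$age_years, orig$age_years)
    expect_equal(back$weight_kg, orig$weight_kg)
    expect_equal(back$country, orig$country)
    expect_equal(back$occupation, orig$occupation)
    expect_equal(back$outcomes, unname(orig$outcomes))
    expect_equal(lapply(back$reactions, sort),
                 lapply(orig$reactions, sort))
    bd <- getFromNamespace("icsr_drug_long", "faersignal")
    expect_equal(bd(back)[c("primary_id", "drug_name", "role_code",
                            "therapy_start")],
                 bd(orig)[c("primary_id", "drug_name", "role_code",
                            "therapy_start")])
  }
})

test_that("orphan rows land in the parse log without changing the collection", {
  dir <- withr::local_tempdir()
  rep1 <- mk_reports(mk_report(primary_id = 1))
  write_faers_quarter(rep1, dir)
  # append a DRUG row whose primaryid matches no DEMO row
  cat("99$1$GHOST DRUG$PS\n", file = file.path(dir, "DRUG.txt"),
      append = TRUE)
  out <- read_faers_quarter(
    file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
    file.path(dir, "REAC.txt"), file.path(dir, "THER.txt"),
    file.path(dir, "OUTC.txt"))
  expect_equal(nrow(out), 1)
  log <- attr(out, "parse_log")
  expect_equal(nrow(log), 1)
  expect_match(log$reason, "not in DEMO")
  expect_equal(log$file, "DRUG.txt")
})

test_that("a DEMO row without any reaction is excluded and logged", {
  dir <- withr::local_tempdir()
  reps <- mk_reports(mk_report(primary_id = 1), mk_report(primary_id = 2))
  write_faers_quarter(reps, dir)
  reac <- readLines(file.path(dir, "REAC.txt"))
  writeLines(reac[!grepl("^2\\$", reac)], file.path(dir, "REAC.txt"))
  out <- read_faers_quarter(
    file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
    file.path(dir, "REAC.txt"), file.path(dir, "THER.txt"),
    file.path(dir, "OUTC.txt"))
  expect_equal(out$primary_id, 1)
  expect_match(attr(out, "parse_log")$reason, "no REAC row")
})

test_that("a missing input file is fatal", {
  expect_error(read_faers_quarter("nope.txt", "nope.txt", "nope.txt",
                                  "nope.txt", "nope.txt"),
               "not found")
})

test_that("partial dates are completed to the 1st and flagged", {
  pd <- getFromNamespace("parse_faers_date", "faersignal")
  d <- pd(c("20200315", "202003", "2020", "", "banana"))
  expect_equal(as.character(d),
               c("2020-03-15", "2020-03-01", "2020-01-01", NA, NA))
  expect_equal(attr(d, "imputed"), c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("FAERS age-unit codes convert to years; unknown codes give NA", {
  a2y <- getFromNamespace("age_to_years", "faersignal")
  expect_equal(a2y(c(6, 60, 18, 104, 730.5, 8766),
                   c("DEC", "YR", "MON", "WK", "DY", "HR")),
               c(60, 60, 1.5, 104 * 7 / 365.25, 2, 1))
  expect_true(is.na(a2y(5, "EON")))
  expect_true(is.na(a2y(-3, "YR")))
})

test_that("deduplication leaves an already-unique collection untouched", {
  reps <- mk_reports(
    mk_report(primary_id = 1, case_id = "A", reactions = "osteoporosis"),
    mk_report(primary_id = 2, case_id = "B", reactions = "bone loss"),
    mk_report(primary_id = 3, case_id = "C", age_years = 61))
  out <- deduplicate_reports(reps)
  expect_equal(out$primary_id, reps$primary_id)
  expect_equal(attr(out, "dedup_log")$removed, c(0L, 0L))
})

test_that("the latest case version (greatest primary_id) wins stage 1", {
  reps <- mk_reports(
    mk_report(primary_id = 100, case_id = "C1", weight_kg = 70),
    mk_report(primary_id = 200, case_id = "C1", weight_kg = 72))
  out <- deduplicate_reports(reps)
  expect_equal(out$primary_id, 200)
  expect_equal(out$weight_kg, 72)
})

test_that("six-field redundancy keeps the record with the latest receipt", {
  reps <- mk_reports(
    mk_report(primary_id = 1, case_id = "A",
              receipt_date = as.Date("2020-01-01")),
    mk_report(primary_id = 2, case_id = "B",
              receipt_date = as.Date("2021-01-01")))
  out <- deduplicate_reports(reps)
  expect_equal(out$primary_id, 2)
  expect_equal(attr(out, "dedup_log")$removed, c(0L, 1L))
})

test_that("matching missing fields still count as duplicates (sentinel rule)", {
  reps <- mk_reports(
    mk_report(primary_id = 1, case_id = "A", event_date = as.Date(NA),
              age_years = NA_real_, receipt_date = as.Date("2020-01-01")),
    mk_report(primary_id = 2, case_id = "B", event_date = as.Date(NA),
              age_years = NA_real_, receipt_date = as.Date("2020-05-01")))
  expect_equal(deduplicate_reports(reps)$primary_id, 2)
  # a report that differs only in a present-vs-missing field is kept
  reps2 <- mk_reports(
    mk_report(primary_id = 1, case_id = "A", event_date = as.Date(NA)),
    mk_report(primary_id = 2, case_id = "B"))
  expect_equal(nrow(deduplicate_reports(reps2)), 2)
})

test_that("deduplication is idempotent and never alters survivors", {
  cfg <- tiny_sim_config(n = 400, seed = 5, duplicate_rate = 0.1,
                         six_field_dup_rate = 0.05)
  sim <- simulate_faers(cfg)
  once <- deduplicate_reports(sim$reports)
  twice <- deduplicate_reports(once)
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)
  expect_lte(nrow(once), nrow(sim$reports))
  # survivors are identical to their originals, field for field
  orig <- sim$reports[match(once$primary_id, sim$reports$primary_id), ]
  expect_equal(as.data.frame(orig), as.data.frame(once),
               ignore_attr = TRUE)
})

test_that("primary-suspect filtering honours the role code", {
  reps <- mk_reports(
    mk_report(primary_id = 1, drug = "DRUG X", role = "SS"),
    mk_report(primary_id = 2, drug = "DRUG X", role = "PS"),
    mk_report(primary_id = 3, drug = "DRUG X", role = "PS"),
    mk_report(primary_id = 4, drug = "DRUG X", role = "C"),
    mk_report(primary_id = 5, drug = "OTHER", role = "PS"))
  out <- filter_primary_suspect(reps, "drug x")  # name is normalized
  expect_equal(out$primary_id, c(2, 3))
  expect_warning(empty <- filter_primary_suspect(reps, "UNKNOWN"),
                 "primary suspect")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(filter_primary_suspect(reps[0, ], "DRUG X")), 0)
})
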