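make_jsonl <- function(lines) {
  path <- withr::local_tempfile(fileext = ".jsonl", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("well-formed JSON-lines evidence parses row for row", {
  path <- make_jsonl(c(
    '{"record_id":"a","target_id":"T1","disease_id":"D1","datasource_id":"gwas","datatype_id":"genetic_association","score":0.7,"primary_year":2011}',
    '{"record_id":"b","target_id":"T1","disease_id":"D1","datasource_id":"chembl","datatype_id":"known_drug","score":0.1,"primary_year":2011,"clinical_phase":"I"}',
    '{"record_id":"c","target_id":"T1","disease_id":"D1","datasource_id":"europepmc","datatype_id":"literature","score":0.07,"primary_year":2012}'))
  ev <- read_evidence(path)
  expect_equal(nrow(ev), 3)
  expect_identical(ev$record_id, c("a", "b", "c"))
  expect_identical(ev$clinical_phase, c(NA, "I", NA))
  expect_equal(ev$score, c(0.7, 0.1, 0.07))
})

test_that("invalid rows are skipped with a warning, or abort in strict mode", {
  path <- make_jsonl(c(
    '{"record_id":"a","target_id":"T1","disease_id":"D1","datasource_id":"gwas","datatype_id":"genetic_association","score":0.7,"primary_year":2011}',
    '{"record_id":"bad","target_id":"T1","disease_id":"D1","datasource_id":"gwas","datatype_id":"genetic_association","score":1.3,"primary_year":2011}',
    '{"record_id":"c","target_id":"T1","disease_id":"D1","datasource_id":"europepmc","datatype_id":"literature","score":0.07,"primary_year":2012}'))
  expect_warning(ev <- read_evidence(path), "record_id=bad")
  expect_equal(nrow(ev), 2)
  expect_false("bad" %in% ev$record_id)
  expect_error(read_evidence(path, strict = TRUE), "record_id=bad")
})

test_that("schema and domain violations are reported precisely", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\ttarget_id\tscore", "a\tT1\t0.5"), path)
  expect_error(read_evidence(path), "disease_id")
  path2 <- make_jsonl(
    '{"record_id":"y","target_id":"T1","disease_id":"D1","datasource_id":"x","datatype_id":"literature","score":0.5,"primary_year":1850}')
  expect_warning(ev <- read_evidence(path2), "\\[1900, 2100\\]")
  expect_equal(nrow(ev), 0)
  expect_error(read_evidence(withr::local_tempfile()), "not found")
})

test_that("the TSLP fixture file yields the seven printed evidence scores", {
  path <- system.file("extdata", "tslp_asthma_evidence.tsv",
                      package = "tdnovelty")
  ev <- read_evidence(path)
  expect_equal(nrow(ev), 7)
  expect_equal(sort(ev$score, decreasing = TRUE),
               c(0.70, 0.70, 0.20, 0.10, 0.07, 0.06, 0.02))
  expect_identical(ev, tslp_fixture()$evidence, ignore_attr = TRUE)
  jl <- read_evidence(system.file("extdata", "tslp_asthma_evidence.jsonl",
                                  package = "tdnovelty"))
  expect_identical(jl, ev, ignore_attr = TRUE)
})

test_that("write/read round-trips reproduce records field for field", {
  ev <- tslp_fixture()$evidence
  ev$curation_year[1] <- 2013L  # exercise the optional-field path
  for (ext in c(".tsv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_evidence(ev, path)
    back <- read_evidence(path)
    expect_identical(back, ev, ignore_attr = TRUE)
  }
  empty <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(tslp_fixture()$evidence[0, ], empty)
  expect_equal(nrow(read_evidence(empty)), 0)
})

test_that("timestamp precedence picks curation, primary, or trial-start year", {
  ev <- data.frame(
    record_id = c("cur", "lit", "none", "drug", "path"),
    target_id = "T1", disease_id = "D1",
    datasource_id = c("eva", "europepmc", "europepmc", "chembl", "reactome"),
    datatype_id = c("genetic_association", "literature", "literature",
                    "known_drug", "affected_pathway"),
    score = 0.5,
    primary_year = c(2010L, 2012L, NA, 2016L, 2018L),
    curation_year = c(2018L, NA, NA, NA, NA),
    clinical_phase = c(NA, NA, NA, "II", NA), stringsAsFactors = FALSE)
  res <- suppressMessages(resolve_timestamps(ev))
  expect_identical(res$year, c(2018L, 2012L, NA, 2016L, 2018L))
  expect_identical(res$timestamp_kind,
                   c("curation", "primary", NA, "trial_start",
                     "project_release"))
  expect_identical(res$resolved, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(attr(res, "n_unresolved"), 1L)
  # deterministic and idempotent on the resolvable fields
  res2 <- suppressMessages(resolve_timestamps(ev))
  expect_identical(res[names(ev)], res2[names(ev)])
  expect_identical(res$year, res2$year)
  # a source not flagged curated falls back to the primary year
  res3 <- suppressMessages(resolve_timestamps(ev, curated_sources = character()))
  expect_identical(res3$year[1], 2010L)
  expect_identical(res3$timestamp_kind[1], "primary")
})

test_that("resolution rate and curation lag summarize the corpus", {
  full <- suppressMessages(resolve_timestamps(tslp_fixture()$evidence))
  expect_identical(resolution_rate(full), 1)
  ev <- tslp_fixture()$evidence
  ev$curation_year <- c(2022L, NA, 2023L, NA, NA, NA, NA)  # lags 11 and 11
  expect_identical(curation_lag(ev), 11)
  expect_true(is.na(curation_lag(tslp_fixture()$evidence)))
})

test_that("approval tables collapse duplicates and tolerate absent phases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "target_id\tdisease_id\tdrug_id\tfirst_approval_year\tphase_1_2_year\tphase_3_year",
    "T1\tD1\tdrugA\t2003\t.\t2001",
    "T1\tD1\tdrugA\t2001\t1999\t.",
    "T2\tD2\tdrugB\t2010\t.\t2008"), path)
  ap <- read_approvals(path)
  expect_equal(nrow(ap), 2)
  a1 <- ap[ap$drug_id == "drugA", ]
  expect_identical(a1$first_approval_year, 2001L)
  expect_identical(a1$phase_1_2_year, 1999L)
  expect_identical(a1$phase_3_year, 2001L)
  expect_true(is.na(ap$phase_1_2_year[ap$drug_id == "drugB"]))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("target_id\tdisease_id\tdrug_id\tfirst_approval_year", empty)
  expect_equal(nrow(read_approvals(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_id\tdisease_id\tdrug_id\tfirst_approval_year",
               "T1\tD1\tdrugA\t."), bad)
  expect_error(read_approvals(bad), "first_approval_year")
})

test_that("first approval per target is the earliest across its drugs", {
  ap <- data.frame(target_id = c("T1", "T1", "T2"),
                   disease_id = c("D1", "D2", "D3"),
                   drug_id = c("a", "b", "c"),
                   first_approval_year = c(2008L, 2003L, 2015L),
                   phase_1_2_year = NA_integer_, phase_3_year = NA_integer_,
                   stringsAsFactors = FALSE)
  fa <- first_approvals(ap)
  expect_equal(nrow(fa), 2)
  expect_identical(fa$disease_id[fa$target_id == "T1"], "D2")
  expect_identical(fa$first_approval_year[fa$target_id == "T1"], 2003L)
})
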