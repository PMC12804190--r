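peak_row <- function(target, disease, category, year, value) {
  data.frame(target_id = target, disease_id = disease,
             scope = paste0("datasource:x"), datasource_id = "x",
             datatype_id = category, year = as.integer(year), value = value,
             above_cutoff = value >= 0.1, grid_start = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the top peak per category is the maximum, earliest on ties", {
  pk <- rbind(peak_row("T1", "D1", "genetic_association", 2011, 0.52),
              peak_row("T1", "D1", "genetic_association", 2017, 0.17))
  top <- top_peak_per_category(pk)
  expect_equal(nrow(top), 1)
  expect_identical(top$top_peak_year, 2011L)
  expect_equal(top$top_peak_value, 0.52)

  single <- top_peak_per_category(peak_row("T1", "D1", "literature", 2014, 0.2))
  expect_identical(single$top_peak_year, 2014L)

  tie <- rbind(peak_row("T1", "D1", "literature", 2014, 0.3),
               peak_row("T1", "D1", "literature", 2010, 0.3))
  expect_identical(top_peak_per_category(tie)$top_peak_year, 2010L)

  # category restriction and absent categories
  both <- rbind(pk, peak_row("T1", "D1", "literature", 2012, 0.05))
  expect_equal(nrow(top_peak_per_category(both)), 2)
  expect_equal(nrow(top_peak_per_category(both, category = "animal_model")), 0)
  expect_equal(nrow(top_peak_per_category(both, cutoff = 0.1)), 1)
})

test_that("approval deltas follow the peak-precedes-approval sign convention", {
  appr <- data.frame(target_id = c("T1", "T2", "T3"),
                     disease_id = c("D1", "D2", "D3"), drug_id = letters[1:3],
                     first_approval_year = c(2015L, 2011L, 2005L),
                     phase_1_2_year = NA_integer_, phase_3_year = NA_integer_,
                     stringsAsFactors = FALSE)
  tops <- data.frame(target_id = c("T1", "T2", "T3", "T4"),
                     disease_id = c("D1", "D2", "D3", "D4"),
                     category = "literature",
                     top_peak_year = c(2011L, 2011L, 2012L, 2000L),
                     top_peak_value = 0.4, stringsAsFactors = FALSE)
  expect_message(d <- approval_deltas(tops, appr), "T4")
  expect_equal(nrow(d), 3)
  expect_identical(d$delta_years[d$target_id == "T1"], 4L)   # peak before approval
  expect_identical(d$delta_years[d$target_id == "T2"], 0L)
  expect_identical(d$delta_years[d$target_id == "T3"], -7L)  # peak after approval
  # antisymmetry under swapping the two years
  swapped <- tops[1, ]
  swapped$top_peak_year <- 2015L
  appr_sw <- appr[1, ]
  appr_sw$first_approval_year <- 2011L
  d_sw <- approval_deltas(swapped, appr_sw, quiet = TRUE)
  expect_identical(d_sw$delta_years, -d$delta_years[d$target_id == "T1"])
})

test_that("clinical-phase deltas are emitted per available phase year", {
  appr <- data.frame(target_id = c("T1", "T2"), disease_id = c("D1", "D2"),
                     drug_id = c("a", "b"),
                     first_approval_year = c(2021L, 2010L),
                     phase_1_2_year = c(2011L, NA),
                     phase_3_year = c(2019L, 2008L), stringsAsFactors = FALSE)
  d <- clinical_phase_deltas(appr)
  expect_equal(nrow(d), 3)
  t1 <- d[d$target_id == "T1", ]
  expect_identical(t1$delta_years[t1$category == "clinical_I_II"], 10L)
  expect_identical(t1$delta_years[t1$category == "clinical_III"], 2L)
  expect_identical(sort(d$category[d$target_id == "T2"]), "clinical_III")
  none <- clinical_phase_deltas(appr[0, ])
  expect_equal(nrow(none), 0)
})

test_that("TSLP pipeline end-to-end: genetic peak 2011 vs a 2021 approval", {
  prof <- quiet_profile(tslp_fixture()$evidence)
  tops <- top_peak_per_category(novelty_peaks(prof), cutoff = 0.1)
  appr <- read_approvals(system.file("extdata", "tslp_approvals_synthetic.tsv",
                                     package = "tdnovelty"))
  d <- approval_deltas(tops, appr, quiet = TRUE)
  gen <- d[d$category == "genetic_association", ]
  expect_identical(gen$top_peak_year, 2011L)
  expect_identical(gen$delta_years, 10L)  # 2021 - 2011
  cd <- clinical_phase_deltas(appr)
  expect_identical(cd$delta_years[cd$category == "clinical_I_II"], 10L)
  expect_identical(cd$delta_years[cd$category == "clinical_III"], 2L)
})

test_that("yearly novelty counts assign associations and targets once", {
  pk <- peak_row("T1", "D1", "literature", 2016, 0.4)
  one <- yearly_novelty_counts(pk)
  expect_identical(one, data.frame(year = 2016L, category = "literature",
                                   n_associations = 1L, n_targets = 1L))
  # shared target: counted once, at its earliest top-peak year
  two <- rbind(peak_row("T1", "D1", "literature", 2016, 0.4),
               peak_row("T1", "D2", "literature", 2018, 0.5))
  ct <- yearly_novelty_counts(two)
  expect_identical(ct$n_associations, c(1L, 1L))
  expect_identical(ct$n_targets, c(1L, 0L))
  # everything below cutoff vanishes
  expect_equal(nrow(yearly_novelty_counts(peak_row("T1", "D1", "literature",
                                                   2016, 0.05))), 0)
})

test_that("yearly counts honor the therapeutic-area exclusion list", {
  pk <- rbind(peak_row("T1", "D1", "literature", 2016, 0.4),
              peak_row("T2", "D2", "literature", 2016, 0.4))
  amap <- data.frame(disease_id = c("D1", "D2"),
                     therapeutic_area = c("measurement", "respiratory"),
                     stringsAsFactors = FALSE)
  ct <- yearly_novelty_counts(pk, area_map = amap)
  expect_identical(ct$n_associations, 1L)
  expect_identical(unique(yearly_novelty_counts(pk)$n_associations), 2L)
})

test_that("count invariants hold on a random peak corpus", {
  set.seed(99)
  n <- 120
  pk <- peak_row(sprintf("T%02d", sample.int(25, n, replace = TRUE)),
                 sprintf("D%02d", sample.int(12, n, replace = TRUE)),
                 sample(c("literature", "genetic_association"), n, TRUE),
                 sample(2000:2020, n, TRUE), runif(n))
  pk <- pk[!duplicated(pk[c("target_id", "disease_id", "datatype_id",
                            "year")]), ]
  ct <- yearly_novelty_counts(pk, cutoff = 0.1)
  kept <- pk[pk$value >= 0.1, ]
  for (cat_lab in unique(ct$category)) {
    n_pairs <- nrow(unique(kept[kept$datatype_id == cat_lab,
                                c("target_id", "disease_id")]))
    expect_identical(sum(ct$n_associations[ct$category == cat_lab]), n_pairs)
    n_targets <- length(unique(kept$target_id[kept$datatype_id == cat_lab]))
    expect_identical(sum(ct$n_targets[ct$category == cat_lab]), n_targets)
  }
  expect_true(all(ct$n_targets <= ct$n_associations))
})
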