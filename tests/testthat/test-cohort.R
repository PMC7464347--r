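test_that("cut-off sweep conserves counts and behaves monotonically", {
  cohort <- simulate_cohort(sim_config(n_patients = 80, seed = 12))
  sw <- sweep_cutoffs(cohort$measurements)
  expect_true(all(sw$positive + sw$negative + sw$nonassessable == sw$n))
  expect_true(all(sw$n == 80))
  by_assay <- split(sw[order(-sw$cutoff), ], sw$assay[order(-sw$cutoff)])
  for (tab in by_assay) {
    expect_true(all(diff(tab$positive) >= 0))  # cut-off decreasing down rows
    expect_true(all(diff(tab$negative) <= 0))
  }
  expect_error(sweep_cutoffs(cohort$measurements[0, ]), "empty")
  expect_error(sweep_cutoffs(cohort$measurements, numeric()), "cutoffs")
})

test_that("single-sample status trajectory over the sweep is consistent", {
  # MFC, 1e6 events, no aberrant cells: LOD 3e-5
  m <- meas("P1", "MFC", 1e6, 0)
  sw <- sweep_cutoffs(m, cutoffs = c(1e-4, 1e-5, 1e-6))
  expect_identical(sw$negative, c(1L, 0L, 0L))
  expect_identical(sw$nonassessable, c(0L, 1L, 1L))
})

test_that("the concordance partition reproduces the published fixture", {
  res <- mrd_concordance(concordance_fixture(), cutoff = 1e-5)
  expect_identical(res$n_total, 125L)
  expect_identical(unname(res$counts),
                   c(42L, 43L, 14L, 14L, 12L))
  expect_equal(unname(res$proportions[["concordant_pos"]] +
                        res$proportions[["concordant_neg"]]), 0.680)
  expect_equal(unname(res$proportions[["discordant_ngs_pos"]] +
                        res$proportions[["discordant_mfc_pos"]]), 0.224)
  expect_equal(unname(res$proportions[["lod_discordant"]]), 0.096)
  expect_identical(res$kappa_n, 113L)
  # definition-level kappa of the printed 2x2 table (42,14,14,43):
  # po = 85/113, pe = (56^2 + 57^2)/113^2 -> kappa = 3220/6384
  expect_equal(res$kappa, 3220 / 6384)
  expect_equal(sum(res$proportions), 1)
})

test_that("patients lacking an assay are excluded with a warning", {
  cohort <- dplyr::bind_rows(concordance_fixture(),
                             meas("solo", "NGS", 1.1e6, 0))
  expect_warning(res <- mrd_concordance(cohort), "lack one")
  expect_identical(res$n_total, 125L)
  expect_identical(res$n_excluded, 1L)
})

test_that("cohen_kappa matches its definition and an independent library", {
  expect_identical(cohen_kappa(c(10, 0, 0, 10)), 1)
  expect_identical(cohen_kappa(c(5, 5, 5, 5)), 0)
  expect_error(cohen_kappa(c(0, 0, 0, 0)), "zero")
  expect_error(cohen_kappa(c(1, 2, 3)), "2x2")
  set.seed(88)
  for (i in 1:100) {
    tab <- matrix(rbinom(4, 60, runif(1, 0.1, 0.9)), 2)
    if (sum(tab) == 0) next
    expect_equal(cohen_kappa(tab), kappa_bruteforce(tab))
    if (requireNamespace("e1071", quietly = TRUE)) {
      expect_equal(cohen_kappa(tab),
                   e1071::classAgreement(tab)$kappa)
    }
  }
})

test_that("response stratification reproduces the published rates", {
  res <- stratify_by_response(stratified_fixture(), cutoff = 1e-5)
  ngs <- dplyr::filter(res$by_response, assay == "NGS")
  expect_identical(ngs$negative[match(c("CR", "nCR", "VGPR"), ngs$response)],
                   c(37L, 19L, 4L))
  agg <- res$vgpr_or_better
  expect_identical(agg$n, c(109L, 109L))
  expect_equal(agg$negative[agg$assay == "NGS"], 60L)
  expect_equal(agg$negative[agg$assay == "MFC"], 54L)
  expect_equal(agg$prop_negative[agg$assay == "NGS"], 60 / 109)
  expect_equal(agg$prop_negative[agg$assay == "MFC"], 54 / 109)
})

test_that("empty strata report NA proportions, not zero", {
  m <- pair_rows("P1", 1.1e6, 110, 5e6, 500, response = "CR")
  res <- stratify_by_response(m)$by_response
  mr <- dplyr::filter(res, response == "MR")
  expect_identical(mr$n, c(0L, 0L))
  expect_true(all(is.na(mr$prop_negative)))
})

test_that("identical tumor loads give r = 1 and a null paired t-test", {
  set.seed(5)
  counts <- round(10^runif(12, 1.5, 3.5))
  m <- dplyr::bind_rows(lapply(seq_along(counts), function(i)
    pair_rows(sprintf("P%02d", i), 1e7, counts[i], 1e7, counts[i])))
  res <- compare_tl(m, cutoff = 1e-6)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$pearson_r_outliers_removed, 1)
})

test_that("a planted cross-assay correlation of 0.8 is recovered", {
  # between-patient log10 sd 0.9 with per-assay noise sd 0.45 gives a true
  # log-scale correlation 0.9^2 / (0.9^2 + 0.45^2) = 0.8; huge cell counts
  # make counting noise negligible
  cfg <- sim_config(
    n_patients = 44, seed = 240,
    p_mrd_negative_by_response = setNames(rep(0, 7), mrd_responses()),
    tl_log10_mean_by_response = setNames(rep(-3, 7), mrd_responses()),
    tl_log10_sd = 0.9,
    ngs_cells_range = c(1e8, 1e8), mfc_events_range = c(1e8, 1e8),
    cross_assay_log10_sd = 0.45)
  res <- compare_tl(simulate_cohort(cfg)$measurements, cutoff = 1e-5,
                    n_outliers = 0)
  se_z <- 1 / sqrt(res$n_pairs - 3)
  expect_lt(abs(atanh(res$pearson_r) - atanh(0.8)), 3 * se_z)
})

test_that("removing planted off-line outliers raises the correlation", {
  set.seed(23)
  log_tl <- seq(-4.5, -2.5, length.out = 42)
  mfc_tl <- 10^log_tl
  mfc_tl[c(5, 38)] <- 10^c(-2.0, -4.8)  # two extreme off-line pairs
  cells <- 1e8
  m <- dplyr::bind_rows(lapply(1:42, function(i)
    pair_rows(sprintf("P%02d", i), cells, round(10^log_tl[i] * cells),
              cells, round(mfc_tl[i] * cells))))
  res <- compare_tl(m, cutoff = 1e-5, n_outliers = 2)
  expect_identical(res$n_outliers_removed, 2)
  expect_setequal(res$outlier_patients, c("P05", "P38"))
  expect_gt(res$pearson_r_outliers_removed, res$pearson_r)
  expect_gt(res$pearson_r_outliers_removed, 0.99)
})

test_that("too few concordant positives is an error", {
  m <- pair_rows(c("P1", "P2"), 1.1e6, 110, 5e6, 500)
  expect_error(compare_tl(m), "at least 3")
})
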