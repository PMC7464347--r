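test_that("the decision rules classify the canonical cases", {
  # cohort-median metrics at cut-off 1e-5: clearly positive and quantifiable
  s <- assign_status(tl = 4.1e-5, lod = 1.7e-6, loq = 2.2e-6, cutoff = 1e-5)
  expect_identical(s$status, "positive")
  expect_identical(s$rule_fired, "B1a")
  # no clone detected, LOD comfortably under the cut-off: negative
  s <- assign_status(tl = 0, lod = 6.0e-6, loq = 1.0e-5, cutoff = 1e-5)
  expect_identical(s$status, "negative")
  expect_identical(s$rule_fired, "B2a")
  # LOD exceeds the cut-off: no negative call is valid
  s <- assign_status(tl = 0, lod = 3.0e-5, loq = 5.0e-5, cutoff = 1e-5)
  expect_identical(s$status, "nonassessable")
  expect_identical(s$rule_fired, "B2c")
  # TL above cut-off but below LOD (only possible when LOD > cut-off)
  s <- assign_status(tl = 2e-5, lod = 3e-5, loq = 5e-5, cutoff = 1e-5)
  expect_identical(s$status, "nonassessable")
  expect_identical(s$rule_fired, "B1c")
})

test_that("tumor-load quantifiability follows the positive call", {
  expect_identical(assess_tl_quantifiability("positive", 1.5e-4, 2.2e-6),
                   "quantifiable")
  expect_identical(assess_tl_quantifiability("positive", 1.1e-5, 2.0e-5),
                   "nonquantifiable")
  expect_identical(assess_tl_quantifiability("negative", 0, 2.0e-5),
                   "not_applicable")
  expect_identical(assess_tl_quantifiability("nonassessable", 0, 2.0e-5),
                   "not_applicable")
})

test_that("mrd_call composes metrics, status and quantifiability", {
  call <- mrd_call(meas("P1", "NGS", 1.1e6, 45), cutoff = 1e-5)
  expect_identical(call$status, "positive")
  expect_identical(call$tl_quantifiable, "quantifiable")
  # MFC with 1e6 events and no aberrant cells: LOD 3e-5
  m <- meas("P2", "MFC", 1e6, 0)
  expect_identical(mrd_call(m, cutoff = 1e-4)$status, "negative")
  expect_identical(mrd_call(m, cutoff = 1e-6)$status, "nonassessable")
  expect_identical(mrd_call(m, cutoff = 1e-6)$tl_quantifiable,
                   "not_applicable")
})

test_that("boundary ties resolve inclusively on the favorable side", {
  # TL exactly at the cut-off is positive
  s <- assign_status(tl = 1e-5, lod = 1e-6, loq = 2e-6, cutoff = 1e-5)
  expect_identical(s$status, "positive")
  # LOD arising as a float quotient that equals the cut-off is assessable
  s <- assign_status(tl = 0, lod = 30 / 3e6, loq = 50 / 3e6, cutoff = 1e-5)
  expect_identical(s$status, "negative")
  # TL exactly at the LOQ counts as quantifiable
  s <- assign_status(tl = 2e-5, lod = 1e-6, loq = 2e-5, cutoff = 1e-5)
  expect_identical(s$rule_fired, "B1a")
})

test_that("exactly one rule fires and it matches the brute-force table", {
  grid <- random_metric_grid(2000, seed = 99)
  got <- assign_status(grid$tl, grid$lod, grid$loq, 1e-5)
  # vectorized call with per-row cutoffs via loop over the preset values
  for (co in unique(grid$cutoff)) {
    idx <- which(grid$cutoff == co)
    res <- assign_status(grid$tl[idx], grid$lod[idx], grid$loq[idx], co)
    want_rule <- vapply(idx, function(i)
      oracle_rule(grid$tl[i], grid$lod[i], grid$loq[i], co), character(1))
    expect_identical(res$rule_fired, want_rule)
    expect_identical(res$status, vapply(want_rule, oracle_status,
                                        character(1), USE.NAMES = FALSE))
  }
  # structural invariants of the rule/status mapping
  expect_true(all((got$status == "positive") ==
                    (got$rule_fired %in% c("B1a", "B1b"))))
  expect_true(all((got$status == "negative") ==
                    (got$rule_fired %in% c("B2a", "B2b"))))
  expect_true(all((got$status == "nonassessable") ==
                    (got$rule_fired %in% c("B1c", "B2c"))))
})

test_that("a sample whose LOD undercuts the cut-off is always assessable", {
  grid <- random_metric_grid(500, seed = 3)
  ok <- grid$lod <= grid$cutoff
  res <- mapply(function(tl, lod, loq, co)
    assign_status(tl, lod, loq, co)$status,
    grid$tl[ok], grid$lod[ok], grid$loq[ok], grid$cutoff[ok])
  expect_true(all(res != "nonassessable"))
})

test_that("lowering the cut-off never flips a positive call", {
  grid <- random_metric_grid(300, seed = 17)
  cutoffs <- sort(c(1e-4, 2e-5, 1e-5, 1e-6), decreasing = TRUE)
  status <- sapply(cutoffs, function(co)
    assign_status(grid$tl, grid$lod, grid$loq, co)$status)
  for (j in seq_len(ncol(status) - 1)) {
    was_pos <- status[, j] == "positive"
    expect_true(all(status[was_pos, j + 1] == "positive"))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(assign_status(0, 1e-6, 2e-6, cutoff = 0), "cutoff")
  expect_error(assign_status(0, 1e-6, 2e-6, cutoff = c(1e-5, 1e-4)),
               "cutoff")
  expect_error(assign_status(0, 2e-6, 1e-6, cutoff = 1e-5), "LOD")
})
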