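# Categorization rules, depth QC, fixed-cutoff classifiers and ROC analysis.

test_that("primary categorization follows temperature and contact time", {
  expect_equal(primary_categorize(63, 18), "PT-Superficial")
  expect_equal(primary_categorize(63, 35), "PT-Deep")
  expect_equal(primary_categorize(96, 30), "Full-thickness")
  expect_equal(primary_categorize(45), "Superficial")
  expect_error(primary_categorize(63, 25), "outside the protocol")
  expect_error(primary_categorize(70, 20), "not part of the protocol")
  expect_error(primary_categorize(63, NA), "contact duration")
})

test_that("secondary criterion retains/excludes by time to heal", {
  rec <- tibble::tibble(
    primary_category = c("PT-Superficial", "PT-Deep", "PT-Superficial",
                         "Superficial", "Full-thickness"),
    heal_pod = c(43, 50, NA, 2, NA))
  out <- secondary_categorize(rec)
  expect_equal(out$final_category,
               c("PT-Superficial", "Excluded", "Excluded",
                 "Superficial", "Full-thickness"))
  expect_equal(out$exclusion_reason[2], "secondary-criterion")
})

test_that("depth adjustment and QC implement the printed cutoffs", {
  expect_equal(adjust_depth_score(500, TRUE), 600)
  expect_equal(adjust_depth_score(500, FALSE), 500)
  expect_error(adjust_depth_score(-5, TRUE), ">= 0")

  expect_true(depth_score_qc("PT-Deep", 870))
  expect_true(depth_score_qc("Superficial", 102.5))
  expect_false(depth_score_qc("PT-Superficial", 900))
  expect_true(depth_score_qc("Full-thickness", 2261))
  expect_false(depth_score_qc("Full-thickness", 1750))
  # the boundary itself goes to PT-Superficial by default, overridable
  expect_true(depth_score_qc("PT-Superficial", 680))
  expect_false(depth_score_qc("PT-Deep", 680))
  expect_true(depth_score_qc("PT-Deep", 680, boundary_to = "PT-Deep"))
  expect_error(depth_score_qc("unknown", 100), "unknown")
})

test_that("classify_hi uses strict inequalities at the printed cutoffs", {
  expect_true(classify_hi(5.0, 3.54, "greater"))
  expect_false(classify_hi(3.54, 3.54, "greater"))
  expect_true(classify_hi(5.0, 6.58, "less"))
  expect_false(classify_hi(6.58, 6.58, "less"))
})

test_that("roc_curve reproduces canonical AUC cases", {
  perfect <- roc_curve(c(5, 6, 7), c(1, 2, 3), "greater")
  expect_equal(perfect$auc, 1)
  same <- roc_curve(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(same$auc, 0.5)
  expect_equal(roc_curve(c(2, 4), c(1, 3), "greater")$auc, 0.75)
  expect_error(roc_curve(numeric(0), 1), "at least one")
})

test_that("rank-based AUC matches the pair-counting oracle", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    pos <- round(rnorm(n1, 1), 1)  # rounding forces ties
    neg <- round(rnorm(n2), 1)
    dir <- sample(c("greater", "less"), 1)
    expect_equal(roc_curve(pos, neg, dir)$auc, auc_pairs(pos, neg, dir))
  }
})

test_that("AUC antisymmetry under group swap", {
  set.seed(8)
  pos <- rnorm(6, 1); neg <- rnorm(5)
  expect_equal(roc_curve(pos, neg, "greater")$auc,
               1 - roc_curve(neg, pos, "greater")$auc)
})

test_that("youden_cutoff picks the separating midpoint and handles ties", {
  sep <- roc_curve(c(5, 6, 7), c(1, 2, 3), "greater")
  expect_equal(youden_cutoff(sep)$threshold, 4)  # midpoint of the gap

  yj <- youden_cutoff(roc_curve(c(2, 4), c(1, 3), "greater"))
  expect_equal(yj$threshold, 3.5)

  flat <- youden_cutoff(roc_curve(c(1, 2), c(1, 2), "greater"))
  expect_true(flat$degenerate)
})

test_that("classify_hi at the Youden threshold reproduces that ROC point", {
  set.seed(9)
  pos <- rnorm(8, 2); neg <- rnorm(10)
  r <- roc_curve(pos, neg, "greater")
  yj <- youden_cutoff(r)
  called_pos <- classify_hi(pos, yj$threshold, "greater")
  called_neg <- classify_hi(neg, yj$threshold, "greater")
  expect_equal(mean(called_pos), yj$sensitivity)
  expect_equal(mean(!called_neg), yj$specificity)
})

test_that("categorization rules reproduce the study's attrition on the fixture", {
  wt <- wound_table_fixture()
  wt$primary_category <- primary_categorize(wt$block_temp_c, wt$contact_s)
  out <- secondary_categorize(wt)
  expect_equal(sum(!out$included), 3)
  counts <- table(out$final_category[out$included])
  expect_equal(as.vector(counts[c("Superficial", "PT-Superficial", "PT-Deep",
                                  "Full-thickness")]), c(4L, 6L, 5L, 6L))
})
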