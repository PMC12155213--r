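# Hemoglobin and Fluorescence Index arithmetic, per-wound averaging,
# imputation, and the table-level index pipeline.

meas <- function(a = 0, b = 0, c = 0, pig = 1, pod = 3) {
  tibble::tibble(a = a, b = b, c = c, pig = pig, pod = pod)
}

test_that("hemoglobin_index implements the healthy-normalized ratio", {
  healthy <- meas(a = c(1, 2, 0.5, 0.5), b = c(1, 0, 1.5, 1.5))
  # wound at the healthy mean (a+b = 2) has HI = 1
  expect_equal(hemoglobin_index(meas(a = 1, b = 1), healthy), 1)
  # straight equation arithmetic
  h1 <- meas(a = c(1, 1, 1, 1), b = 0)
  expect_equal(hemoglobin_index(meas(a = 3, b = 2), h1), 5)
  expect_error(hemoglobin_index(meas(a = 1, b = 1), healthy[1:3, ]), "exactly 4")
  expect_error(hemoglobin_index(meas(a = 1, b = 1, pig = 2), healthy), "pig")
  expect_error(hemoglobin_index(meas(a = 1, b = 1), meas(a = rep(0, 4), b = 0)),
               "> 0")
})

test_that("fluorescence_index is the c-ratio with the same contract", {
  healthy <- meas(c = c(2, 2, 2, 2))
  expect_equal(fluorescence_index(meas(c = 2), healthy), 1)
  expect_equal(fluorescence_index(meas(c = 14.5), healthy), 7.25)
  expect_error(fluorescence_index(meas(c = 1), meas(c = rep(0, 4))), "> 0")
})

test_that("indices are invariant to permuting the healthy batch", {
  healthy <- meas(a = c(0.6, 1.1, 2.0, 0.3), b = c(0.4, 0.9, 0.2, 1.5),
                  c = c(3, 5, 2, 8))
  w <- meas(a = 2, b = 1, c = 4)
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    expect_equal(hemoglobin_index(w, healthy[perm, ]), hemoglobin_index(w, healthy))
    expect_equal(fluorescence_index(w, healthy[perm, ]), fluorescence_index(w, healthy))
  }
})

test_that("per_wound_index averages survivors and flags attrition", {
  expect_equal(per_wound_index(c(8, 10))$value, 9)
  one <- per_wound_index(7)
  expect_equal(one$value, 7)
  expect_true(one$single_site)
  none <- per_wound_index(numeric(0))
  expect_true(none$missing)
  expect_true(is.na(none$value))
  expect_error(per_wound_index(1:3), "at most 2")
})

test_that("impute_pod7 fills the gap from its neighbors and flags it", {
  s <- tibble::tibble(category = "PT-Superficial",
                      pod = c(3, 14), value = c(9.19, 5.39))
  out <- impute_pod7(s)
  expect_equal(out$value[out$pod == 7], (9.19 + 5.39) / 2)  # = 7.29
  expect_true(out$imputed[out$pod == 7])

  s2 <- tibble::tibble(category = "x", pod = c(3, 7, 14), value = c(4, NA, 4))
  expect_equal(impute_pod7(s2)$value[2], 4)
  expect_error(impute_pod7(tibble::tibble(category = "x", pod = 3, value = 1)),
               "POD 14")
})

test_that("index_table composes per-site indices, ROUT and per-wound averaging", {
  coefs <- dplyr::bind_rows(
    tidyr::expand_grid(pig = 1, pod = 3, wound = 1:3,
                       site = c("central-1", "central-2")),
    tidyr::expand_grid(pig = 1, pod = 3, wound = NA_integer_,
                       site = paste0("healthy-", 1:4)))
  coefs$category <- ifelse(is.na(coefs$wound), "healthy", "burn")
  coefs$a <- 1; coefs$b <- 1; coefs$c <- 5
  # healthy mean a+b = 2; wound 1 sites at 4x and 4x, wound 2 at 2x/2x,
  # wound 3 has one wild site
  coefs$a[coefs$wound %in% 1] <- 4
  coefs$b[coefs$wound %in% 1] <- 4
  coefs$a[coefs$wound %in% 3 & coefs$site == "central-2"] <- 200
  out <- index_table(coefs, q = 0.02)
  w <- dplyr::arrange(out$wound, wound)
  expect_equal(w$hi[1], 4)
  expect_equal(w$hi[2], 1)
  # the wild site is removed; wound 3 keeps its single clean site
  expect_true(w$single_site[3])
  expect_equal(w$hi[3], 1)

  # q = 0 disables removal entirely
  out0 <- index_table(coefs, q = 0)
  expect_false(any(out0$site$removed))

  # healthy-count contract
  bad <- dplyr::filter(coefs, site != "healthy-4")
  expect_error(index_table(bad), "exactly 4")
})
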