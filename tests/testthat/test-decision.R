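test_that("uncorrected Pearson chi-square matches the cell-wise oracle", {
  set.seed(20)
  for (i in 1:25) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    if ((a + b) == 0 || (a + b) == (n1 + n2)) next
    got <- pearson_chi2_2x2(a, n1, b, n2)
    O <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(got$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
    # independent oracle
    expect_equal(got$statistic,
                 unname(suppressWarnings(chisq.test(O, correct = FALSE))$statistic),
                 tolerance = 1e-9)
    # invariance under group swap and success/failure relabeling
    expect_equal(got$statistic, pearson_chi2_2x2(b, n2, a, n1)$statistic)
    expect_equal(got$statistic,
                 pearson_chi2_2x2(n1 - a, n1, n2 - b, n2)$statistic)
  }
  expect_equal(pearson_chi2_2x2(10, 20, 10, 20)$statistic, 0)
  expect_error(pearson_chi2_2x2(30, 20, 1, 20), "flagged counts")
})

test_that("Fisher exact p equals hypergeometric enumeration and fisher.test", {
  even <- exact_test_2x2(5, 10, 5, 10)
  expect_equal(even$p_value, 1)

  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    got <- exact_test_2x2(a, n1, b, n2)
    O <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    expect_equal(got$p_value, fisher.test(O)$p.value, tolerance = 1e-9)
  }
  # full enumeration oracle for (0,5,5,5): support 0..5 of flagged in group 1
  p_obs <- dhyper(0, 5, 5, 5)
  enum <- sum(dhyper(0:5, 5, 5, 5)[dhyper(0:5, 5, 5, 5) <= p_obs * (1 + 1e-7)])
  expect_equal(exact_test_2x2(0, 5, 5, 5)$p_value, enum)
})

test_that("small expected cells route to the exact method", {
  # (15,22,20,22): failure margin 9 of 44 -> min expected 4.5 < 5
  expect_lt(cogconvert:::min_expected_cell(15, 22, 20, 22), 5)
  expect_equal(cogconvert:::compare_2x2(15, 22, 20, 22)$method, "exact")
  expect_equal(cogconvert:::compare_2x2(139, 224, 104, 224)$method, "pearson")
  expect_equal(cogconvert:::compare_2x2(15, 22, 20, 22,
                                        adjust = "yates")$method, "yates")
})

test_that("reassignment flags mirror CNI labels and rates tally", {
  labs <- data.frame(
    id = rep(1:4, 2), month = rep(c(3, 6), each = 4),
    label = factor(c("CI", "CNI", "CI", "CNI", "CNI", "CNI", "CI", "CI"),
                   levels = c("CNI", "CI"))
  )
  f3 <- flag_reassignment(labs, 3)
  expect_equal(f3$flagged, c(FALSE, TRUE, FALSE, TRUE))
  f6 <- flag_reassignment(labs, 6)
  expect_equal(f6$flagged, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(reassignment_rate(f3), 0.5)
  expect_error(flag_reassignment(labs, 12), "no labels")

  # cumulative reading: CNI at 3 keeps the flag at 6
  f6c <- flag_reassignment(labs, 6, cumulative = TRUE)
  expect_equal(f6c$flagged, c(TRUE, TRUE, FALSE, TRUE))

  # rate = 1 - CI prevalence by construction
  expect_equal(reassignment_rate(f6), 1 - mean(labs$label[labs$month == 6] == "CI"))
  big <- data.frame(flagged = rep(c(TRUE, FALSE), c(139, 85)))
  expect_equal(round(100 * reassignment_rate(big), 2), 62.05)
})

test_that("the reassignment report tabulates strata and degenerate cells", {
  tab <- generate_cohort(planted_spec(n = 60, seed = 30))
  actual <- label_conversion(tab)
  # predicted = actual -> X2 = 0 (or degenerate), rates equal everywhere
  rep1 <- reassignment_report(tab, actual, actual)
  expect_true(all(rep1$actual_pct == rep1$predicted_pct))
  expect_true(all(rep1$statistic == 0 | is.na(rep1$statistic)))
  overall <- rep1[rep1$stratifier == "overall", ]
  expect_equal(unique(overall$n), 60)

  # stratum n values partition the cohort within each stratifier
  for (s in c("arm", "age_band", "gender", "diagnosis")) {
    sub <- rep1[rep1$stratifier == s & rep1$month == 3, ]
    expect_equal(sum(sub$n), 60)
  }

  # hand-tabulated counts on a constructed two-arm cohort
  tab2 <- tab[tab$id %in% 1:10, ]
  act <- data.frame(id = rep(1:10, 2), month = rep(c(3, 6), each = 10),
                    label = factor(rep(c("CNI", "CI"), 10),
                                   levels = c("CNI", "CI")))
  prd <- act
  prd$label[prd$id <= 3] <- "CNI"
  rep2 <- reassignment_report(tab2, act, prd)
  row3 <- rep2[rep2$stratifier == "overall" & rep2$month == 3, ]
  expect_equal(row3$actual_flagged, sum(act$label[act$month == 3] == "CNI"))
  expect_equal(row3$predicted_flagged, sum(prd$label[prd$month == 3] == "CNI"))
})

test_that("mcnemar test counts discordant pairs", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  p <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  got <- mcnemar_flags(a, p)
  expect_equal(got$statistic, (abs(2 - 1) - 1)^2 / 3)
  expect_equal(got$method, "mcnemar")
  expect_equal(mcnemar_flags(a, a)$statistic, 0)
})
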