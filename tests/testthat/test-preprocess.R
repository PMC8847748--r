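test_that("patients with more than half their cells missing are excluded", {
  tab <- generate_cohort(planted_spec(n = 4, seed = 1))
  feats <- setdiff(names(tab), c("id", "month", "diagnosis"))
  # per patient: 16 static cells + 11 time-dependent cells x 3 visits = 49
  statics <- c("age", "education", "height", "weight", "his",
               "hypertension", "diabetes", "thyropathy", "cardiovascular",
               "asthma", "cerebrovascular", "hyperlithuria", "hyperlipidemia",
               "family_history", "gender", "arm")
  tdep <- setdiff(feats, statics)
  blank_cells <- function(tab, id, k) {
    # blank k of the patient's 49 cells: statics first, then visit cells
    n_static <- min(k, length(statics))
    for (f in statics[seq_len(n_static)]) tab[[f]][tab$id == id] <- NA
    left <- k - n_static
    if (left > 0) {
      rows <- which(tab$id == id)
      cells <- expand.grid(row = rows, f = tdep, stringsAsFactors = FALSE)
      cells <- cells[order(cells$f != "adas_cog"), ]  # spare baseline adas last
      cells <- cells[!(cells$f == "adas_cog" & tab$month[cells$row] == 0), ]
      for (i in seq_len(left)) tab[[cells$f[i]]][cells$row[i]] <- NA
    }
    tab
  }
  tab <- blank_cells(tab, 2, 24)  # 24/49 = 0.49
  tab <- blank_cells(tab, 3, 25)  # 25/49 = 0.51
  for (f in feats) tab[[f]][tab$id == 4] <- NA  # 49/49 = 1.0

  out <- filter_missing(tab, patient_threshold = 0.5, feature_threshold = 0)
  expect_setequal(out$report$excluded_patients$id, c(3, 4))
  expect_setequal(unique(out$table$id), c(1, 2))

  full <- generate_cohort(planted_spec(n = 6, seed = 2))
  res <- filter_missing(full)
  expect_identical(res$table, full)
  expect_equal(nrow(res$report$excluded_patients), 0)

  empty <- generate_cohort(cohort_spec(n_patients = 0))
  res0 <- filter_missing(empty)
  expect_equal(nrow(res0$table), 0)
})

test_that("features observed in under half the patients are dropped first", {
  tab <- generate_cohort(planted_spec(n = 10, seed = 3))
  tab$gds[tab$id %in% 1:6] <- NA  # observed in 4/10 patients' rows < 0.5
  out <- filter_missing(tab)
  expect_true("gds" %in% out$report$dropped_features)
  expect_false("gds" %in% names(out$table))
  expect_equal(nrow(out$report$excluded_patients), 0)
})

test_that("imputation fills means, modes, and breaks ties by sort order", {
  tab <- data.frame(
    id = 1:5, month = 0, diagnosis = "AD",
    cont = c(1, 2, NA, NA, NA),
    flag = c(0, 0, 1, NA, NA),
    cat = c("A", "A", "B", "B", NA)
  )
  out <- impute_missing(tab)
  expect_equal(out$table$cont, c(1, 2, 1.5, 1.5, 1.5))
  expect_equal(out$table$flag, c(0, 0, 1, 0, 0))     # mode of {0,0,1}
  expect_equal(out$table$cat[5], "A")                 # tie {A,A,B,B} -> sorted first
  expect_equal(out$report$imputation_values$cont, 1.5)

  # observed values untouched; idempotence
  again <- impute_missing(out$table)
  expect_identical(again$table, out$table)

  allna <- data.frame(id = 1:2, month = 0, x = c(NA_real_, NA_real_))
  expect_error(impute_missing(allna), "'x' has no observed values")
})

test_that("standardization hits zero mean unit variance on the fit set", {
  tab <- data.frame(id = 1:3, month = 0, x = c(1, 2, 3))
  out <- standardize_features(tab)
  expect_equal(out$table$x, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  const <- data.frame(id = 1:3, month = 0, x = c(2, 2, 2))
  outc <- standardize_features(const)
  expect_equal(outc$table$x, c(0, 0, 0))
  expect_true("x" %in% outc$report$constant_features)

  # fit on a subset: row 3 transformed with subset statistics
  sub <- standardize_features(tab, fit_ids = c(1, 2))
  expect_equal(sub$table$x[3], 3.0)

  expect_error(standardize_features(tab, fit_ids = c(1, 99)), "subset")
})

test_that("standardized fit-set features have mean 0 and sd 1 to 1e-9", {
  tab <- generate_cohort(planted_spec(n = 60, seed = 8))
  fit_ids <- 1:40
  out <- standardize_features(tab, fit_ids = fit_ids)
  fit_rows <- out$table$id %in% fit_ids
  for (f in c("age", "adas_cog", "mmse", "tmt_b")) {
    v <- out$table[[f]][fit_rows]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
})

test_that("the 4-point decline rule labels boundary cases exactly", {
  tab <- tiny_table(rbind(c(20, 16, 25),    # decline 4 at 3mo -> CI; rise -> CNI
                          c(20, 17, 15.9),  # decline 3 -> CNI; 4.1 -> CI
                          c(20, 16.1, 16)))  # 3.9 -> CNI; 4 exactly -> CI
  lab <- label_conversion(tab)
  get <- function(id, m) as.character(lab$label[lab$id == id & lab$month == m])
  expect_equal(get(1, 3), "CI")
  expect_equal(get(1, 6), "CNI")
  expect_equal(get(2, 3), "CNI")
  expect_equal(get(2, 6), "CI")
  expect_equal(get(3, 3), "CNI")
  expect_equal(get(3, 6), "CI")
})

test_that("labels omit missing follow-ups and never flip CI->CNI as scores fall", {
  tab <- tiny_table(rbind(c(20, NA, 18)))
  lab <- label_conversion(tab)
  expect_equal(nrow(lab), 1)
  expect_equal(attr(lab, "omitted")$month, 3)

  # monotonicity: lowering a follow-up ADAS-cog can only move CNI -> CI
  set.seed(42)
  for (i in 1:25) {
    base <- runif(1, 10, 40)
    f1 <- base + rnorm(1, 0, 6)
    f2 <- f1 - runif(1, 0, 5)
    l1 <- label_conversion(tiny_table(rbind(c(base, f1, f1))))
    l2 <- label_conversion(tiny_table(rbind(c(base, f2, f2))))
    better <- function(l) l$label[l$month == 3] == "CI"
    expect_false(better(l1) & !better(l2))
  }
})

test_that("filter -> impute -> standardize preserves accounted patient counts", {
  spec <- cohort_spec(n_patients = 40, miss_rate = 0.25, seed = 11)
  tab <- inject_missingness(generate_cohort(spec), spec)
  filt <- filter_missing(tab)
  imp <- impute_missing(filt$table)
  std <- standardize_features(imp$table)
  expect_equal(length(unique(std$table$id)) +
                 nrow(filt$report$excluded_patients),
               40)
  expect_false(anyNA(imp$table[setdiff(names(imp$table),
                                       c("id", "month", "diagnosis"))]))
})
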