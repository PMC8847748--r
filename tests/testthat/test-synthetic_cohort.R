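test_that("empty cohort keeps the schema header", {
  tab <- generate_cohort(cohort_spec(n_patients = 0, seed = 1))
  expect_equal(nrow(tab), 0)
  expect_true(all(c("id", "month", "diagnosis", "adas_cog", "mmse", "arm")
                  %in% names(tab)))
})

test_that("identical spec and seed give a bit-identical table", {
  a <- generate_cohort(cohort_spec(n_patients = 80, seed = 5))
  b <- generate_cohort(cohort_spec(n_patients = 80, seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n_patients = 80, seed = 6))
  expect_false(identical(a$adas_cog, c$adas_cog))
})

test_that("large-sample marginals recover the cohort-summary targets", {
  tab <- generate_cohort(cohort_spec(n_patients = 10000, seed = 1))
  base <- tab[tab$month == 0, ]
  # 3-sigma CLT bounds at n = 10000: 3 * 8.52/100 = 0.26, 3 * 9.55/100 = 0.29
  expect_lt(abs(mean(base$age) - 69.75), 0.25 + 0.05)
  expect_lt(abs(mean(base$adas_cog) - 16.62), 0.30)
  # every continuous feature within 4 sd/sqrt(n) of its schema mean
  sch <- default_schema()
  marg <- rbind(sch$static_continuous[, c("name", "mean", "sd")],
                sch$time_dependent[, c("name", "mean", "sd")])
  for (i in seq_len(nrow(marg))) {
    expect_lt(abs(mean(base[[marg$name[i]]]) - marg$mean[i]),
              4 * marg$sd[i] / sqrt(10000) + 1e-9,
              label = sprintf("|mean(%s) - %.2f|", marg$name[i], marg$mean[i]))
  }
  expect_lt(abs(mean(base$gender == "female") - 0.6116), 0.02)
  expect_true(all(base$adas_cog >= 0 & base$adas_cog <= 70))
  expect_true(all(tab$mmse >= 0 & tab$mmse <= 30))
})

test_that("arm drift moves 6-month conversion prevalence as planted", {
  spec <- cohort_spec(
    n_patients = 1000, seed = 2,
    drift = c(observation = 1.5, exercise = 0, donepezil = -3,
              gbe = 0, donepezil_gbe = 0),
    noise_sd = 2, miss_rate = 0
  )
  tab <- generate_cohort(spec)
  lab <- label_conversion(tab)
  l6 <- lab[lab$month == 6, ]
  arm <- tab$arm[tab$month == 0][match(l6$id, tab$id[tab$month == 0])]
  ci_rate <- tapply(l6$label == "CI", arm, mean)
  expect_gt(ci_rate[["donepezil"]], ci_rate[["observation"]])
})

test_that("conversion prevalence is monotone in the planted drift", {
  rates <- vapply(c(2, 0, -2, -4, -6), function(d) {
    spec <- cohort_spec(n_patients = 800, seed = 3,
                        drift = c(observation = d, exercise = d,
                                  donepezil = d, gbe = d, donepezil_gbe = d),
                        noise_sd = 2, miss_rate = 0)
    lab <- label_conversion(generate_cohort(spec))
    mean(lab$label[lab$month == 6] == "CI")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("missingness injection honors rates and protects baseline ADAS-cog", {
  spec0 <- planted_spec(n = 100, seed = 4)
  tab <- generate_cohort(spec0)

  spec_zero <- spec0; spec_zero$miss_rate <- 0
  expect_identical(inject_missingness(tab, spec_zero), tab)

  spec_gds <- spec0; spec_gds$miss_rate <- c(gds = 1)
  out <- inject_missingness(tab, spec_gds)
  expect_true(all(is.na(out$gds)))
  expect_false(anyNA(out$adas_cog[out$month == 0]))

  # binomial 3-sigma bound on the observed missing fraction
  spec_big <- cohort_spec(n_patients = 1700, seed = 5,
                          miss_rate = c(gds = 0.3))
  big <- inject_missingness(generate_cohort(spec_big), spec_big)
  n_cells <- nrow(big)
  expect_equal(n_cells, 5100)
  expect_lt(abs(mean(is.na(big$gds)) - 0.3), 0.02)
})

test_that("cohort CSV round-trips, and malformed files are rejected by name", {
  tab <- inject_missingness(generate_cohort(planted_spec(n = 25, seed = 9)),
                            cohort_spec(n_patients = 25, miss_rate = 0.1,
                                        seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(tab, path)
  expect_true(file.exists(paste0(path, ".schema.json")))
  back <- read_cohort(path)
  attr(tab, "clipped") <- NULL  # generation-time log, not part of the data
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  raw <- utils::read.csv(path)
  raw$mystery <- 1
  bad1 <- tempfile(fileext = ".csv")
  utils::write.csv(raw, bad1, row.names = FALSE)
  expect_error(read_cohort(bad1), "unknown column.*mystery")

  raw2 <- utils::read.csv(path)
  raw2$month[2] <- 4
  bad2 <- tempfile(fileext = ".csv")
  utils::write.csv(raw2, bad2, row.names = FALSE)
  expect_error(read_cohort(bad2), "month.*4.*not a scheduled visit")
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_patients = -1), "nonnegative")
  expect_error(cohort_spec(drift = c(observation = 1, exercise = 0,
                                     donepezil = 0, gbe = 0,
                                     donepezil_gbe = 0, banana = 2)),
               "unknown arm")
  expect_error(cohort_spec(miss_rate = 1.5), "miss_rate")
})
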