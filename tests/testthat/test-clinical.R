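test_that("the packaged cohort reproduces the published group statistics", {
  fx <- iga_cohort()
  expect_identical(nrow(fx), 39L)
  expect_identical(as.integer(table(fx$group)[c("IGA", "control")]),
                   c(18L, 21L))
  tab <- clinical_table(fx)
  expect_identical(nrow(tab), 7L)
  get <- function(v, col) tab[tab$variable == v, col]
  expect_equal(get("cias", "mean_iga"), 74.44, tolerance = 0.005)
  expect_equal(get("cias", "mean_control"), 38.43, tolerance = 0.005)
  expect_equal(get("cias", "sd_iga"), 8.33, tolerance = 0.005)
  expect_equal(get("cias", "sd_control"), 9.10, tolerance = 0.005)
  expect_equal(get("age", "mean_iga"), 20.5, tolerance = 0.005)
  expect_equal(get("age", "mean_control"), 21.95, tolerance = 0.005)
  expect_equal(get("sex", "mean_iga"), 15)      # male counts
  expect_equal(get("sex", "mean_control"), 18)
  # the addiction scales separate the groups decisively, age does not
  expect_lt(get("cias", "p"), 1e-10)
  expect_gt(get("age", "p"), 0.05)
})

test_that("group_summary matches stats::t.test and flips under relabeling", {
  fx <- iga_cohort()
  ref <- t.test(age ~ factor(group, c("IGA", "control")), data = fx,
                var.equal = TRUE)
  row <- group_summary(fx, "age")
  expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  # swapping the group labels negates t and swaps the summary columns
  sw <- fx
  sw$group <- ifelse(fx$group == "IGA", "control", "IGA")
  row2 <- group_summary(cohort_table(sw), "age")
  expect_equal(row2$statistic, -row$statistic, tolerance = 1e-12)
  expect_equal(row2$mean_iga, row$mean_control)
  expect_equal(row2$sd_control, row$sd_iga)
  expect_equal(row2$p, row$p, tolerance = 1e-12)
  # Welch option delegates to the unequal-variance test
  refw <- t.test(age ~ factor(group, c("IGA", "control")), data = fx)
  expect_equal(group_summary(fx, "age", var_equal = FALSE)$p, refw$p.value,
               tolerance = 1e-12)
})

test_that("the sex comparison is a chi-square on the 2x2 table", {
  fx <- iga_cohort()
  tab <- table(factor(fx$group, c("IGA", "control")), fx$sex)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  row <- group_summary(fx, "sex")
  expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  refy <- suppressWarnings(chisq.test(tab, correct = TRUE))
  expect_equal(group_summary(fx, "sex", yates = TRUE)$p, refy$p.value,
               tolerance = 1e-12)
})

test_that("degenerate and malformed inputs are handled explicitly", {
  fx <- iga_cohort()
  fx$age <- ifelse(fx$group == "IGA", 20, 21)    # zero variance in both groups
  row <- group_summary(fx, "age")
  expect_match(row$test, "degenerate")
  expect_true(is.na(row$p))
  expect_error(group_summary(fx, "shoe_size"), "unknown variable")
  expect_error(cohort_table(data.frame(subject_id = "a")), "missing columns")
  bad <- iga_cohort(); bad$group[1] <- "patient"
  expect_error(cohort_table(as.data.frame(bad)))
})

test_that("missing values are excluded and counted", {
  fx <- iga_cohort()
  fx$sas[c(1, 25)] <- NA
  row <- group_summary(fx, "sas")
  expect_identical(row$n_excluded, 2L)
  keep <- !is.na(fx$sas)
  ref <- t.test(fx$sas[keep & fx$group == "IGA"],
                fx$sas[keep & fx$group == "control"], var.equal = TRUE)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
})

test_that("null simulated cohorts give uniform p-values", {
  # same score model for both groups -> the t-test p for CIAS is U(0,1)
  model <- default_score_model()
  model$means$IGA <- model$means$control
  model$sds$IGA <- model$sds$control
  ps <- vapply(1:200, function(s)
    group_summary(simulate_scores(model, seed = s), "cias")$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})
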