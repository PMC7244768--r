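test_that("follow-up is capped at 60 months with events recoded as censored", {
  rec <- survival_records(c("A", "B", "C"), c(30, 72, 60), c(TRUE, TRUE, TRUE))
  expect_equal(rec$time, c(30, 60, 60))
  expect_equal(rec$event, c(TRUE, FALSE, TRUE))
  expect_error(survival_records("A", -1, TRUE), "negative")
})

test_that("Kaplan-Meier matches the hand product-limit on 3 uncensored deaths", {
  rec <- survival_records(paste0("S", 1:3), c(1, 2, 3), rep(TRUE, 3))
  km <- km_estimate(rec)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$lower >= 0 & km$upper <= 1))
})

test_that("Kaplan-Meier degenerate cases: all censored, no censoring", {
  cens <- survival_records(paste0("S", 1:4), c(5, 10, 20, 30), rep(FALSE, 4))
  expect_true(all(km_estimate(cens)$surv == 1))
  # without censoring the estimate equals the empirical survival function
  set.seed(2)
  t <- sort(ceiling(runif(20, 1, 50)))
  rec <- survival_records(paste0("S", 1:20), t, rep(TRUE, 20))
  km <- km_estimate(rec)
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank is zero on duplicated groups and matches a manual O-E tabulation", {
  base <- survival_records(paste0("S", 1:5), c(2, 4, 6, 8, 10),
                           c(TRUE, TRUE, FALSE, TRUE, FALSE))
  dup <- rbind(base, base)
  dup$sample <- paste0(dup$sample, rep(c("a", "b"), each = 5))
  lr <- logrank_test(dup, rep(c(0, 1), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # 6-subject fixture: manual observed-minus-expected tabulation
  rec <- survival_records(paste0("S", 1:6), c(1, 2, 3, 4, 5, 6),
                          c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  grp <- c(1, 0, 1, 0, 1, 0)
  manual <- local({
    times <- sort(unique(rec$time[rec$event]))
    o_minus_e <- 0; var_sum <- 0
    for (tt in times) {
      at_risk <- rec$time >= tt
      d <- sum(rec$time == tt & rec$event)
      d1 <- sum(rec$time == tt & rec$event & grp == 1)
      n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
      o_minus_e <- o_minus_e + (d1 - d * n1 / n)
      if (n > 1)
        var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_minus_e^2 / var_sum
  })
  lr2 <- logrank_test(rec, grp)
  expect_equal(lr2$statistic, manual, tolerance = 1e-10)
})

test_that("log-rank detects a hazard ratio of 2 at n=100 per arm", {
  set.seed(19)
  ps <- replicate(50, {
    seed <- sample.int(1e6, 1)
    covs <- data.frame(double_expressor = rep(c(FALSE, TRUE), each = 100))
    rec <- simulate_survival(covs, c(double_expressor = 2.0),
                             baseline_hazard = 0.03, censor_rate = 0.004,
                             seed = seed)
    logrank_test(rec, rec$double_expressor)$p_value
  })
  expect_lt(median(ps), 0.01)
})

test_that("threshold scan returns the argmin split and rejects degenerate input", {
  set.seed(33)
  n <- 120
  x <- rnorm(n)
  expr <- expression_matrix(
    matrix(x, n, 1, dimnames = list(sprintf("S%04d", 1:n), "MYC")))
  covs <- data.frame(high = x > quantile(x, 0.7),
                     row.names = sprintf("S%04d", 1:n))
  rec <- simulate_survival(covs, c(high = 3.0), seed = 9)
  scan <- threshold_scan(expr, "MYC", rec)
  expect_equal(scan$chosen_p, min(scan$grid$p_value, na.rm = TRUE))
  expect_equal(scan$chosen,
               scan$grid$threshold[which.min(scan$grid$p_value)])
  expect_equal(nrow(scan$grid), 17)

  const <- expression_matrix(
    matrix(1, n, 1, dimnames = list(sprintf("S%04d", 1:n), "MYC")))
  expect_error(threshold_scan(const, "MYC", rec), "degenerate grid")
})

test_that("double-expressor calls are conjunctive and monotone in thresholds", {
  set.seed(14)
  v <- matrix(rnorm(60 * 2, 5), 60, 2,
              dimnames = list(sprintf("S%02d", 1:60), c("MYC", "BCL2")))
  expr <- expression_matrix(v, level = "gene")
  de <- double_expressor(expr, 5, 5)
  expect_equal(de$flag, unname(v[, "MYC"] > 5) & unname(v[, "BCL2"] > 5),
               ignore_attr = TRUE)
  none <- double_expressor(expr, Inf, Inf)
  expect_equal(none$n_positive, 0L)
  # raising either threshold never adds a positive
  for (bump in c(0.2, 1, 2)) {
    expect_true(all(double_expressor(expr, 5 + bump, 5)$flag <= de$flag))
    expect_true(all(double_expressor(expr, 5, 5 + bump)$flag <= de$flag))
  }
})

test_that("Cox fit validates covariates and warns on sparse events", {
  covs <- data.frame(double_expressor = rep(c(TRUE, FALSE), 10),
                     abc_subtype = rep(TRUE, 20),
                     ipi_high = rep(c(TRUE, FALSE), each = 10))
  rec <- simulate_survival(covs, c(double_expressor = 2), seed = 3)
  expect_error(cox_multivariate(rec), "non-identifiable.*abc_subtype")
  expect_warning(cox_multivariate(rec, c("double_expressor", "ipi_high")),
                 "events")
})

test_that("null-covariate Cox CIs cover HR=1 at the nominal rate", {
  set.seed(77)
  covered <- replicate(200, {
    seed <- sample.int(1e6, 1)
    covs <- data.frame(flag = rep(c(TRUE, FALSE), each = 40))
    rec <- simulate_survival(covs, c(flag = 1.0), baseline_hazard = 0.03,
                             seed = seed)
    fit <- cox_multivariate(rec, "flag")
    fit$lower <= 1 && 1 <= fit$upper
  })
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("clinical CSV ingest maps IPI scores to the high-risk flag", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time_months,event,ipi_score",
               "S1,24,1,4", "S2,80,1,1"), path)
  rec <- read_clinical(path)
  expect_equal(rec$ipi_high, c(TRUE, FALSE))
  expect_equal(rec$time, c(24, 60))
  expect_equal(rec$event, c(TRUE, FALSE))
})
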