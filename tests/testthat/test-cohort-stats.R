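test_that("test-switching rule agrees with the expected-count oracle", {
  expect_equal(select_test(matrix(c(50, 50, 50, 50), 2)), "chi_square")
  expect_equal(select_test(matrix(c(1, 2, 9, 8), 2)), "fisher")
  # exactly 25% of cells below 5 already switches (inclusive rule)
  expect_equal(select_test(matrix(c(2, 8, 8, 32), 2)), "fisher")
  set.seed(13)
  for (i in 1:1000) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, lambda = sample(c(1, 4, 10, 40), 1)),
                  nr, nc)
    if (sum(tab) == 0) next
    expect_identical(select_test(tab), oracle_select_test(tab))
  }
  expect_error(select_test(matrix(1:3, 1)), "2x2")
  expect_error(select_test(matrix(0, 2, 2)), "zero")
})

test_that("association scan applies the right test per variable type", {
  set.seed(21)
  n <- 200
  co <- data.frame(
    mut_BAP1 = rep(c(TRUE, FALSE), each = n / 2),
    gep_class = sample(c("Class1", "Class2"), n, TRUE),
    thickness_mm = rnorm(n, 6, 2),
    rare_cat = sample(c("a", "b"), n, TRUE, prob = c(0.97, 0.03)),
    stringsAsFactors = FALSE)
  sc <- association_scan(co, "BAP1",
                         c("gep_class", "thickness_mm", "rare_cat"))
  expect_equal(sc$test_used[sc$variable == "gep_class"], "chi_square")
  expect_equal(sc$test_used[sc$variable == "thickness_mm"], "wilcoxon")
  expect_equal(sc$test_used[sc$variable == "rare_cat"], "fisher")
  # reported p matches a direct call
  ct <- chisq.test(table(co$mut_BAP1, co$gep_class), correct = FALSE)
  expect_equal(sc$p_value[sc$variable == "gep_class"], ct$p.value)
  # constant variable is untestable, not an error
  co$flat <- 1
  sc2 <- association_scan(co, "BAP1", "flat")
  expect_true(sc2$untestable)
  expect_error(association_scan(co, "NOPE", "flat"), "mut_NOPE")
})

test_that("Kaplan-Meier estimates match the product-limit oracle", {
  time <- c(2, 4, 4, 7, 9, 12, 15, 20)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km <- km_logrank(time, event, rep("all", 8))
  or <- oracle_km(time, event)
  ss <- summary(km$fit, times = or$time)
  expect_equal(ss$surv, or$surv)
  expect_false(km$test_defined)
})

test_that("log-rank chi-square matches direct risk-set arithmetic", {
  set.seed(31)
  for (i in 1:20) {
    n <- 40
    time <- round(rexp(n, 0.05), 1)
    event <- rbinom(n, 1, 0.7)
    group <- rep(c("A", "B"), each = n / 2)
    km <- km_logrank(time, event, group)
    expect_equal(km$chisq, oracle_logrank_chisq(time, event, group),
                 tolerance = 1e-8)
  }
  # no events: flagged undefined
  expect_false(km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0),
                          c("A", "A", "B", "B"))$test_defined)
})

test_that("log-rank p is calibrated against exact permutation on tiny data", {
  time <- c(3, 5, 8, 11, 14, 17, 20, 23)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  group <- c("A", "A", "A", "A", "B", "B", "B", "B")
  km <- km_logrank(time, event, group)
  p_perm <- oracle_logrank_perm_p(time, event, group)
  # chi-square reference vs exact permutation: same order of magnitude and
  # same accept/reject region at the 10% level
  expect_lt(abs(km$logrank_p - p_perm), 0.06)
  expect_equal(km$logrank_p < 0.1, p_perm < 0.1)
})

test_that("Cox fit recovers a known hazard ratio and flags bad designs", {
  set.seed(41)
  hits <- 0L
  for (s in 1:10) {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    lambda0 <- 0.223 / 60            # ~40% events at the 60-month horizon
    t_ev <- rexp(n, lambda0 * 4^x)
    df <- data.frame(mfs_months = pmin(t_ev, 60),
                     mfs_event = as.integer(t_ev <= 60), x = x)
    cx <- cox_fit(df, "x", "MFS")
    hr <- unname(cx$hazard_ratios)
    if (hr > 3.2 && hr < 5.0) hits <- hits + 1L
    expect_true(unname(cx$ci_lower) < hr && hr < unname(cx$ci_upper))
  }
  expect_gte(hits, 9L)
  # aliased covariates error; sparse events warn
  df2 <- data.frame(mfs_months = rexp(40, 0.05), mfs_event = 1,
                    a = rnorm(40))
  df2$b <- 2 * df2$a
  expect_error(cox_fit(df2, c("a", "b"), "MFS"), "singular")
  df3 <- data.frame(mfs_months = c(rexp(30, 0.01), rexp(10, 0.2)),
                    x = rnorm(40))
  df3$mfs_event <- c(rep(0, 36), rep(1, 4))
  expect_warning(cox_fit(df3, "x", "MFS"), "events")
  expect_error(cox_fit(transform(df3, x = 1), "x", "MFS"), "constant")
})

test_that("propensity matching balances size covariates at 3:1", {
  set.seed(51)
  n <- 800
  co <- data.frame(thickness_mm = c(rnorm(100, 2, 0.4),
                                    rnorm(n - 100, 7, 2.5)),
                   diameter_mm = c(rnorm(100, 10, 1.5),
                                   rnorm(n - 100, 15, 3)))
  case <- rep(c(TRUE, FALSE), c(100, n - 100))
  pm <- propensity_match(co, case)
  expect_lte(length(pm$matched_controls), 300)
  expect_equal(anyDuplicated(pm$matched_controls), 0)
  expect_true(all(!case[pm$matched_controls]))
  # matching reduces the standardized mean differences
  expect_true(all(pm$smd_after < pm$smd_before))
  expect_error(propensity_match(co[1:10, ], rep(c(TRUE, FALSE), c(5, 5))),
               "controls")
})

test_that("model survival probabilities respect covariate ordering", {
  set.seed(61)
  n <- 600
  d <- runif(n, -1, 1)
  t_ev <- rexp(n, 0.004 * exp(1.2 * d))
  df <- data.frame(dscore = d, mfs_months = pmin(t_ev, 72),
                   mfs_event = as.integer(t_ev <= 72))
  st <- survival_at_times(df, "dscore", "MFS")
  expect_equal(dim(st$surv), c(5, 5))
  expect_true(all(st$surv >= 0 & st$surv <= 1))
  # survival decreases with time at fixed covariate value ...
  expect_true(all(apply(st$surv, 1, function(r) all(diff(r) <= 1e-12))))
  # ... and with the (hazard-increasing) covariate at fixed time
  expect_true(all(apply(st$surv, 2, function(cl) all(diff(cl) <= 1e-12))))
  expect_false(any(st$extrapolated))
  expect_warning(survival_at_times(df, "dscore", "MFS", times = c(60, 120)),
                 "extrapolated")
})

test_that("closed-form power matches the oracle and behaves sensibly", {
  expect_equal(schoenfeld_power(c(25, 85), c(0.90, 0.70)),
               oracle_schoenfeld(25, 85, 0.90, 0.70), tolerance = 1e-12)
  # frozen value of the closed form for the study design
  expect_equal(schoenfeld_power(c(25, 85), c(0.90, 0.70)), 0.7716074,
               tolerance = 1e-6)
  # power grows with sample size and with effect size
  expect_gt(schoenfeld_power(c(50, 170), c(0.90, 0.70)),
            schoenfeld_power(c(25, 85), c(0.90, 0.70)))
  expect_gt(schoenfeld_power(c(25, 85), c(0.90, 0.60)),
            schoenfeld_power(c(25, 85), c(0.90, 0.70)))
})

test_that("Monte-Carlo power is reproducible and calibrated under the null", {
  p1 <- logrank_power(c(40, 40), c(0.8, 0.8), n_reps = 2000, seed = 7)
  expect_lt(abs(p1$estimated_power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  p2 <- logrank_power(c(40, 40), c(0.8, 0.8), n_reps = 2000, seed = 7)
  expect_identical(p1$estimated_power, p2$estimated_power)
  expect_error(logrank_power(c(25, 85), c(0.9, 0.7), n_reps = 100),
               "n_reps")
  # where events are plentiful and the effect moderate, the closed form
  # and the simulation agree closely
  p3 <- logrank_power(c(150, 150), c(0.55, 0.40), n_reps = 2000, seed = 8)
  expect_lt(abs(p3$estimated_power - p3$schoenfeld), 0.04)
})
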