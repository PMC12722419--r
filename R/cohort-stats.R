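# Cohort statistics: test-switching rule, association scans, Kaplan-Meier /
# log-rank, Cox models, propensity matching, survival probabilities for
# continuous covariates, and the log-rank power simulation.  All tests are
# two-sided; raw p-values are reported without multiplicity correction.

#' Chi-square versus Fisher switching rule
#'
#' Fisher's exact test is selected when at least 25% of cells have expected
#' counts below 5 under the independence margins; otherwise chi-square.
#'
#' @param table Matrix of non-negative contingency counts (>= 2x2).
#' @return `"chi_square"` or `"fisher"`.
#' @examples
#' select_test(matrix(c(50, 50, 50, 50), 2))  # chi_square
#' select_test(matrix(c(1, 2, 9, 8), 2))      # fisher
#' @export
select_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || nrow(table) < 2 || ncol(table) < 2)
    stop("need a contingency matrix of non-negative counts, >= 2x2",
         call. = FALSE)
  tot <- sum(table)
  if (tot == 0) stop("zero grand total: test undefined", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / tot
  if (mean(expected < 5) >= 0.25) "fisher" else "chi_square"
}

# run the categorical test chosen by the switching rule
categorical_test <- function(tab) {
  test <- select_test(tab)
  if (test == "fisher") {
    ft <- stats::fisher.test(tab)
    list(test_used = "fisher", statistic = unname(ft$estimate)[1],
         p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test_used = "chi_square", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  }
}

#' Association scan of one mutation against clinical variables
#'
#' Compares all samples carrying a given mutation to all those without it:
#' categorical variables through the chi-square/Fisher switching rule
#' ([select_test()]), continuous variables through the two-tailed
#' Wilcoxon rank-sum test.
#'
#' @param cohort Cohort data frame with logical `mut_<gene>` columns.
#' @param mutation Gene id (e.g. `"BAP1"`); the scan uses column
#'   `mut_<mutation>`.
#' @param variables Character vector of cohort column names to test.
#' @return Data frame: `variable`, `mutation`, `test_used`, `statistic`,
#'   `p_value`, `untestable`.
#' @export
association_scan <- function(cohort, mutation, variables) {
  mcol <- paste0("mut_", mutation)
  if (!mcol %in% names(cohort))
    stop("cohort lacks column ", mcol, call. = FALSE)
  flag <- cohort[[mcol]]
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    base <- data.frame(variable = v, mutation = mutation,
                       test_used = NA_character_, statistic = NA_real_,
                       p_value = NA_real_, untestable = FALSE,
                       stringsAsFactors = FALSE)
    if (length(unique(flag)) < 2 || length(unique(x[!is.na(x)])) < 2) {
      base$untestable <- TRUE
      return(base)
    }
    if (is.numeric(x)) {
      wt <- stats::wilcox.test(x ~ factor(flag), exact = FALSE)
      base$test_used <- "wilcoxon"
      base$statistic <- unname(wt$statistic)
      base$p_value <- wt$p.value
    } else {
      res <- categorical_test(table(flag, x))
      base$test_used <- res$test_used
      base$statistic <- res$statistic
      base$p_value <- res$p_value
    }
    base
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival curves per group with the two-sided log-rank test.
#' A single group yields curves only (`logrank_p = NA`); data with no events
#' yield flat curves and an undefined (flagged) test.
#'
#' @param time,event Follow-up times (months) and event indicators.
#' @param group Group labels.
#' @return List with `fit` (a [survival::survfit] object), `logrank_p`,
#'   `chisq` and `test_defined`.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  df <- data.frame(time = time, event = as.integer(event),
                   group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (nlevels(df$group) < 2 || sum(df$event) == 0)
    return(list(fit = fit, logrank_p = NA_real_, chisq = NA_real_,
                test_defined = FALSE))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = nlevels(df$group) - 1,
                     lower.tail = FALSE)
  list(fit = fit, logrank_p = p, chisq = unname(sd_$chisq),
       test_defined = TRUE)
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Partial-likelihood fit with two-sided Wald p-values per covariate.
#' Warns when events are fewer than five per covariate; convergence failure
#' or singular covariates error rather than returning silent estimates.
#'
#' @param data Data frame containing the covariates and the endpoint
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param endpoint `"MFS"` or `"OS"`: uses `mfs_months`/`mfs_event` or
#'   `os_months`/`os_event`.
#' @return List of class `cox_result`: `endpoint`, `model_type`,
#'   `hazard_ratios`, `ci_lower`, `ci_upper`, `p_values`, `fit`.
#' @export
cox_fit <- function(data, covariates, endpoint = c("MFS", "OS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "MFS") "mfs_months" else "os_months"
  ecol <- if (endpoint == "MFS") "mfs_event" else "os_event"
  for (cv in covariates)
    if (length(unique(data[[cv]])) < 2)
      stop("constant covariate: ", cv, call. = FALSE)
  nev <- sum(data[[ecol]])
  if (nev < 5 * length(covariates))
    warning(sprintf("only %d events for %d covariates", nev,
                    length(covariates)))
  fml <- stats::as.formula(paste0(
    "survival::Surv(", tcol, ", ", ecol, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("singular design: aliased covariates in the Cox fit",
         call. = FALSE)
  s <- summary(fit)
  out <- list(endpoint = endpoint,
              model_type = if (length(covariates) > 1) "multivariate"
              else "univariate",
              hazard_ratios = s$conf.int[, "exp(coef)"],
              ci_lower = s$conf.int[, "lower .95"],
              ci_upper = s$conf.int[, "upper .95"],
              p_values = s$coefficients[, "Pr(>|z|)"],
              fit = fit)
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("%s Cox model (%s)\n", x$endpoint, x$model_type))
  hr <- x$hazard_ratios
  for (i in seq_along(hr))
    cat(sprintf("  %-20s HR %.2f (%.2f-%.2f), p = %.3g\n",
                names(hr)[i], hr[i], x$ci_lower[i], x$ci_upper[i],
                x$p_values[i]))
  invisible(x)
}

#' 3:1 propensity-score matching on tumor size
#'
#' Propensity of case status is fitted by logistic regression on the
#' matching variables (default thickness and diameter); controls are
#' matched greedily, nearest-neighbour on the logit propensity without
#' replacement, `ratio` controls per case, within a caliper of
#' `caliper_sd` standard deviations of the logit.  Cases are processed in
#' decreasing propensity order.  Standardized mean differences before and
#' after matching are reported.
#'
#' @param data Cohort data frame.
#' @param case_flag Logical vector: TRUE for cases.
#' @param match_vars Matching variable column names.
#' @param ratio Controls per case (default 3).
#' @param caliper_sd Caliper in SD units of the logit propensity; `Inf`
#'   disables it.
#' @return List of class `propensity_match`: `matched_controls` (row
#'   indices into `data`), `case_rows`, `smd_before`, `smd_after`,
#'   `complete` (FALSE when some cases could not be fully matched within
#'   the caliper).
#' @export
propensity_match <- function(data, case_flag,
                             match_vars = c("thickness_mm", "diameter_mm"),
                             ratio = 3, caliper_sd = 0.2) {
  stopifnot(length(case_flag) == nrow(data))
  n_case <- sum(case_flag)
  n_ctrl <- sum(!case_flag)
  if (n_ctrl < ratio * n_case)
    stop("need at least ratio x cases eligible controls", call. = FALSE)
  fml <- stats::as.formula(paste(".case ~",
                                 paste(match_vars, collapse = " + ")))
  df <- data[, match_vars, drop = FALSE]
  df$.case <- as.integer(case_flag)
  ps <- stats::predict(stats::glm(fml, family = stats::binomial(),
                                  data = df), type = "link")
  cal <- caliper_sd * stats::sd(ps)

  case_idx <- which(case_flag)[order(-ps[case_flag])]
  avail <- which(!case_flag)
  matched <- integer(0)
  complete <- TRUE
  for (ci in case_idx) {
    d <- abs(ps[avail] - ps[ci])
    ok <- order(d)[seq_len(min(ratio, length(avail)))]
    ok <- ok[d[ok] <= cal]
    if (length(ok) < ratio) complete <- FALSE
    if (length(ok)) {
      matched <- c(matched, avail[ok])
      avail <- avail[-ok]
    }
  }

  smd <- function(idx_ctrl) {
    vapply(match_vars, function(v) {
      xc <- data[[v]][case_flag]
      xk <- data[[v]][idx_ctrl]
      pooled <- sqrt((stats::var(xc) + stats::var(xk)) / 2)
      abs(mean(xc) - mean(xk)) / pooled
    }, numeric(1))
  }
  out <- list(matched_controls = matched, case_rows = which(case_flag),
              smd_before = smd(which(!case_flag)),
              smd_after = smd(matched),
              propensity = ps, complete = complete)
  class(out) <- "propensity_match"
  out
}

#' @export
print.propensity_match <- function(x, ...) {
  cat(sprintf("Propensity match: %d cases, %d matched controls%s\n",
              length(x$case_rows), length(x$matched_controls),
              if (x$complete) "" else " (partial: caliper exhausted)"))
  cat("  SMD before:", paste(sprintf("%s %.3f", names(x$smd_before),
                                     x$smd_before), collapse = ", "), "\n")
  cat("  SMD after: ", paste(sprintf("%s %.3f", names(x$smd_after),
                                     x$smd_after), collapse = ", "), "\n")
  invisible(x)
}

#' Survival probabilities at specified times for a continuous covariate
#'
#' Fits a Cox model containing the continuous covariate and evaluates the
#' model survival function at the requested times for a grid of covariate
#' values (baseline survival exp-linked to the covariate effect).
#'
#' @param data Cohort data frame.
#' @param covariate Continuous covariate column name (e.g. `"dscore"`).
#' @param endpoint `"MFS"` or `"OS"`.
#' @param times Months at which to evaluate (default 12, 24, 36, 48, 60).
#' @param values Covariate values to evaluate at (default quintile
#'   midpoints of the observed distribution).
#' @return List of class `survival_at_times`: `surv` matrix (values x
#'   times), `times`, `values`, `extrapolated` (times beyond follow-up),
#'   `cox`.
#' @export
survival_at_times <- function(data, covariate, endpoint = c("MFS", "OS"),
                              times = c(12, 24, 36, 48, 60),
                              values = NULL) {
  endpoint <- match.arg(endpoint)
  cx <- cox_fit(data, covariate, endpoint)
  if (is.null(values))
    values <- unname(stats::quantile(data[[covariate]],
                                     probs = seq(0.1, 0.9, by = 0.2)))
  nd <- stats::setNames(data.frame(values), covariate)
  sf <- survival::survfit(cx$fit, newdata = nd)
  tcol <- if (endpoint == "MFS") "mfs_months" else "os_months"
  max_fu <- max(data[[tcol]])
  extrapolated <- times > max_fu
  if (any(extrapolated))
    warning("requested times beyond follow-up are flagged extrapolated")
  ss <- summary(sf, times = pmin(times, max_fu), extend = TRUE)
  surv <- t(matrix(ss$surv, nrow = length(times)))
  dimnames(surv) <- list(value = signif(values, 4), time = times)
  out <- list(surv = surv, times = times, values = values,
              extrapolated = extrapolated, cox = cx)
  class(out) <- "survival_at_times"
  out
}

#' @export
print.survival_at_times <- function(x, ...) {
  cat(sprintf("%s survival probabilities (Cox, continuous covariate)\n",
              x$cox$endpoint))
  print(round(x$surv, 3))
  invisible(x)
}

#' Schoenfeld closed-form power for the log-rank test
#'
#' Events-based approximation: with expected event count d, allocation
#' fractions p1, p2 and hazard ratio HR,
#' power = Phi(sqrt(d p1 p2) |log HR| - z_(1-alpha/2)).
#' Exponential margins are assumed, with administrative censoring at the
#' horizon, so d = n1 (1 - S1) + n2 (1 - S2) and
#' HR = log(S2) / log(S1).
#'
#' @param n_per_group Length-2 group sizes.
#' @param survival_at_horizon Length-2 survival fractions at the horizon.
#' @param alpha Two-sided type-I error.
#' @return Power (fraction).
#' @export
schoenfeld_power <- function(n_per_group, survival_at_horizon,
                             alpha = 0.05) {
  s <- survival_at_horizon
  stopifnot(length(n_per_group) == 2, length(s) == 2,
            all(s > 0), all(s < 1))
  d <- sum(n_per_group * (1 - s))
  p1 <- n_per_group[1] / sum(n_per_group)
  hr <- log(s[2]) / log(s[1])
  stats::pnorm(sqrt(d * p1 * (1 - p1)) * abs(log(hr)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Monte-Carlo power of the two-sided log-rank test
#'
#' Simulates exponential event times in two groups matched to the stated
#' horizon survivals, applies administrative censoring at the horizon and
#' the two-sided log-rank test per replicate; power is the rejection
#' fraction with its Monte-Carlo standard error.
#'
#' @param n_per_group Length-2 group sizes (e.g. `c(25, 85)`).
#' @param survival_at_horizon Length-2 survival fractions at
#'   `horizon_months` (e.g. `c(0.90, 0.70)`).
#' @param horizon_months Censoring horizon (default 60).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param n_reps Number of replicates (>= 1000).
#' @param seed Integer seed.
#' @return List of class `power_result`: `estimated_power`, `mc_se`,
#'   inputs, and `schoenfeld` (the closed-form cross-check).
#' @examples
#' \donttest{
#' logrank_power(c(25, 85), c(0.90, 0.70), n_reps = 2000, seed = 1)
#' }
#' @export
logrank_power <- function(n_per_group, survival_at_horizon,
                          horizon_months = 60, alpha = 0.05,
                          n_reps = 10000, seed = 1) {
  s <- survival_at_horizon
  stopifnot(length(n_per_group) == 2, length(s) == 2,
            all(s > 0), all(s < 1))
  if (n_reps < 1000) stop("n_reps must be >= 1000", call. = FALSE)
  set.seed(seed)
  rates <- -log(s) / horizon_months
  n1 <- n_per_group[1]; n2 <- n_per_group[2]
  grp <- factor(rep(1:2, c(n1, n2)))
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    t_ev <- c(stats::rexp(n1, rates[1]), stats::rexp(n2, rates[2]))
    event <- as.integer(t_ev <= horizon_months)
    tm <- pmin(t_ev, horizon_months)
    if (sum(event) == 0) { rej[r] <- FALSE; next }
    sd_ <- survival::survdiff(survival::Surv(tm, event) ~ grp)
    rej[r] <- stats::pchisq(sd_$chisq, 1, lower.tail = FALSE) < alpha
  }
  pw <- mean(rej)
  out <- list(n_per_group = n_per_group,
              survival_at_horizon = s, horizon_months = horizon_months,
              alpha = alpha, n_reps = n_reps,
              estimated_power = pw,
              mc_se = sqrt(pw * (1 - pw) / n_reps),
              schoenfeld = schoenfeld_power(n_per_group, s, alpha))
  if (abs(s[1] - s[2]) < 1e-12 && abs(pw - alpha) > 3 * out$mc_se)
    warning("null design: estimated power deviates from alpha by > 3 MC-SE")
  class(out) <- "power_result"
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Log-rank power: %.1f%% (MC-SE %.2f%%, %d reps)\n  groups n = %d/%d, S(%g mo) = %.2f/%.2f, alpha = %g\n  Schoenfeld closed form: %.1f%%\n",
    100 * x$estimated_power, 100 * x$mc_se, x$n_reps,
    x$n_per_group[1], x$n_per_group[2], x$horizon_months,
    x$survival_at_horizon[1], x$survival_at_horizon[2], x$alpha,
    100 * x$schoenfeld))
  invisible(x)
}
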