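test_that("Kaplan-Meier estimate matches hand computation and edge cases", {
  ex <- km_hand_example()
  km <- km_fit(ex$time, ex$event)
  expect_equal(km$surv, c(5 / 6, 5 / 6, 5 / 8, 5 / 8, 5 / 16, 0))
  expect_equal(km$median$est, 5)  # first time S(t) <= 0.5
  # without censoring KM equals the empirical survival function
  set.seed(12)
  t <- stats::rexp(300, 0.1)
  km2 <- km_fit(t, rep(1, 300))
  expect_equal(km2$surv, 1 - seq_along(sort(t)) / 300, tolerance = 1e-12)
  # no events: flat at 1, median not reached
  km3 <- km_fit(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median$est))
  expect_error(km_fit(c(0, 0), c(1, 1)), "zero")
  expect_error(km_fit(numeric(0), numeric(0)), "no observations")
})

test_that("horizon rates track the exponential closed form", {
  set.seed(30)
  lam <- 0.02
  t <- stats::rexp(800, lam)
  km <- km_fit(t, rep(1, 800), horizons = c(36, 60))
  i60 <- which(km$rates$horizon == 60)
  se <- sqrt(exp(-lam * 60) * (1 - exp(-lam * 60)) / 800)  # binomial SE, no censoring
  expect_lt(abs(km$rates$rate[i60] - exp(-lam * 60)), 3 * se)
  expect_true(all(km$rates$lower <= km$rates$rate & km$rates$rate <= km$rates$upper))
})

test_that("two-group log-rank agrees with survdiff and behaves under separation", {
  set.seed(40)
  d <- sim_two_arm(80, 0.05, 0.02, censor = 50)
  lr <- logrank_test(d$times, d$events, d$group)
  sd_ref <- survival::survdiff(survival::Surv(d$times, d$events) ~ d$group)
  expect_equal(lr$statistic, unname(sd_ref$chisq), tolerance = 1e-10)
  expect_equal(lr$p_value, stats::pchisq(sd_ref$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # three groups delegate to survdiff
  g3 <- rep(c("a", "b", "c"), length.out = nrow(d))
  lr3 <- logrank_test(d$times, d$events, g3)
  expect_equal(lr3$df, 2L)
  expect_error(logrank_test(d$times, d$events, rep("a", nrow(d))), "two groups")
  # power under HR = 3
  hits <- 0
  for (s in 1:10) {
    dd <- sim_two_arm(200, 0.06, 0.02)
    if (logrank_test(dd$times, dd$events, dd$group)$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # extreme separation stays finite
  ex <- logrank_test(c(rep(1, 50), stats::rexp(50, 0.001) + 1),
                     c(rep(1, 50), rep(0, 50)),
                     rep(c("all_events", "none"), each = 50))
  expect_true(is.finite(ex$statistic))
  expect_lt(ex$p_value, 0.05)
})

test_that("stratified Cox recovers simulated effects and reports degeneracies", {
  set.seed(50)
  n <- 1000
  grp <- sample(c("lo", "hi"), n, replace = TRUE)
  ctr <- sample(c("c1", "c2", "c3"), n, replace = TRUE)
  base <- c(c1 = 0.03, c2 = 0.06, c3 = 0.10)[ctr]
  t <- stats::rexp(n, base * ifelse(grp == "hi", 2, 1))
  cens <- stats::runif(n, 5, 60)
  co <- data.frame(ttr_months = pmin(t, cens), ttr_event = as.integer(t <= cens),
                   grp = grp, center = ctr)
  fit <- cox_fit(co, "ttr", "grp", strata = "center", ref_levels = list(grp = "lo"))
  est <- log(fit$terms$hr[1])
  se <- (log(fit$terms$upper[1]) - log(fit$terms$hr[1])) / stats::qnorm(0.975)
  expect_lt(abs(est - log(2)), 2 * se)
  # strata relabeling leaves the estimate untouched
  co2 <- co; co2$center <- paste0("relabel_", co2$center)
  fit2 <- cox_fit(co2, "ttr", "grp", strata = "center", ref_levels = list(grp = "lo"))
  expect_equal(fit2$terms$hr, fit$terms$hr, tolerance = 1e-12)
  # log-rank p and single-covariate Cox Wald p agree asymptotically
  lr <- logrank_test(co$ttr_months, co$ttr_event, co$grp)
  expect_equal(fit_nostrata <- cox_fit(co, "ttr", "grp", strata = NULL,
                                       ref_levels = list(grp = "lo"))$terms$p_value,
               lr$p_value, tolerance = 0.1)
  # constant covariate: degenerate, flagged, HR 1
  co$flat <- "x"
  fitc <- cox_fit(co, "ttr", c("grp", "flat"), strata = "center")
  row <- fitc$terms[fitc$terms$covariate == "flat", ]
  expect_equal(row$hr, 1)
  expect_equal(row$p_value, 1)
  expect_true(row$degenerate)
  expect_error(cox_fit(co, "ttr", "flat", strata = "center"), "constant")
  # separated level carries the 0/Inf HR sentinel rather than erroring
  co$sep <- ifelse(co$ttr_event == 1, "ev", sample(c("ev", "never"), n, TRUE))
  fits <- suppressWarnings(cox_fit(co, "ttr", "sep", strata = NULL))
  expect_lt(fits$terms$hr[1], 1e-2)
})

test_that("concordance hits its theoretical anchors", {
  # perfectly separating continuous predictor, no ties, no censoring
  set.seed(60)
  x <- stats::runif(120)
  co <- data.frame(ttr_months = 100 - 90 * x, ttr_event = 1L, risk = x)
  fit <- suppressWarnings(cox_fit(co, "ttr", "risk", strata = NULL))
  expect_equal(fit$c_index$est, 1)
  # null covariate: C near 1/2
  co$noise <- stats::runif(120)
  fit0 <- cox_fit(co, "ttr", "noise", strata = NULL)
  expect_lt(abs(fit0$c_index$est - 0.5), 0.15)
})

test_that("RMST comparison matches closed forms, KM integration, and symmetry", {
  expect_identical_arms <- rmst_compare(c(1:10, 1:10), rep(1, 20),
                                        rep(c("a", "b"), each = 10))
  expect_equal(expect_identical_arms$diff, 0)
  expect_equal(expect_identical_arms$p_value, 1)
  # exponential closed form (1 - exp(-lam * tau)) / lam
  set.seed(70)
  lam <- 0.02; tau <- 60
  t <- stats::rexp(800, lam)
  one <- rmst_one(t, rep(1, 800), tau)
  expect_lt(abs(one$rmst - (1 - exp(-lam * tau)) / lam), 3 * one$se)
  # against independent numerical integration of the survfit curve
  sf <- survival::survfit(survival::Surv(t, rep(1, 800)) ~ 1)
  steps <- c(0, sf$time[sf$time <= tau], tau)
  sv <- c(1, sf$surv[sf$time <= tau])
  expect_equal(one$rmst, sum(diff(steps) * sv), tolerance = 1e-10)
  # dominance: uniformly better arm has positive RMST difference
  d <- sim_two_arm(300, 0.08, 0.02, censor = 80)
  cmp <- rmst_compare(d$times, d$events, d$group)
  expect_gt(cmp$diff, 0)  # arm b (second level) has the lower hazard
  expect_lt(cmp$p_value, 0.05)
  expect_error(rmst_compare(d$times, d$events, d$group, tau = 1000), "exceeds")
})

test_that("chi-squared importance shares are normalized and sane", {
  set.seed(80)
  d <- sim_two_arm(200, 0.08, 0.02)
  co <- data.frame(ttr_months = d$times, ttr_event = d$events, grp = d$group)
  fit <- cox_fit(co, "ttr", "grp", strata = NULL)
  expect_equal(unname(chi2_importance(fit)), 1)
  # two equal-effect independent covariates split the importance roughly evenly
  n <- 2000
  a <- sample(0:1, n, TRUE); b <- sample(0:1, n, TRUE)
  t <- stats::rexp(n, 0.04 * exp(0.7 * a + 0.7 * b))
  co2 <- data.frame(ttr_months = t, ttr_event = 1L,
                    a = c("x", "y")[a + 1], b = c("x", "y")[b + 1])
  sh <- chi2_importance(cox_fit(co2, "ttr", c("a", "b"), strata = NULL))
  expect_equal(sum(sh), 1)
  expect_true(all(sh > 0.35 & sh < 0.65))
})

test_that("Schoenfeld event counts follow the closed form", {
  s <- schoenfeld_sample_size(hr = 2, alpha = 0.05, sided = 2, power = 0.8,
                              allocation = 0.5, event_fraction = 1)
  expect_equal(ceiling(s$events), 66)
  expect_equal(s$total_n, 66L)
  # halving (ln hr)^2 doubles the required events exactly
  s1 <- schoenfeld_sample_size(hr = exp(1), power = 0.9)
  s2 <- schoenfeld_sample_size(hr = exp(1 / sqrt(2)), power = 0.9)
  expect_equal(s2$events / s1$events, 2, tolerance = 1e-12)
  # monotone divergence as hr -> 1
  es <- vapply(c(1.5, 1.2, 1.05, 1.01), function(h)
    schoenfeld_sample_size(h)$events, numeric(1))
  expect_true(all(diff(es) > 0))
  expect_error(schoenfeld_sample_size(1), "different from 1")
  # the published design range reproduces under a one-sided alpha
  lo <- schoenfeld_sample_size(2.1, alpha = 0.05, sided = 1, power = 0.9,
                               event_fraction = 0.6)
  hi <- schoenfeld_sample_size(1.85, alpha = 0.05, sided = 1, power = 0.9,
                               event_fraction = 0.6)
  expect_equal(lo$total_n, 104L)
  expect_equal(hi$total_n, 151L)
})
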