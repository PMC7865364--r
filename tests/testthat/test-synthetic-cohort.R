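test_that("generator is deterministic, honors n = 0, and keeps time invariants", {
  cfg <- cohort_config(n_patients = 200, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cohort_config(n_patients = 200, seed = 12))))

  empty <- generate_cohort(cohort_config(n_patients = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("cd3_ct", "pcr", "os_event") %in% names(empty)))

  expect_true(all(a$ttr_months >= 0 & a$os_months >= 0))
  expect_true(all(a$ttr_months <= a$os_months + 1e-9))
  expect_true(all(a$ttr_event %in% 0:1 & a$os_event %in% 0:1))
  # IM densities jointly present or jointly missing
  expect_false(any(xor(is.na(a$cd3_im), is.na(a$cd8_im))))
})

test_that("default config reproduces the cohort's categorical margins within 3 binomial SDs", {
  co <- generate_cohort(cohort_config(seed = 4))
  n <- nrow(co)
  expect_equal(n, 117)
  check_margin <- function(observed_frac, p) {
    expect_lt(abs(observed_frac - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
  check_margin(mean(co$gender == "Male"), 91 / 117)
  cfg <- cohort_config()
  for (lev in names(cfg$center_probs))
    check_margin(mean(co$center == lev), cfg$center_probs[[lev]])
  for (lev in names(cfg$n_stage_probs))
    check_margin(mean(co$n_stage == lev), cfg$n_stage_probs[[lev]])
  for (lev in names(cfg$regimen_probs))
    check_margin(mean(co$regimen == lev), cfg$regimen_probs[[lev]])
  check_margin(mean(is.na(co$pcr)), 16 / 117)
  check_margin(mean(is.na(co$cd3_im)), 14 / 117)
})

test_that("invalid configs are rejected", {
  expect_error(cohort_config(n_patients = -1), "n_patients")
  expect_error(cohort_config(latent_corr = 1), "latent_corr")
  expect_error(cohort_config(baseline_hazard_ttr = 0), "baseline_hazard_ttr")
  expect_error(cohort_config(frac_missing_im = 1.2), "frac_missing_im")
  expect_error(cohort_config(center_probs = c(a = 0.5, b = 0.4)), "summing to 1")
  expect_error(cohort_config(admin_censor_months = NaN), "admin_censor")
})

test_that("a stronger immune effect on pCR raises the simulated pCR rate", {
  rate <- function(effect, seed) {
    co <- generate_cohort(cohort_config(n_patients = 5000, seed = seed,
                                        immune_effect_pcr = effect,
                                        frac_missing_pcr = 0))
    mean(co$pcr == "yes")
  }
  r0 <- rate(0, 21); r2 <- rate(2, 21); r5 <- rate(5, 21)
  expect_lt(r0, r2)
  expect_lt(r2, r5)
})

test_that("cohort CSV round-trips losslessly and the reader enforces invariants", {
  co <- generate_cohort(cohort_config(seed = 8))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back, co)

  # empty IM density cells come back as a jointly-missing margin
  expect_identical(is.na(back$cd3_im), is.na(co$cd3_im))

  bad <- co; bad$ttr_months[3] <- -1
  g <- tempfile(fileext = ".csv"); write_cohort(bad, g)
  expect_error(read_cohort(g), "negative time.*row 3")

  bad2 <- co; bad2$cd8_ct <- as.character(bad2$cd8_ct); bad2$cd8_ct[5] <- "high"
  h <- tempfile(fileext = ".csv"); utils::write.csv(bad2, h, row.names = FALSE, na = "")
  expect_error(read_cohort(h), "non-numeric.*cd8_ct.*row 5")

  txt <- readLines(f); txt[1] <- sub("cd3_ct", "cd3ct", txt[1])
  m <- tempfile(fileext = ".csv"); writeLines(txt, m)
  expect_error(read_cohort(m), "malformed cohort header")
})

test_that("synthetic slides follow the Poisson point model and propagate missing margins", {
  targets <- c(cd3_ct = 500, cd8_ct = 200, cd3_im = 600, cd8_im = 250)
  sl <- generate_slide(targets, areas = c(ct = 2, im = 1), seed = 14)
  expect_identical(generate_slide(targets, areas = c(ct = 2, im = 1), seed = 14), sl)
  # expectation 1000 points for cd3_ct; Poisson 4-sigma band
  n_cd3_ct <- quantify_density(sl, "cd3", "ct") * 2
  expect_lt(abs(n_cd3_ct - 1000), 4 * sqrt(1000))

  zero <- generate_slide(c(cd3_ct = 0, cd8_ct = 0, cd3_im = 0, cd8_im = 0),
                         areas = c(ct = 1, im = 1), seed = 2)
  expect_identical(unname(quantify_quartet(zero)), rep(0, 4))

  no_im <- generate_slide(targets, areas = c(ct = 2, im = 1),
                          im_present = FALSE, seed = 3)
  q <- quantify_quartet(no_im)
  expect_true(all(is.na(q[c("cd3_im", "cd8_im")])))
  expect_true(all(!is.na(q[c("cd3_ct", "cd8_ct")])))

  expect_error(generate_slide(c(cd3_ct = -1, cd8_ct = 0, cd3_im = 0, cd8_im = 0)),
               ">= 0")
  expect_error(generate_slide(targets, areas = c(ct = 0, im = 1)), "positive")
})
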