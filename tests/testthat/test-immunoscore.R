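test_that("midrank percentiles follow the stated convention", {
  expect_equal(empirical_percentile(2, c(1, 2, 3)), 50)
  # boundary: at or below the smallest reference value
  ref <- c(5, 10, 20, 40)
  expect_equal(empirical_percentile(5, ref), 100 * 0.5 / 4)
  expect_lte(empirical_percentile(1, ref), 100 * 0.5 / 4)
  expect_gte(empirical_percentile(1, ref), 0)
  # monotone, and strictly increasing over distinct reference values
  set.seed(31)
  r <- sort(stats::runif(100))
  p <- empirical_percentile(r, r)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 100))
  # ties: all mass at one value
  expect_equal(empirical_percentile(7, rep(7, 10)), 50)
  expect_error(empirical_percentile(1, numeric(0)), "empty")
})

test_that("mean percentile averages the available entries", {
  q <- c(cd3_ct = 10, cd8_ct = 20, cd3_im = 30, cd8_im = 40)
  expect_equal(mean_percentile(q), 25)
  expect_equal(mean_percentile(q[sample(4)]), 25)  # permutation invariance
  ct_only <- c(cd3_ct = 60, cd8_ct = 80, cd3_im = NA, cd8_im = NA)
  expect_equal(mean_percentile(ct_only), 70)
  expect_error(mean_percentile(c(cd3_ct = NA, cd8_ct = 50)), "tumor-center")
})

test_that("category assignment counts high calls with >= at the threshold", {
  th <- fixed_cutoffs(c(cd3_ct = 100, cd8_ct = 100, cd3_im = 100, cd8_im = 100))
  all_low <- assign_categories(c(cd3_ct = 50, cd8_ct = 50, cd3_im = 50, cd8_im = 50), th)
  expect_equal(all_low$is_category, "IS-0")
  expect_equal(all_low$isb_category, "ISb-0")
  all_high <- assign_categories(c(cd3_ct = 150, cd8_ct = 100, cd3_im = 150, cd8_im = 100), th)
  expect_equal(all_high$is_category, "IS-4")  # = threshold counts as high
  expect_equal(all_high$isb_category, "ISb-2")
  mixed <- assign_categories(c(cd3_ct = 150, cd8_ct = 150, cd3_im = 50, cd8_im = 50), th)
  expect_equal(mixed$is_category, "IS-2")
  expect_equal(mixed$isb_category, "ISb-2")
  expect_equal(mixed$is3, "IS-1-2")
  expect_equal(mixed$is2, "IS-0-2")
  expect_equal(mixed$isb2, "ISb-1-2")
  # missing margin: ISb defined, IS unclassified
  biopsy <- assign_categories(c(cd3_ct = 150, cd8_ct = 50, cd3_im = NA, cd8_im = NA), th)
  expect_true(is.na(biopsy$is_category))
  expect_equal(biopsy$isb_category, "ISb-1")
  expect_error(assign_categories(c(cd3_ct = NA, cd8_ct = 50, cd3_im = 1, cd8_im = 1), th),
               "tumor-center")
})

test_that("raising any single density never lowers IS or ISb", {
  th <- fixed_cutoffs(c(cd3_ct = 80, cd8_ct = 120, cd3_im = 60, cd8_im = 200))
  set.seed(42)
  cat_num <- function(s) as.integer(sub(".*-", "", s))
  for (rep in 1:50) {
    q <- stats::setNames(stats::runif(4, 0, 300),
                         c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im"))
    base <- assign_categories(q, th)
    d <- sample(names(q), 1)
    q2 <- q; q2[d] <- q2[d] + stats::runif(1, 0, 200)
    up <- assign_categories(q2, th)
    expect_gte(cat_num(up$is_category), cat_num(base$is_category))
    expect_gte(cat_num(up$isb_category), cat_num(base$isb_category))
    # consistency: at most two of four highs can sit in the margin
    if (cat_num(base$is_category) >= 3)
      expect_gte(cat_num(base$isb_category), 1)
  }
})

test_that("percentiles and categories are invariant under monotone density transforms", {
  set.seed(7)
  x <- stats::rlnorm(60, 5, 1)
  tr <- function(v) log1p(v)^2  # strictly increasing
  expect_equal(empirical_percentile(x, x), empirical_percentile(tr(x), tr(x)))
  th_raw <- fixed_cutoffs(c(cd3_ct = 100, cd8_ct = 100, cd3_im = 100, cd8_im = 100))
  th_tr <- fixed_cutoffs(c(cd3_ct = tr(100), cd8_ct = tr(100),
                           cd3_im = tr(100), cd8_im = tr(100)))
  for (i in 1:20) {
    q <- stats::setNames(stats::rlnorm(4, log(100), 1),
                         c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im"))
    a <- assign_categories(q, th_raw)
    b <- assign_categories(stats::setNames(tr(q), names(q)), th_tr)
    expect_identical(a$is_category, b$is_category)
    expect_identical(a$isb_category, b$isb_category)
  }
})

test_that("slide quantification is counting divided by area", {
  set.seed(9)
  pts <- cbind(x = stats::runif(200, 0, 2), y = stats::runif(200, 0, 1))
  sl <- manual_slide(pts, ct_area = 2)
  expect_equal(quantify_density(sl, "cd3", "ct"), 100)
  expect_equal(quantify_density(sl, "cd8", "ct"), 0)
  expect_true(is.na(quantify_density(sl, "cd3", "im")))
})

test_that("scoring the default synthetic cohort populates every IS and ISb level", {
  sc <- score_cohort(generate_cohort(cohort_config(seed = 1)))$cohort
  expect_setequal(unique(stats::na.omit(sc$is_category)), paste0("IS-", 0:4))
  expect_setequal(unique(sc$isb_category), paste0("ISb-", 0:2))
  expect_true(all(sc$mean_percentile >= 0 & sc$mean_percentile <= 100))
  # unclassified exactly where the margin is missing
  expect_identical(is.na(sc$is_category), is.na(sc$cd3_im))
})
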