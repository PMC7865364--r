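#' Kaplan-Meier estimate with the reporting quantities
#'
#' Product-limit estimate with Greenwood variance and log-log transformed 95%
#' confidence intervals (via [survival::survfit()]), plus the quantities the
#' outcome tables report: the median with its Brookmeyer-Crowley 95% CI
#' (`NA` = "not reached" when the curve never crosses the bound) and the
#' survival rate at requested horizons (3 and 5 years by default).
#'
#' @param times Non-negative follow-up times (months).
#' @param events 0/1 event indicators.
#' @param horizons Months at which to report survival rates.
#' @param conf_level Confidence level.
#' @return Object of class `km_estimate`: `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (Greenwood SE of S), `lower`, `upper`; `median` (list `est`,
#'   `lower`, `upper`, each possibly `NA`); `rates` (data.frame `horizon`,
#'   `rate`, `lower`, `upper`); `n`, `n_events`.
#' @export
km_fit <- function(times, events, horizons = c(36, 60), conf_level = 0.95) {
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0) stop("no observations", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  if (all(times == 0)) stop("all follow-up times are zero", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  med <- stats::quantile(fit, probs = 0.5, conf.int = TRUE)
  s <- summary(fit, times = horizons, extend = TRUE)
  rates <- data.frame(horizon = horizons, rate = s$surv,
                      lower = s$lower, upper = s$upper)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, std_err = fit$std.err * fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 median = list(est = as.numeric(med$quantile)[1],
                               lower = as.numeric(med$lower)[1],
                               upper = as.numeric(med$upper)[1]),
                 rates = rates, n = length(times), n_events = sum(events)),
            class = "km_estimate")
}

#' Stratified Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie handling, stratified by center (so
#' each center keeps its own baseline hazard), on either outcome. Categorical
#' covariates keep an explicit `"Unknown"` level — missing clinical data is an
#' analysis category, not an exclusion — and the stated reference levels carry
#' HR = 1. Reports per-level hazard ratios with Wald CIs and p-values,
#' Harrell's C-index on the linear predictor, and per-covariate joint Wald
#' chi-squared statistics with their shares of the total (the relative
#' importance of each parameter to the survival risk).
#'
#' A separated level (no events in it) is reported with its infinite-HR
#' sentinel (HR 0 or Inf) rather than an error, matching how such rows are
#' printed in multivariable tables.
#'
#' @param cohort A cohort `data.frame` (scored or not).
#' @param outcome `"ttr"` or `"os"`.
#' @param covariates Character vector of cohort column names; each is treated
#'   as a factor. Reference level = first of `ref_levels[[cov]]` if supplied,
#'   else the factor's first level.
#' @param strata Stratification column (default `"center"`); `NULL` for none.
#' @param ref_levels Optional named list of reference levels.
#' @return Object of class `cox_fit`: `terms` (data.frame: `covariate`,
#'   `level`, `ref`, `hr`, `lower`, `upper`, `p_value`), `c_index` (list `est`,
#'   `lower`, `upper`), `chi2` (named per-covariate joint Wald chi-squared),
#'   `chi2_share`, `events`, `n`, `outcome`, and the underlying `fit`.
#' @export
cox_fit <- function(cohort, outcome = c("ttr", "os"), covariates,
                    strata = "center", ref_levels = NULL) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_months"); ecol <- paste0(outcome, "_event")
  dat <- cohort[, c(tcol, ecol, covariates, strata), drop = FALSE]
  names(dat)[1:2] <- c(".time", ".event")
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) == 0) stop("no complete cases for the Cox fit", call. = FALSE)
  for (cv in covariates) {
    if (is.numeric(dat[[cv]])) next  # continuous covariates pass through
    f <- factor(dat[[cv]])
    if (!is.null(ref_levels[[cv]]) && ref_levels[[cv]] %in% levels(f))
      f <- stats::relevel(f, ref_levels[[cv]])
    dat[[cv]] <- f
  }
  # a covariate constant over the analysis set is degenerate: reported with
  # HR 1 / p 1 and zero chi-squared, not fitted
  constant <- covariates[vapply(covariates, function(cv)
    if (is.numeric(dat[[cv]])) stats::var(dat[[cv]]) == 0
    else nlevels(dat[[cv]]) < 2, logical(1))]
  covariates <- setdiff(covariates, constant)
  if (length(covariates) == 0)
    stop("all covariates are constant across patients", call. = FALSE)
  rhs <- paste(sprintf("`%s`", covariates), collapse = " + ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(`", strata, "`)")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  # separation is reported through the 0/Inf hazard-ratio sentinel, so the
  # fitter's "coefficient may be infinite" warning is expected, not actionable
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|beta may be infinite",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (is.null(fit$coefficients)) stop("no estimable coefficients", call. = FALSE)

  cf <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(0.975)
  n_coef <- vapply(covariates, function(cv)
    if (is.numeric(dat[[cv]])) 1L else nlevels(dat[[cv]]) - 1L, integer(1))
  assign_map <- rep(covariates, n_coef)
  lv <- unlist(lapply(covariates, function(cv)
    if (is.numeric(dat[[cv]])) "(per unit)" else levels(dat[[cv]])[-1]))
  refs <- vapply(covariates, function(cv)
    if (is.numeric(dat[[cv]])) "" else levels(dat[[cv]])[1], character(1))
  terms <- data.frame(
    covariate = assign_map, level = lv, ref = refs[assign_map],
    hr = exp(cf), lower = exp(cf - z * se), upper = exp(cf + z * se),
    p_value = 2 * stats::pnorm(-abs(cf / se)),
    degenerate = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (length(constant))
    terms <- rbind(terms, data.frame(
      covariate = constant,
      level = vapply(constant, function(cv)
        if (is.numeric(dat[[cv]])) "(constant)" else levels(dat[[cv]])[1],
        character(1)),
      ref = vapply(constant, function(cv)
        if (is.numeric(dat[[cv]])) "(constant)" else levels(dat[[cv]])[1],
        character(1)),
      hr = 1, lower = NA_real_, upper = NA_real_, p_value = 1,
      degenerate = TRUE, row.names = NULL, stringsAsFactors = FALSE
    ))
  # joint Wald chi-squared per covariate over its levels
  V <- fit$var
  chi2 <- vapply(covariates, function(cv) {
    idx <- which(assign_map == cv)
    b <- cf[idx]
    ok <- is.finite(b)
    if (!any(ok)) return(NA_real_)
    idx <- idx[ok]; b <- b[ok]
    drop(t(b) %*% solve(V[idx, idx, drop = FALSE], b))
  }, numeric(1))
  if (length(constant))
    chi2 <- c(chi2, stats::setNames(rep(0, length(constant)), constant))
  conc <- fit$concordance
  cse <- sqrt(conc["var"])
  c_index <- list(est = unname(conc["concordance"]),
                  lower = unname(conc["concordance"] - z * cse),
                  upper = unname(conc["concordance"] + z * cse))
  structure(list(terms = terms, c_index = c_index,
                 chi2 = chi2, chi2_share = chi2 / sum(chi2, na.rm = TRUE),
                 events = sum(dat$.event), n = nrow(dat),
                 outcome = outcome, fit = fit),
            class = "cox_fit")
}

#' Relative-importance shares from a Cox fit
#'
#' The per-covariate joint Wald chi-squared divided by the sum over all
#' covariates in the model — the "chi-squared proportion" displayed as a pie
#' of each parameter's contribution to the survival risk.
#'
#' @param fit A [cox_fit()] object.
#' @return Named numeric shares in `[0, 1]` summing to 1.
#' @export
chi2_importance <- function(fit) {
  if (!inherits(fit, "cox_fit")) stop("need a cox_fit object", call. = FALSE)
  sh <- fit$chi2 / sum(fit$chi2, na.rm = TRUE)
  sh[is.na(sh)] <- 0
  sh
}

#' Schoenfeld sample-size for a two-group survival comparison
#'
#' Number of events required to detect a hazard ratio `hr` at significance
#' `alpha` with the given power:
#' `d = (z_alpha + z_power)^2 / (p (1 - p) (ln hr)^2)`, with `p` the allocation
#' fraction; the total sample size inflates events by the expected event
#' fraction, `n = ceil(d / event_fraction)`.
#'
#' @param hr Hazard ratio under the alternative (not 1).
#' @param alpha Significance level.
#' @param sided 1 or 2.
#' @param power Target power.
#' @param allocation Fraction of patients in the first group, in (0, 1).
#' @param event_fraction Expected fraction of patients with an event, in (0, 1].
#' @return List `events` (unrounded), `total_n` (integer).
#' @examples
#' schoenfeld_sample_size(hr = 2, alpha = 0.05, sided = 2, power = 0.8)
#' @export
schoenfeld_sample_size <- function(hr, alpha = 0.05, sided = 2, power = 0.9,
                                   allocation = 0.5, event_fraction = 1) {
  if (!is.finite(hr) || hr <= 0 || hr == 1)
    stop("hr must be positive and different from 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  if (allocation <= 0 || allocation >= 1)
    stop("allocation must lie in (0, 1)", call. = FALSE)
  if (event_fraction <= 0 || event_fraction > 1)
    stop("event_fraction must lie in (0, 1]", call. = FALSE)
  if (!sided %in% c(1, 2)) stop("sided must be 1 or 2", call. = FALSE)
  za <- stats::qnorm(1 - alpha / sided)
  zb <- stats::qnorm(power)
  events <- (za + zb)^2 / (allocation * (1 - allocation) * log(hr)^2)
  list(events = events, total_n = as.integer(ceiling(events / event_fraction)))
}
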