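#' Generate a seeded synthetic MIBC cohort
#'
#' Simulates one patient table with the statistical structure the downstream
#' analysis assumes. A latent per-patient immune level `A ~ N(0,1)` drives
#' (i) the four log-densities (shared loading `scale * sqrt(latent_corr)` plus
#' independent noise, giving pairwise correlation `latent_corr` between
#' log-densities), (ii) the probability of pathologic complete response
#' (logistic in the cohort-internal mean density percentile), and (iii) the
#' recurrence hazard (proportional hazards in the immune score level and in
#' nodal status). Overall survival is generated as recurrence time plus an
#' exponential post-recurrence survival, competing with a small background
#' death hazard, so `ttr_months <= os_months` always holds. Each patient has a
#' potential follow-up drawn uniformly on
#' `[dropout_min_months, admin_censor_months]`; both endpoints are censored
#' there. Invasive-margin densities and pCR are masked completely at random at
#' the configured fractions.
#'
#' The immune score level used by the hazard is the generator's own count of
#' the four densities exceeding their configured log-scale medians
#' (`exp(density_location)`); the analysis re-derives scores from the data and
#' never sees this latent truth.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with one row per patient and the documented cohort
#'   CSV columns (see [write_cohort()]): identifiers, covariates (with
#'   `"Unknown"` levels as strings), densities in cells/mm^2 (`cd3_im`/`cd8_im`
#'   `NA` when the margin is missing), `pcr` in `{"yes","no",NA}`, and
#'   `ttr_months`/`ttr_event`, `os_months`/`os_event` in months.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' mean(cohort$gender == "Male")
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  if (n == 0) {
    chr <- character(0); num <- numeric(0); int <- integer(0)
    return(data.frame(
      patient_id = chr, center = chr, gender = chr, age_years = num,
      tobacco = chr, toxic_exposure = chr, prior_bcg = chr, histology = chr,
      t_stage = chr, n_stage = chr, regimen = chr,
      cd3_ct = num, cd8_ct = num, cd3_im = num, cd8_im = num, pcr = chr,
      ttr_months = num, ttr_event = int, os_months = num, os_event = int,
      stringsAsFactors = FALSE
    ))
  }
  withr::with_seed(config$seed, {
    draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    center <- draw(config$center_probs)
    gender <- ifelse(stats::runif(n) < config$p_male, "Male", "Female")
    age <- round(stats::rnorm(n, config$age_mean, config$age_sd), 1)
    tobacco <- draw(config$tobacco_probs)
    toxic <- draw(config$toxic_probs)
    bcg <- draw(config$prior_bcg_probs)
    histology <- draw(config$histology_probs)
    t_stage <- draw(config$t_stage_probs)
    n_stage <- draw(config$n_stage_probs)
    regimen <- draw(config$regimen_probs)

    # latent immune level and correlated log-normal densities
    A <- stats::rnorm(n)
    dens_names <- c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")
    rho <- config$latent_corr
    dens <- vapply(dens_names, function(d) {
      s <- config$density_scale[[d]]
      exp(config$density_location[[d]] +
            s * (sqrt(rho) * A + sqrt(1 - rho) * stats::rnorm(n)))
    }, numeric(n))
    dens <- matrix(dens, nrow = n, dimnames = list(NULL, dens_names))

    # generator-side immune score: densities above their configured medians
    med <- exp(unlist(config$density_location)[dens_names])
    is_level <- rowSums(sweep(dens, 2, med, ">="))

    # pCR: logistic in the cohort-internal mean percentile of the 4 densities
    pct <- vapply(dens_names, function(d) empirical_percentile(dens[, d], dens[, d]),
                  numeric(n))
    mean_pct <- rowMeans(matrix(pct, nrow = n))
    eta <- config$pcr_intercept + config$immune_effect_pcr * (mean_pct / 100 - 0.5)
    pcr_true <- stats::runif(n) < stats::plogis(eta)

    # event times: recurrence, background death, post-recurrence death
    h_rec <- config$baseline_hazard_ttr *
      exp(-config$immune_effect_ttr * is_level +
            config$nplus_loghr_ttr * (n_stage == "N+"))
    t_rec <- stats::rexp(n, h_rec)
    t_death0 <- stats::rexp(n, config$baseline_hazard_os)
    t_post <- stats::rexp(n, config$post_recurrence_hazard)
    t_death <- pmin(t_death0, t_rec + t_post)

    # staggered-accrual administrative censoring
    cens <- stats::runif(n, config$dropout_min_months, config$admin_censor_months)

    ttr_event <- as.integer(t_rec <= pmin(t_death0, cens))
    ttr_months <- pmin(t_rec, t_death0, cens)
    os_event <- as.integer(t_death <= cens)
    os_months <- pmin(t_death, cens)

    # informative-in-name-only missingness: MCAR masks
    dens[stats::runif(n) < config$frac_missing_im, c("cd3_im", "cd8_im")] <- NA_real_
    pcr <- ifelse(pcr_true, "yes", "no")
    pcr[stats::runif(n) < config$frac_missing_pcr] <- NA_character_

    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      center = center, gender = gender, age_years = age,
      tobacco = tobacco, toxic_exposure = toxic, prior_bcg = bcg,
      histology = histology, t_stage = t_stage, n_stage = n_stage,
      regimen = regimen,
      cd3_ct = round(dens[, "cd3_ct"], 2), cd8_ct = round(dens[, "cd8_ct"], 2),
      cd3_im = round(dens[, "cd3_im"], 2), cd8_im = round(dens[, "cd8_im"], 2),
      pcr = pcr,
      ttr_months = round(ttr_months, 2), ttr_event = ttr_event,
      os_months = round(os_months, 2), os_event = os_event,
      stringsAsFactors = FALSE
    )
  })
}
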