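#' Configuration for the synthetic MIBC cohort generator
#'
#' Bundles every parameter of the simulated world: cohort size, recruiting-center
#' mix, log-scale density distributions for CD3/CD8 in tumor center (CT) and
#' invasive margin (IM), the latent correlation tying the four densities to one
#' per-patient immune level, the strength with which that level drives pathologic
#' complete response (pCR) and recurrence hazard, baseline event rates, censoring,
#' and the missingness fractions.
#'
#' Defaults emulate a 117-patient multicenter neoadjuvant-chemotherapy cohort:
#' five centers, 77.8% male, right-skewed (log-normal) densities correlated
#' across markers and regions, ~12% missing invasive margins, ~13.7% missing
#' pCR, pCR probability increasing with the mean density percentile, and
#' recurrence/death hazards decreasing with the immune score level.
#'
#' @param n_patients Number of patients to simulate.
#' @param center_probs Named probability vector over recruiting centers
#'   (must sum to 1, at least 2 centers).
#' @param p_male Probability of male gender.
#' @param age_mean,age_sd Mean and SD of age at diagnosis (years).
#' @param tobacco_probs,toxic_probs,histology_probs,t_stage_probs,n_stage_probs
#'   Named probability vectors over the categorical covariates; an explicit
#'   `"Unknown"` level is a legal analysis category.
#' @param prior_bcg_probs Named probability vector over prior-BCG status.
#' @param regimen_probs Named probability vector over chemotherapy regimens.
#' @param density_location Named numeric: log-scale location (meanlog) of the
#'   four densities, names `cd3_ct`, `cd8_ct`, `cd3_im`, `cd8_im` (cells/mm^2).
#' @param density_scale Named numeric: log-scale SD for the same four entries.
#' @param latent_corr Correlation in `[0, 1)` between any two log-densities,
#'   induced by the shared latent immune level.
#' @param immune_effect_pcr Log-odds of pCR per unit of (mean percentile)/100.
#' @param pcr_intercept Log-odds of pCR at mean percentile 50.
#' @param immune_effect_ttr Log-hazard *reduction* of recurrence per immune
#'   score level (0-4); positive values mean higher scores recur later.
#' @param nplus_loghr_ttr Additive log-hazard of recurrence for N+ vs N0.
#' @param baseline_hazard_ttr Recurrence hazard per month for an IS-0 / N0
#'   patient.
#' @param baseline_hazard_os Hazard per month of death without recurrence.
#' @param post_recurrence_hazard Hazard per month of death after recurrence.
#' @param dropout_min_months Earliest possible dropout/administrative censoring.
#' @param admin_censor_months Administrative censoring horizon (months);
#'   per-patient potential follow-up is uniform on
#'   `[dropout_min_months, admin_censor_months]`, emulating staggered accrual.
#' @param frac_missing_im Probability that the invasive margin is absent from a
#'   specimen (IM densities missing).
#' @param frac_missing_pcr Probability that pCR status is missing from the
#'   pathology report.
#' @param seed Integer seed; the generator is deterministic given the config.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_patients = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_patients = 117,
                          center_probs = c(Lille = 9, HEGP = 20, IMM = 49,
                                           Diaconnesses = 27, Alexandra = 12) / 117,
                          p_male = 91 / 117,
                          age_mean = 66.4,
                          age_sd = 8.2,
                          tobacco_probs = c(No = 27, Yes = 78, Unknown = 12) / 117,
                          toxic_probs = c(No = 75, Yes = 10, Unknown = 32) / 117,
                          prior_bcg_probs = c(No = 93, Yes = 24) / 117,
                          histology_probs = c(UC = 99, Variant = 17, Unknown = 1) / 117,
                          t_stage_probs = c(T2 = 106, `T3-4` = 7, Unknown = 4) / 117,
                          n_stage_probs = c(N0 = 31, `N+` = 77, Unknown = 9) / 117,
                          regimen_probs = c(MVAC = 66, GC = 44, Carboplatin = 3,
                                            OtherPlatinum = 4) / 117,
                          density_location = c(cd3_ct = log(300), cd8_ct = log(150),
                                               cd3_im = log(400), cd8_im = log(200)),
                          density_scale = c(cd3_ct = 1, cd8_ct = 1,
                                            cd3_im = 1, cd8_im = 1),
                          latent_corr = 0.6,
                          immune_effect_pcr = 2.0,
                          pcr_intercept = -1.65,
                          immune_effect_ttr = 0.35,
                          nplus_loghr_ttr = log(2.5),
                          baseline_hazard_ttr = 0.035,
                          baseline_hazard_os = 0.006,
                          post_recurrence_hazard = 0.04,
                          dropout_min_months = 6,
                          admin_censor_months = 96,
                          frac_missing_im = 14 / 117,
                          frac_missing_pcr = 16 / 117,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, center_probs = center_probs, p_male = p_male,
    age_mean = age_mean, age_sd = age_sd,
    tobacco_probs = tobacco_probs, toxic_probs = toxic_probs,
    prior_bcg_probs = prior_bcg_probs, histology_probs = histology_probs,
    t_stage_probs = t_stage_probs, n_stage_probs = n_stage_probs,
    regimen_probs = regimen_probs,
    density_location = density_location, density_scale = density_scale,
    latent_corr = latent_corr,
    immune_effect_pcr = immune_effect_pcr, pcr_intercept = pcr_intercept,
    immune_effect_ttr = immune_effect_ttr, nplus_loghr_ttr = nplus_loghr_ttr,
    baseline_hazard_ttr = baseline_hazard_ttr,
    baseline_hazard_os = baseline_hazard_os,
    post_recurrence_hazard = post_recurrence_hazard,
    dropout_min_months = dropout_min_months,
    admin_censor_months = admin_censor_months,
    frac_missing_im = frac_missing_im, frac_missing_pcr = frac_missing_pcr,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop("invalid cohort_config: ", msg, call. = FALSE)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  stop_if(!num_ok(cfg$n_patients) || length(cfg$n_patients) != 1 ||
            cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients),
          "n_patients must be a non-negative integer")
  for (nm in c("center_probs", "tobacco_probs", "toxic_probs", "prior_bcg_probs",
               "histology_probs", "t_stage_probs", "n_stage_probs", "regimen_probs")) {
    p <- cfg[[nm]]
    stop_if(!num_ok(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8 || is.null(names(p)),
            paste(nm, "must be a named probability vector summing to 1"))
  }
  stop_if(length(cfg$center_probs) < 2, "need at least 2 centers")
  stop_if(!num_ok(cfg$p_male) || cfg$p_male < 0 || cfg$p_male > 1, "p_male must be in [0,1]")
  dens_names <- c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")
  stop_if(!num_ok(cfg$density_location) || !setequal(names(cfg$density_location), dens_names),
          "density_location must be named cd3_ct, cd8_ct, cd3_im, cd8_im")
  stop_if(!num_ok(cfg$density_scale) || !setequal(names(cfg$density_scale), dens_names) ||
            any(cfg$density_scale <= 0),
          "density_scale must be positive and named cd3_ct, cd8_ct, cd3_im, cd8_im")
  stop_if(!num_ok(cfg$latent_corr) || cfg$latent_corr < 0 || cfg$latent_corr >= 1,
          "latent_corr must lie in [0, 1)")
  for (nm in c("baseline_hazard_ttr", "baseline_hazard_os", "post_recurrence_hazard"))
    stop_if(!num_ok(cfg[[nm]]) || cfg[[nm]] <= 0, paste(nm, "must be > 0"))
  for (nm in c("frac_missing_im", "frac_missing_pcr"))
    stop_if(!num_ok(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1,
            paste(nm, "must be in [0,1]"))
  stop_if(!num_ok(cfg$admin_censor_months) || cfg$admin_censor_months <= 0,
          "admin_censor_months must be > 0")
  stop_if(!num_ok(cfg$dropout_min_months) || cfg$dropout_min_months < 0 ||
            cfg$dropout_min_months > cfg$admin_censor_months,
          "dropout_min_months must lie in [0, admin_censor_months]")
  for (nm in c("immune_effect_pcr", "pcr_intercept", "immune_effect_ttr",
               "nplus_loghr_ttr", "age_mean", "age_sd"))
    stop_if(!num_ok(cfg[[nm]]), paste(nm, "must be finite"))
  invisible(cfg)
}
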