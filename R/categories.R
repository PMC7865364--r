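#' Assign Immunoscore categories from a density quartet
#'
#' Each of the four densities (CD3/CD8 x tumor center/invasive margin) is
#' called "high" when it is at or above its threshold (the `>=` convention
#' makes tie handling deterministic). The Immunoscore IS is the count of high
#' calls among all four — IS-0 (both populations low in both localizations)
#' through IS-4 (both elevated in both) — and is unclassified when the
#' invasive margin is missing. The biopsy-adapted ISb counts high calls among
#' the two tumor-center densities only: ISb-0 (both low), ISb-1 (one high),
#' ISb-2 (both high), and is always defined. Collapsed groupings used by the
#' outcome analyses are also filled: `is3` in \{IS-0, IS-1-2, IS-3-4\}, `is2`
#' in \{IS-0-2, IS-3-4\}, `isb2` in \{ISb-0, ISb-1-2\}.
#'
#' @param quartet Named numeric with `cd3_ct`, `cd8_ct` (required) and
#'   `cd3_im`, `cd8_im` (both `NA` when the invasive margin is absent).
#' @param cutoffs A `cutoff_model` (from [optimal_cutoffs()] or
#'   [fixed_cutoffs()]) whose names cover the quartet entries. When the model
#'   is on the percentile scale the quartet must already be percentiles.
#' @return List of class `immunoscore_result`: `high` (named logical calls),
#'   `is_category` (`"IS-0"`..`"IS-4"` or `NA` when unclassified),
#'   `isb_category` (`"ISb-0"`..`"ISb-2"`), and collapsed `is3`, `is2`
#'   (both `NA` when IS is unclassified), `isb2`.
#' @export
assign_categories <- function(quartet, cutoffs) {
  ct <- c("cd3_ct", "cd8_ct")
  im <- c("cd3_im", "cd8_im")
  if (any(is.na(quartet[ct])))
    stop("tumor-center densities must be present", call. = FALSE)
  im_present <- !any(is.na(quartet[im]))
  th <- vapply(cutoffs$cutoffs, `[[`, numeric(1), "threshold")
  need <- if (im_present) c(ct, im) else ct
  if (!all(need %in% names(th)))
    stop("cutoff model lacks thresholds for: ",
         paste(setdiff(need, names(th)), collapse = ", "), call. = FALSE)
  high <- stats::setNames(rep(NA, 4), c(ct, im))
  for (d in need) high[d] <- unname(quartet[d] >= th[d])
  isb_n <- sum(high[ct])
  isb <- paste0("ISb-", isb_n)
  if (im_present) {
    is_n <- sum(high)
    is_cat <- paste0("IS-", is_n)
    is3 <- c("IS-0", "IS-1-2", "IS-1-2", "IS-3-4", "IS-3-4")[is_n + 1]
    is2 <- if (is_n >= 3) "IS-3-4" else "IS-0-2"
  } else {
    is_cat <- NA_character_; is3 <- NA_character_; is2 <- NA_character_
  }
  structure(list(high = high, is_category = is_cat, isb_category = isb,
                 is3 = is3, is2 = is2,
                 isb2 = if (isb_n >= 1) "ISb-1-2" else "ISb-0"),
            class = "immunoscore_result")
}

#' Score a whole cohort
#'
#' Builds the percentile reference from the cohort itself, computes the four
#' percentiles and their mean for every patient, fits (or applies) density
#' cut-offs on the time-to-recurrence outcome, and appends the IS/ISb
#' categories and collapsed groups to the cohort table.
#'
#' @param cohort A cohort `data.frame`.
#' @param cutoffs Optional pre-fitted `cutoff_model`; by default maximally
#'   selected log-rank cut-offs are fitted on TTR via [optimal_cutoffs()].
#' @return List with `cohort` (input plus columns `pct_cd3_ct`, `pct_cd8_ct`,
#'   `pct_cd3_im`, `pct_cd8_im`, `mean_percentile`, `is_category`,
#'   `isb_category`, `is3`, `is2`, `isb2`), `cutoffs` (the `cutoff_model`
#'   used) and `reference` (the `percentile_reference`).
#' @export
score_cohort <- function(cohort, cutoffs = NULL) {
  cohort <- validate_cohort(cohort)
  ref <- percentile_reference(cohort)
  dens_names <- c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")
  for (d in dens_names)
    cohort[[paste0("pct_", d)]] <- empirical_percentile(cohort[[d]], ref[[d]])
  cohort$mean_percentile <- vapply(seq_len(nrow(cohort)), function(i)
    mean_percentile(stats::setNames(
      as.numeric(cohort[i, paste0("pct_", dens_names)]), dens_names)),
    numeric(1))
  if (is.null(cutoffs))
    cutoffs <- optimal_cutoffs(cohort[, dens_names], cohort$ttr_months,
                               cohort$ttr_event)
  scored_cols <- c("is_category", "isb_category", "is3", "is2", "isb2")
  use_pct <- identical(cutoffs$scale, "percentile")
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    q <- if (use_pct)
      stats::setNames(as.numeric(cohort[i, paste0("pct_", dens_names)]), dens_names)
    else
      stats::setNames(as.numeric(cohort[i, dens_names]), dens_names)
    assign_categories(q, cutoffs)
  })
  for (cl in scored_cols)
    cohort[[cl]] <- vapply(res, function(r) r[[cl]][1], character(1))
  list(cohort = cohort, cutoffs = cutoffs, reference = ref)
}
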