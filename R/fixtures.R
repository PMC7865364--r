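#' Patient-level fixture encoding the published response table
#'
#' Builds a deterministic 117-patient cohort whose ISb x pCR and IS x pCR
#' cross-tabulations reproduce, count for count, the published pathologic
#' complete response distribution across Immunoscore categories: ISb margins
#' 34/11/21 (no pCR) and 6/9/19 (pCR) over 100 patients with known response,
#' IS 3-group margins 30/25/7 and 6/12/10 over the 90 of those who also have
#' an invasive margin, 14 patients unclassified for IS overall, and 17 with
#' unknown response. Densities are encoded as 150 ("high") or 50 ("low")
#' against a uniform threshold of 100 cells/mm^2, so [score_cohort()] with
#' `fixed_cutoffs` at 100 regenerates the categories from raw densities.
#'
#' Follow-up columns carry simple deterministic values satisfying the schema
#' invariants; they are placeholders, not study data (no survival quantity of
#' the source tables is patient-level reproducible).
#'
#' @return A cohort `data.frame` (117 rows) passing [validate_cohort()].
#' @export
table2_fixture_cohort <- function() {
  # each block: number of patients, CT high calls, IM high calls (NA = margin
  # absent), pCR ("yes"/"no"/NA). Block design reproduces the published
  # cross-tabs and the overall IS spread 38/21/25/11/8 (+14 unclassified).
  blocks <- list(
    # no pCR (66): 62 IS-classified, 4 margin-missing
    list(30, 0, 0, "no"),   # IS-0 / ISb-0
    list(9, 1, 0, "no"),    # IS-1 / ISb-1
    list(2, 1, 1, "no"),    # IS-2 / ISb-1
    list(14, 2, 0, "no"),   # IS-2 / ISb-2
    list(4, 2, 1, "no"),    # IS-3 / ISb-2
    list(3, 2, 2, "no"),    # IS-4 / ISb-2
    list(4, 0, NA, "no"),   # unclassified / ISb-0
    # pCR (34): 28 IS-classified, 6 margin-missing
    list(6, 0, 0, "yes"),   # IS-0 / ISb-0
    list(6, 1, 0, "yes"),   # IS-1 / ISb-1
    list(6, 2, 0, "yes"),   # IS-2 / ISb-2
    list(6, 2, 1, "yes"),   # IS-3 / ISb-2
    list(4, 2, 2, "yes"),   # IS-4 / ISb-2
    list(3, 1, NA, "yes"),  # unclassified / ISb-1
    list(3, 2, NA, "yes"),  # unclassified / ISb-2
    # pCR unknown (17): 13 IS-classified, 4 margin-missing
    list(2, 0, 0, NA),      # IS-0
    list(6, 1, 0, NA),      # IS-1
    list(3, 2, 0, NA),      # IS-2
    list(1, 2, 1, NA),      # IS-3
    list(1, 2, 2, NA),      # IS-4
    list(1, 0, NA, NA),     # unclassified / ISb-0
    list(1, 1, NA, NA),     # unclassified / ISb-1
    list(2, 2, NA, NA)      # unclassified / ISb-2
  )
  hi <- 150; lo <- 50
  rows <- lapply(blocks, function(b) {
    k <- b[[1]]; ct <- b[[2]]; im <- b[[3]]; pcr <- b[[4]]
    data.frame(
      cd3_ct = rep(if (ct >= 1) hi else lo, k),
      cd8_ct = rep(if (ct >= 2) hi else lo, k),
      cd3_im = rep(if (is.na(im)) NA_real_ else if (im >= 1) hi else lo, k),
      cd8_im = rep(if (is.na(im)) NA_real_ else if (im >= 2) hi else lo, k),
      pcr = rep(if (is.na(pcr)) NA_character_ else pcr, k),
      stringsAsFactors = FALSE
    )
  })
  d <- do.call(rbind, rows)
  n <- nrow(d)
  centers <- c("Lille", "HEGP", "IMM", "Diaconnesses", "Alexandra")
  data.frame(
    patient_id = sprintf("F%04d", seq_len(n)),
    center = centers[(seq_len(n) - 1L) %% 5L + 1L],
    gender = ifelse(seq_len(n) %% 5L == 0L, "Female", "Male"),
    age_years = 55 + (seq_len(n) %% 25),
    tobacco = "Yes", toxic_exposure = "No", prior_bcg = "No",
    histology = "UC", t_stage = "T2", n_stage = "N0", regimen = "MVAC",
    d[, c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")],
    pcr = d$pcr,
    ttr_months = 6 + (seq_len(n) %% 48),
    ttr_event = seq_len(n) %% 2L,
    os_months = 9 + (seq_len(n) %% 48),
    os_event = as.integer(seq_len(n) %% 3L == 0L),
    stringsAsFactors = FALSE
  )
}

#' Hand-checkable 6-subject survival example
#'
#' Times 1, 2+, 3, 4+, 5, 6 (`+` censored). The product-limit estimate is
#' 5/6 after t = 1, then 5/6 x 3/4 = 0.625 after t = 3, 0.625 x 1/2 = 0.3125
#' after t = 5, and 0 after t = 6.
#'
#' @return data.frame with `time` and `event`.
#' @export
km_hand_example <- function() {
  data.frame(time = 1:6, event = c(1L, 0L, 1L, 0L, 1L, 1L))
}

#' Write the packaged fixtures to a directory
#'
#' Writes (a) `table2_cohort.csv`, the patient-level encoding of the published
#' response table; (b) `km_hand.csv`, the 6-subject hand-worked survival
#' example; (c) `synthetic_cohort_default.csv`, the default seeded synthetic
#' cohort. Regeneration with the same seed is byte-identical.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Seed for the synthetic cohort.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 20210128) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table2 = file.path(outdir, "table2_cohort.csv"),
    km_hand = file.path(outdir, "km_hand.csv"),
    synthetic = file.path(outdir, "synthetic_cohort_default.csv")
  )
  write_cohort(table2_fixture_cohort(), paths[["table2"]])
  utils::write.csv(km_hand_example(), paths[["km_hand"]], row.names = FALSE)
  write_cohort(generate_cohort(cohort_config(seed = seed)), paths[["synthetic"]])
  invisible(paths)
}
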