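#' Midrank empirical percentile against a reference cohort
#'
#' Converts a density to its percentile in a reference distribution using the
#' midrank convention: `100 * (#\{r < x\} + 0.5 * #\{r = x\}) / n`. Symmetric,
#' stable under ties, and monotone non-decreasing in `x`. For `ref = c(1,2,3)`
#' and `x = 2` the result is 50.
#'
#' @param x Numeric vector of densities to convert (`NA` passes through).
#' @param ref Non-empty numeric reference vector (the analysis cohort itself in
#'   the default single-cohort design).
#' @return Percentiles in `[0, 100]`, same length as `x`.
#' @export
empirical_percentile <- function(x, ref) {
  ref <- sort(ref[!is.na(ref)])
  if (length(ref) == 0) stop("empty percentile reference", call. = FALSE)
  n <- length(ref)
  leq <- findInterval(x, ref)                     # #{r <= x}
  less <- findInterval(x, ref, left.open = TRUE)  # #{r <  x}
  out <- 100 * (less + 0.5 * (leq - less)) / n
  out[is.na(x)] <- NA_real_
  out
}

#' Build the per-marker, per-region percentile reference of a cohort
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]).
#' @return Object of class `percentile_reference`: list of four sorted density
#'   vectors named `cd3_ct`, `cd8_ct`, `cd3_im`, `cd8_im` (IM vectors use only
#'   specimens with an invasive margin).
#' @export
percentile_reference <- function(cohort) {
  ref <- lapply(cohort[, c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")],
                function(v) sort(v[!is.na(v)]))
  if (any(lengths(ref) == 0)) stop("empty percentile reference", call. = FALSE)
  structure(ref, class = "percentile_reference")
}

#' Mean of the available density percentiles
#'
#' The continuous immune covariate: the arithmetic mean of the four percentiles
#' when the invasive margin is present, and of the two tumor-center percentiles
#' otherwise. At least the two CT percentiles must be present.
#'
#' @param percentiles Named numeric with entries `cd3_ct`, `cd8_ct` and
#'   optionally `cd3_im`, `cd8_im` (IM entries may be `NA`).
#' @return Mean percentile in `[0, 100]`.
#' @export
mean_percentile <- function(percentiles) {
  ct <- percentiles[c("cd3_ct", "cd8_ct")]
  if (any(is.na(ct))) stop("both tumor-center percentiles are required", call. = FALSE)
  mean(percentiles[!is.na(percentiles)])
}
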