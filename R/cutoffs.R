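#' Maximally selected log-rank cut-off search
#'
#' Implements the "optimal cut-off" determination for dichotomizing a density:
#' for each marker x region, every observed unique density between the 10th and
#' 90th percentile is tried as a threshold (high = density >= threshold), the
#' two-group log-rank statistic on the outcome (time to recurrence in the
#' study design) is standardized, and the threshold maximizing its absolute
#' value is selected. Ties in the maximal statistic are broken toward the
#' threshold nearest the median density, which guards against boundary
#' artifacts. The grid restriction to `[q10, q90]` avoids unstable extreme
#' splits.
#'
#' The selected p-value is *not* reported here: a maximally selected statistic
#' has an inflated null distribution and the threshold is treated as a scoring
#' rule, not a test.
#'
#' @param densities Named list (or data.frame columns) of density vectors, one
#'   per marker x region, e.g. `cd3_ct`, `cd8_ct`, `cd3_im`, `cd8_im`; `NA`
#'   entries (missing invasive margins) are dropped pairwise with their times.
#' @param times,events Outcome follow-up times (months) and 0/1 event flags.
#' @param min_events Minimum number of events required (default 20).
#' @return Object of class `cutoff_model`: per density a list with `threshold`
#'   (cells/mm^2), `grid` and `statistic` (the |z| trace), plus `scale =
#'   "density"`.
#' @seealso [assign_categories()] to apply the thresholds, [cutoffs_json()] to
#'   serialize the model.
#' @export
optimal_cutoffs <- function(densities, times, events, min_events = 20) {
  densities <- as.list(densities)
  if (sum(events, na.rm = TRUE) < min_events)
    stop("need at least ", min_events, " events to fit cut-offs", call. = FALSE)
  fits <- lapply(densities, function(x) maxsel_logrank(x, times, events))
  structure(list(cutoffs = fits, scale = "density"), class = "cutoff_model")
}

# single-variable maximally selected log-rank search
maxsel_logrank <- function(x, times, events) {
  keep <- !is.na(x) & !is.na(times) & !is.na(events)
  x <- x[keep]; times <- times[keep]; events <- events[keep]
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("degenerate density distribution", call. = FALSE)
  if (sum(events) == 0) stop("no events: cannot select a survival cut-off", call. = FALSE)
  qs <- stats::quantile(x, c(0.1, 0.9), type = 1)
  grid <- ux[ux >= qs[[1]] & ux <= qs[[2]]]
  grid <- grid[grid > min(ux)]           # 'high' group must be a proper subset
  if (length(grid) == 0) grid <- ux[ux > min(ux)][1]
  zs <- vapply(grid, function(c) logrank_z(times, events, x >= c), numeric(1))
  best <- which(abs(zs) == max(abs(zs)))
  if (length(best) > 1) {                # tie: prefer threshold nearest median
    med <- stats::median(x)
    best <- best[which.min(abs(grid[best] - med))]
  }
  list(threshold = grid[best], grid = grid, statistic = abs(zs))
}

#' Serialize / restore a cut-off model
#'
#' The fitted thresholds, candidate grids and statistic traces round-trip
#' through JSON so that scoring is reproducible across runs (and so a fixed
#' external reference can be supplied instead of refitting).
#'
#' @param model A `cutoff_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `cutoffs_json()`: the JSON string (invisibly when written to file);
#'   `cutoffs_from_json()`: the restored `cutoff_model`.
#' @export
cutoffs_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname cutoffs_json
#' @param json JSON string or file path produced by [cutoffs_json()].
#' @export
cutoffs_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  obj$cutoffs <- lapply(obj$cutoffs, as.list)
  structure(obj, class = "cutoff_model")
}

#' Construct a cut-off model from fixed thresholds
#'
#' @param thresholds Named numeric thresholds (cells/mm^2), names matching the
#'   density columns they dichotomize.
#' @param scale `"density"` (raw cells/mm^2) or `"percentile"`.
#' @return A `cutoff_model`.
#' @export
fixed_cutoffs <- function(thresholds, scale = c("density", "percentile")) {
  scale <- match.arg(scale)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("thresholds must be finite and > 0", call. = FALSE)
  fits <- lapply(as.list(thresholds), function(th)
    list(threshold = th, grid = th, statistic = NA_real_))
  structure(list(cutoffs = fits, scale = scale), class = "cutoff_model")
}
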