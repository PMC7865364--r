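#' Log-rank test
#'
#' Standard log-rank comparison of survival between groups. With two groups the
#' result carries the signed standardized statistic
#' `z = (O1 - E1) / sqrt(V1)` (group 1 = second factor level), which the
#' maximally selected cut-off search consumes; with more than two groups the
#' test delegates to [survival::survdiff()].
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List of class `imscore_test`: `statistic` (chi-squared), `df`,
#'   `p_value`, `method`, and for two groups `z` (signed).
#' @export
logrank_test <- function(times, events, group) {
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]; group <- group[keep]
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs at least two groups", call. = FALSE)
  if (all(times == 0)) stop("all follow-up times are zero", call. = FALSE)
  if (nlevels(g) == 2) {
    z <- logrank_z(times, events, g == levels(g)[2])
    res <- list(statistic = z^2, df = 1L,
                p_value = stats::pchisq(z^2, 1, lower.tail = FALSE),
                z = z, method = "log-rank")
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ g)
    df <- nlevels(g) - 1L
    res <- list(statistic = unname(sd$chisq), df = df,
                p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                z = NA_real_, method = "log-rank")
  }
  class(res) <- "imscore_test"
  res
}

# Signed standardized two-group log-rank statistic. `in_group` is logical;
# the sign is positive when the flagged group has more events than expected.
logrank_z <- function(times, events, in_group) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]; in_group <- in_group[ord]
  n <- length(times)
  # at-risk counts just before each ordered time
  at_risk <- n - seq_len(n) + 1L
  at_risk1 <- rev(cumsum(rev(as.integer(in_group))))
  first <- !duplicated(times)
  tid <- cumsum(first)                       # distinct-time index per row
  dj <- as.vector(rowsum(as.numeric(events), tid))
  d1j <- as.vector(rowsum(as.numeric(events & in_group), tid))
  nj <- at_risk[first]
  n1j <- at_risk1[first]
  keep <- dj > 0
  dj <- dj[keep]; d1j <- d1j[keep]; nj <- nj[keep]; n1j <- n1j[keep]
  O1 <- sum(d1j)
  E1 <- sum(dj * n1j / nj)
  vterm <- ifelse(nj > 1,
                  dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1), 0)
  V1 <- sum(vterm)
  if (V1 <= 0) return(0)
  (O1 - E1) / sqrt(V1)
}
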