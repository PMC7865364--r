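#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test conditioning on both margins. The p-value is the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (with a relative
#' tolerance of 1e-7 to absorb floating-point ties) — the convention of
#' mainstream statistical software, so printed study p-values reproduce to
#' 4 decimal places.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive margins.
#' @return List of class `imscore_test` with `p_value`, `method`, `margins`.
#' @examples
#' fisher_exact_2x2(matrix(c(34, 32, 6, 28), 2))$p_value  # 0.0012
#' @export
fisher_exact_2x2 <- function(table) {
  table <- check_counts(table, 2, 2)
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1, 1], m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(p_value = p, method = "Fisher exact (2x2)",
                 margins = table_margins(table)),
            class = "imscore_test")
}

#' Freeman-Halton exact test for an RxC table
#'
#' Exact generalization of Fisher's test: all non-negative integer tables with
#' the observed row and column margins are enumerated, each is assigned its
#' multivariate hypergeometric probability
#' `prod(r_i!) * prod(c_j!) / (N! * prod(n_ij!))`, and the p-value is the sum
#' of probabilities not exceeding the observed one (relative tolerance 1e-7).
#' Enumeration is guarded by `max_tables`; past the guard an error instructs
#' the seeded Monte-Carlo fallback, which samples margin-fixed tables with
#' [stats::r2dtable()] (Patefield's algorithm) and reports the estimate with
#' its standard error.
#'
#' @param table RxC matrix of non-negative integer counts with positive margins.
#' @param max_tables Enumeration budget (default 1e6 tables).
#' @param monte_carlo Use the Monte-Carlo estimate instead of enumeration.
#' @param B Number of Monte-Carlo tables.
#' @param seed Seed for the Monte-Carlo sampler.
#' @return List of class `imscore_test` with `p_value`, `method`, `margins`,
#'   `n_tables` (enumeration) or `mc_se` (Monte-Carlo).
#' @examples
#' fisher_exact_rxc(matrix(c(34, 11, 21, 6, 9, 19), 3))$p_value  # 0.0035
#' @export
fisher_exact_rxc <- function(table, max_tables = 1e6, monte_carlo = FALSE,
                             B = 1e5, seed = 1L) {
  # a zero row/column margin is tolerated here: those cells are forced to zero
  # in every attainable table (a single nonzero column gives p = 1)
  table <- check_counts(table, 2, 2, allow_zero_margin = TRUE)
  r <- rowSums(table); cs <- colSums(table)
  logp_obs <- log_mhg_prob(table, r, cs)
  tol <- logp_obs + log1p(1e-7)
  if (monte_carlo) {
    p <- withr::with_seed(as.integer(seed), {
      hits <- vapply(stats::r2dtable(B, r, cs),
                     function(tb) log_mhg_prob(tb, r, cs) <= tol, logical(1))
      (1 + sum(hits)) / (B + 1)
    })
    return(structure(list(p_value = p, method = "Freeman-Halton (Monte-Carlo)",
                          mc_se = sqrt(p * (1 - p) / B),
                          margins = table_margins(table)),
                     class = "imscore_test"))
  }
  env <- new.env()
  env$p <- 0; env$count <- 0
  enumerate_tables(r, cs, function(tb) {
    env$count <- env$count + 1
    if (env$count > max_tables)
      stop("enumeration budget exceeded (", format(max_tables, scientific = FALSE),
           " tables); rerun with monte_carlo = TRUE for a seeded estimate",
           call. = FALSE)
    lp <- log_mhg_prob(tb, r, cs)
    if (lp <= tol) env$p <- env$p + exp(lp)
  })
  structure(list(p_value = min(1, env$p), method = "Freeman-Halton exact",
                 n_tables = env$count, margins = table_margins(table)),
            class = "imscore_test")
}

# log multivariate hypergeometric probability of a margin-fixed table
log_mhg_prob <- function(tb, r = rowSums(tb), cs = colSums(tb)) {
  sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(r) + 1) -
    sum(lgamma(tb + 1))
}

# depth-first enumeration of all non-negative integer tables with margins (r, cs),
# calling `fun` on each completed table; prunes branches that cannot close.
enumerate_tables <- function(r, cs, fun) {
  R <- length(r); C <- length(cs)
  tb <- matrix(0L, R, C)
  fill_row <- function(i, col_left) {
    if (i == R) {                       # last row forced by column margins
      if (any(col_left < 0)) return()
      tb[R, ] <<- col_left
      fun(tb)
      return()
    }
    fill_cell <- function(j, row_left, col_left) {
      if (j == C) {                     # last cell of the row forced
        if (row_left > col_left[C]) return()
        tb[i, C] <<- row_left
        col_left[C] <- col_left[C] - row_left
        fill_row(i + 1, col_left)
        return()
      }
      for (v in 0:min(row_left, col_left[j])) {
        tb[i, j] <<- v
        cl <- col_left; cl[j] <- cl[j] - v
        fill_cell(j + 1, row_left - v, cl)
      }
    }
    fill_cell(1, r[i], col_left)
  }
  fill_row(1, cs)
  invisible(NULL)
}

check_counts <- function(table, min_r, min_c, allow_zero_margin = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < min_r || ncol(table) < min_c)
    stop("table must be at least ", min_r, "x", min_c, call. = FALSE)
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("degenerate margin", call. = FALSE)
  if (!allow_zero_margin &&
      (any(rowSums(table) == 0) || any(colSums(table) == 0)))
    stop("degenerate margin", call. = FALSE)
  storage.mode(table) <- "integer"
  table
}

table_margins <- function(table) {
  list(rows = rowSums(table), cols = colSums(table), total = sum(table))
}

#' Two-sample t-test on immune densities
#'
#' Compares the densities of one lymphocyte population between two clinical
#' categories. `variant = "student"` pools the variances (the classical
#' two-sample t); `variant = "welch"` uses the unequal-variance form. Two-sided.
#' If both groups are constant the test degenerates: p = 1 for equal means and
#' p = 0 (flagged) for unequal means.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param variant `"student"` (default) or `"welch"`.
#' @return List of class `imscore_test` with `statistic`, `p_value`, `method`,
#'   `degenerate` flag.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(statistic = if (eq) 0 else Inf,
                          p_value = if (eq) 1 else 0,
                          method = paste0("t-test (", variant, ")"),
                          degenerate = TRUE),
                     class = "imscore_test"))
  }
  tt <- stats::t.test(a, b, var.equal = variant == "student")
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 method = paste0("t-test (", variant, ")"), degenerate = FALSE),
            class = "imscore_test")
}

#' Cross-tabulate two cohort variables
#'
#' Counts patients with both values observed (complete-case per test, which is
#' why e.g. an IS x pCR table can have a smaller total than an ISb x pCR table
#' on the same cohort) and records how many were excluded.
#'
#' @param cohort A cohort `data.frame`.
#' @param row_var,col_var Names of categorical columns.
#' @param row_levels,col_levels Optional explicit level orders.
#' @return List of class `contingency_table`: `counts` (matrix), `n_excluded`,
#'   `row_var`, `col_var`.
#' @export
crosstab <- function(cohort, row_var, col_var,
                     row_levels = NULL, col_levels = NULL) {
  rv <- cohort[[row_var]]; cv <- cohort[[col_var]]
  if (is.null(rv) || is.null(cv))
    stop("variables not found in cohort", call. = FALSE)
  keep <- !is.na(rv) & !is.na(cv)
  if (!any(keep)) stop("empty contingency table: no complete cases", call. = FALSE)
  rf <- if (is.null(row_levels)) factor(rv[keep]) else factor(rv[keep], row_levels)
  cf <- if (is.null(col_levels)) factor(cv[keep]) else factor(cv[keep], col_levels)
  counts <- unclass(table(rf, cf))
  dimnames(counts) <- list(levels(rf), levels(cf))
  structure(list(counts = counts, n_excluded = sum(!keep),
                 row_var = row_var, col_var = col_var),
            class = "contingency_table")
}
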