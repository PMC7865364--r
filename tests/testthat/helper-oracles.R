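# Independent oracles and simulation helpers shared across tests.

# Brute-force exact RxC p-value: enumerate every non-negative integer table
# with the observed margins by nested loops over the (R-1) x (C-1) free cells,
# score each with the multivariate hypergeometric probability computed from
# binomial coefficients (a different code path from the package's
# lgamma-in-log-space enumeration), and sum probabilities <= observed.
brute_force_exact_p <- function(tab, tol = 1e-7) {
  tab <- as.matrix(tab)
  r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  # P(table) = prod_j [ multichoose(c_j over column cells) ] / multichoose(N over rows)
  prob_of <- function(m) {
    num <- prod(vapply(seq_along(cs), function(j) {
      p <- 1; left <- cs[j]
      for (i in seq_along(r)) { p <- p * choose(left, m[i, j]); left <- left - m[i, j] }
      p
    }, numeric(1)))
    den <- {
      p <- 1; left <- N
      for (i in seq_along(r)) { p <- p * choose(left, r[i]); left <- left - r[i] }
      p
    }
    num / den
  }
  p_obs <- prob_of(tab)
  R <- length(r); C <- length(cs)
  free <- expand.grid(rep(list(0:max(r)), (R - 1) * (C - 1)))
  total <- 0
  for (k in seq_len(nrow(free))) {
    m <- matrix(0, R, C)
    m[seq_len(R - 1), seq_len(C - 1)] <- as.numeric(free[k, ])
    m[seq_len(R - 1), C] <- r[seq_len(R - 1)] - rowSums(m[seq_len(R - 1), , drop = FALSE])
    m[R, ] <- cs - colSums(m)
    if (any(m < 0)) next
    pk <- prob_of(m)
    if (pk <= p_obs * (1 + tol)) total <- total + pk
  }
  total
}

# random contingency table with strictly positive margins
random_table <- function(nmax = 30, dims = c(2, 2)) {
  repeat {
    N <- sample(4:nmax, 1)
    cells <- as.vector(stats::rmultinom(1, N, rep(1, prod(dims))))
    tab <- matrix(cells, dims[1], dims[2])
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# two-arm exponential survival sample
sim_two_arm <- function(n_per_arm, lambda1, lambda2, censor = Inf) {
  t1 <- stats::rexp(n_per_arm, lambda1)
  t2 <- stats::rexp(n_per_arm, lambda2)
  times <- c(t1, t2)
  data.frame(times = pmin(times, censor),
             events = as.integer(times <= censor),
             group = rep(c("a", "b"), each = n_per_arm))
}

# density-changepoint survival sample: densities on a 25 cells/mm^2 lattice,
# hazard drops by factor `hr` at and above the changepoint
sim_changepoint <- function(n = 500, changepoint = 500, hr = 3,
                            lambda_low = 0.05, censor = 60) {
  x <- 25 * sample(4:40, n, replace = TRUE)
  lam <- ifelse(x >= changepoint, lambda_low / hr, lambda_low)
  t <- stats::rexp(n, lam)
  data.frame(x = x, times = pmin(t, censor), events = as.integer(t <= censor))
}

# minimal synthetic slide built by hand (counting oracle for quantify_density)
manual_slide <- function(ct_points, im_points = NULL, ct_area = 2, im_area = 1) {
  masks <- list(ct = list(xmin = 0, xmax = 2, ymin = 0, ymax = ct_area / 2,
                          area = ct_area))
  if (!is.null(im_points))
    masks$im <- list(xmin = 0, xmax = 2, ymin = ct_area / 2,
                     ymax = ct_area / 2 + im_area / 2, area = im_area)
  pts <- rbind(ct_points, im_points)
  structure(list(masks = masks,
                 points = list(cd3 = pts, cd8 = pts[0, , drop = FALSE]),
                 im_present = !is.null(im_points)),
            class = "synthetic_slide")
}
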