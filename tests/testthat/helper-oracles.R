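# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: the spline oracle solves the natural-spline
# tridiagonal system directly, the REML oracle evaluates the closed-form
# gaussian criterion on a dense grid, and the BH oracle applies the
# step-up definition literally.

# natural cubic spline interpolation through (knots, yk), evaluated at x
ncs_interp_oracle <- function(knots, yk, x) {
  k <- length(knots)
  h <- diff(knots)
  # solve tridiagonal system for interior second derivatives m_2..m_{k-1}
  m <- k - 2
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  for (i in seq_len(m)) {
    A[i, i] <- (h[i] + h[i + 1]) / 3
    if (i > 1) A[i, i - 1] <- h[i] / 6
    if (i < m) A[i, i + 1] <- h[i + 1] / 6
    rhs[i] <- (yk[i + 2] - yk[i + 1]) / h[i + 1] - (yk[i + 1] - yk[i]) / h[i]
  }
  m2 <- c(0, solve(A, rhs), 0)
  vapply(x, function(xx) {
    j <- max(1, min(k - 1, findInterval(xx, knots, rightmost.closed = TRUE)))
    hj <- h[j]
    dl <- knots[j + 1] - xx
    dr <- xx - knots[j]
    dl * yk[j] / hj + dr * yk[j + 1] / hj +
      ((dl^3 / hj - hj * dl) * m2[j] + (dr^3 / hj - hj * dr) * m2[j + 1]) / 6
  }, 0)
}

# closed-form gaussian REML criterion (phi profiled) for an intercept +
# one penalized block design; returns the criterion on a log10(lambda) grid
reml_grid_oracle <- function(X, S0, pen_idx, y, grid = seq(-8, 8, by = 0.05)) {
  n <- nrow(X); p <- ncol(X)
  ev <- eigen(S0, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev > max(ev) * 1e-10
  rk <- sum(pos); ldS0 <- sum(log(ev[pos]))
  Mp <- p - rk
  vapply(grid, function(l10) {
    lam <- 10^l10
    Sl <- matrix(0, p, p)
    Sl[pen_idx, pen_idx] <- lam * S0
    H <- crossprod(X) + Sl
    b <- solve(H, crossprod(X, y))
    P <- sum((y - X %*% b)^2) + drop(t(b) %*% Sl %*% b)
    phi <- P / (n - Mp)
    -P / (2 * phi) - (n - Mp) / 2 * log(2 * pi * phi) +
      (rk * log(lam) + ldS0) / 2 -
      as.numeric(determinant(H, logarithm = TRUE)$modulus) / 2
  }, 0)
}

# literal Benjamini-Hochberg step-up: reject H_(1..k*) where k* is the
# largest k with p_(k) <= k/m alpha; adjusted p_i is the smallest alpha at
# which i would be rejected
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  vapply(seq_len(m), function(i) {
    ri <- which(o == i)   # rank of p_i
    # smallest alpha rejecting i: min over k >= rank(i) of m p_(k) / k
    min(1, min(m * p[o][ri:m] / (ri:m)))
  }, 0)
}

# paper-design dataset from an explicit log-scale truth (thin wrapper
# to keep test bodies short)
paper_design_sim <- function(g, d = 0, seed = 1, noise_cv = 0.10,
                             shift = 0, replicates = 3) {
  simulate_for_recovery(g, d, days = 1:20, replicates = replicates,
                        intercept = log(50), shift = shift,
                        noise_cv = noise_cv, seed = seed)
}

# single-smooth gaussian spec on a replicated daily design
gaussian_smooth_spec <- function(tvec, k = 10) {
  bs <- cr_basis(tvec, k = k)
  cb <- center_basis(bs, tvec)
  Xp <- matrix(1, length(tvec), 1, dimnames = list(NULL, "(Intercept)"))
  gam_model_spec(Xp, list(gam_smooth("s_t", cb, tvec)), family = "gaussian")
}
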