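test_that("gaussian fit at lambda ~ 0 equals the OLS solution", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 40
    t <- sort(runif(n, 1, 20))
    y <- rnorm(n, cos(t / 4), 0.6)
    spec <- gaussian_smooth_spec(t, k = 8)
    fit <- pirls_fit(spec, y, 0)
    bols <- qr.coef(qr(spec$X), y)
    expect_lt(max(abs(fit$coefficients - bols)), 1e-8)
  }
})

test_that("gamma/log fitted means are strictly positive", {
  set.seed(52)
  t <- rep(1:20, each = 3)
  y <- exp(sin(t / 3)) * rgamma(length(t), 50, 50)
  bs <- cr_basis(t, 10); cb <- center_basis(bs, t)
  spec <- gam_model_spec(matrix(1, length(t), 1, dimnames = list(NULL, "I")),
                         list(gam_smooth("s_t", cb, t)), family = "gamma")
  fit <- optimize_reml(spec, y)
  expect_gt(min(fit$fitted), 0)
  expect_error(pirls_fit(spec, c(-1, y[-1]), 1), "strictly positive")
})

test_that("huge lambda forces an affine fit and e.d.f. 1", {
  set.seed(53)
  t <- rep(1:20, each = 3)
  y <- rnorm(length(t), sin(t / 2), 0.4)
  spec <- gaussian_smooth_spec(t, k = 10)
  fit <- pirls_fit(spec, y, 1e8)
  line <- lm.fit(cbind(1, t), fit$fitted)
  expect_lt(max(abs(fit$fitted - line$fitted.values)), 1e-4 * sd(y))
  expect_equal(fit$edf[["s_t"]], 1, tolerance = 0.01)
})

test_that("e.d.f. limits and trace additivity hold", {
  set.seed(54)
  t <- rep(1:20, each = 3)
  y <- rnorm(length(t), sin(t / 2), 0.4)
  spec <- gaussian_smooth_spec(t, k = 10)
  fit0 <- pirls_fit(spec, y, 0)
  expect_equal(fit0$edf[["s_t"]], 9, tolerance = 1e-8)  # basis dimension
  # trace additivity: smooth e.d.f. + parametric count = total
  for (lam in c(0, 1, 1e4)) {
    fit <- pirls_fit(spec, y, lam)
    expect_equal(sum(fit$edf) + spec$n_par, fit$edf_total, tolerance = 1e-8)
    expect_gt(fit$edf[["s_t"]], 0)
    expect_lte(fit$edf[["s_t"]], 9 + 1e-8)
  }
})

test_that("e.d.f. is monotone non-increasing along a lambda ladder", {
  set.seed(55)
  t <- rep(1:20, each = 3)
  y <- rnorm(length(t), sin(t / 2), 0.4)
  spec <- gaussian_smooth_spec(t, k = 10)
  edfs <- vapply(10^seq(-6, 6, by = 1),
                 function(l) pirls_fit(spec, y, l)$edf[["s_t"]], 0)
  expect_true(all(diff(edfs) <= 1e-10))
})

test_that("gaussian REML fit is scale equivariant", {
  set.seed(56)
  t <- rep(1:20, each = 3)
  y <- rnorm(length(t), sin(t / 2) + 2, 0.4)
  spec <- gaussian_smooth_spec(t, k = 10)
  f1 <- optimize_reml(spec, y)
  f2 <- optimize_reml(spec, 100 * y)
  expect_equal(f2$fitted, 100 * f1$fitted, tolerance = 1e-6)
  expect_equal(f2$edf[["s_t"]], f1$edf[["s_t"]], tolerance = 1e-6)
})

test_that("permuting observation order leaves the fit unchanged", {
  set.seed(57)
  t <- rep(1:20, each = 3)
  y <- exp(0.5 + sin(t / 3)) * rgamma(length(t), 100, 100)
  perm <- sample(length(t))
  mkspec <- function(tt) {
    bs <- cr_basis(tt, 10); cb <- center_basis(bs, tt)
    gam_model_spec(matrix(1, length(tt), 1, dimnames = list(NULL, "I")),
                   list(gam_smooth("s_t", cb, tt)), family = "gamma")
  }
  f1 <- pirls_fit(mkspec(t), y, 3)
  f2 <- pirls_fit(mkspec(t[perm]), y[perm], 3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$edf, f2$edf, tolerance = 1e-10)
  expect_equal(approx_pvalue(f1, "s_t")$p_value,
               approx_pvalue(f2, "s_t")$p_value, tolerance = 1e-10)
})

test_that("approximate p-values are probabilities and bands are ordered", {
  set.seed(58)
  t <- rep(1:20, each = 3)
  spec <- gaussian_smooth_spec(t, k = 10)
  for (rep in 1:5) {
    y <- rnorm(length(t), 0.2 * rep * sin(t / 3), 0.5)
    fit <- optimize_reml(spec, y)
    pv <- approx_pvalue(fit, "s_t")
    expect_gte(pv$p_value, 0)
    expect_lte(pv$p_value, 1)
    b <- confidence_band(fit, "s_t", seq(1, 20, by = 0.5))
    expect_true(all(b$lower <= b$estimate & b$estimate <= b$upper))
    expect_true(all(b$se >= 0))
  }
})

test_that("quadrupling replicates narrows the band on average", {
  set.seed(59)
  wins <- 0L
  for (i in 1:50) {
    g <- function(t) sin(t / 3)
    t1 <- rep(1:20, each = 3); t4 <- rep(1:20, each = 12)
    y1 <- rnorm(length(t1), g(t1), 0.3)
    y4 <- rnorm(length(t4), g(t4), 0.3)
    b1 <- confidence_band(optimize_reml(gaussian_smooth_spec(t1), y1), "s_t", 1:20)
    b4 <- confidence_band(optimize_reml(gaussian_smooth_spec(t4), y4), "s_t", 1:20)
    if (mean(b4$upper - b4$lower) < mean(b1$upper - b1$lower)) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("residual diagnostics behave for well-specified models", {
  set.seed(60)
  t <- rep(1:20, each = 3)
  # gaussian: Pearson residuals sum to ~0 with an intercept in the model
  spec <- gaussian_smooth_spec(t, k = 10)
  fit <- optimize_reml(spec, rnorm(length(t), sin(t / 2), 0.4))
  expect_lt(abs(mean(residual_diagnostics(fit)$pearson)), 1e-8)
  # gamma with constant CV: heteroscedasticity screen mostly quiet
  bs <- cr_basis(t, 10); cb <- center_basis(bs, t)
  gspec <- gam_model_spec(matrix(1, length(t), 1, dimnames = list(NULL, "I")),
                          list(gam_smooth("s_t", cb, t)), family = "gamma")
  quiet <- 0L
  for (i in 1:100) {
    y <- exp(1 + sin(t / 3)) * rgamma(length(t), 100, 100)
    rd <- residual_diagnostics(optimize_reml(gspec, y))
    if (rd$hetero_p > 0.05) quiet <- quiet + 1L
  }
  expect_gte(quiet, 80L)
})

test_that("saturated gaussian fit interpolates (deviance ~ 0)", {
  set.seed(61)
  t <- 1:12                       # distinct times, k = n
  y <- rnorm(12, sin(t), 0.5)
  spec <- gaussian_smooth_spec(t, k = 12)
  fit <- pirls_fit(spec, y, 0)
  expect_lt(fit$deviance, 1e-6)
})
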