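#' Define a smooth term for a GAM model specification
#'
#' A smooth term couples a centred spline basis with the observation times
#' it is evaluated at, and optionally a 0/1 `by` indicator that zeroes the
#' basis rows for one group.  With a `by` indicator the term becomes a
#' treatment-specific ("differential") smoother: it contributes to treated
#' observations only, and identifiability against the treatment factor is
#' ensured by centering the basis over the treated design times.
#'
#' @param name term label.
#' @param basis a `centered_basis` from [center_basis()].
#' @param times numeric vector of observation times (length n).
#' @param by optional 0/1 numeric vector of length n.
#' @return an object of class `gam_smooth`.
#' @export
gam_smooth <- function(name, basis, times, by = NULL) {
  stopifnot(inherits(basis, "centered_basis"))
  if (!is.null(by)) {
    if (length(by) != length(times))
      stop("'by' must have one value per observation", call. = FALSE)
    if (!all(by %in% c(0, 1)))
      stop("'by' indicator must contain only 0 and 1", call. = FALSE)
  }
  structure(list(name = name, basis = basis, times = times, by = by),
            class = "gam_smooth")
}

#' Assemble a GAM model specification
#'
#' Builds the full design matrix (parametric columns followed by one block
#' per smooth term), the block-embedded penalty matrices, and per-term
#' bookkeeping.  Supported families are gaussian with identity link and
#' Gamma with log link; for both, the iteratively-reweighted-least-squares
#' working weights are identically 1, which the fitting code exploits.
#'
#' @param parametric numeric matrix (or data.frame) of parametric columns
#'   with column names, e.g. intercept and treatment indicator.
#' @param smooths list of [gam_smooth()] terms.
#' @param family `"gaussian"` (identity link) or `"gamma"` (log link).
#' @return an object of class `gam_spec`.
#' @export
gam_model_spec <- function(parametric, smooths = list(),
                           family = c("gaussian", "gamma")) {
  family <- match.arg(family)
  Xp <- as.matrix(parametric)
  if (is.null(colnames(Xp)))
    colnames(Xp) <- paste0("par", seq_len(ncol(Xp)))
  n <- nrow(Xp)
  blocks <- list(Xp)
  term_idx <- list()
  p0 <- ncol(Xp)
  off <- p0
  S_emb <- list()
  s_rank <- numeric(0)
  s_ldet <- numeric(0)
  for (sm in smooths) {
    stopifnot(inherits(sm, "gam_smooth"))
    Xs <- eval_centered(sm$basis, sm$times)
    if (!is.null(sm$by)) Xs <- Xs * sm$by
    if (nrow(Xs) != n) stop("smooth term row count mismatch", call. = FALSE)
    q <- ncol(Xs)
    colnames(Xs) <- paste0(sm$name, ".", seq_len(q))
    blocks[[length(blocks) + 1L]] <- Xs
    idx <- off + seq_len(q)
    term_idx[[sm$name]] <- idx
    off <- off + q
    Sj <- sm$basis$penalty
    ev <- eigen(Sj, symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-10
    s_rank <- c(s_rank, sum(pos))
    s_ldet <- c(s_ldet, sum(log(ev[pos])))
    S_emb[[sm$name]] <- Sj
  }
  X <- do.call(cbind, blocks)
  structure(list(X = X, XtX = crossprod(X), n = n, p = ncol(X),
                 n_par = p0, par_names = colnames(Xp),
                 smooths = smooths,
                 term_idx = term_idx,
                 S_emb = S_emb, s_rank = s_rank, s_ldet = s_ldet,
                 family = family),
            class = "gam_spec")
}

# total penalty matrix at given lambda, full p x p
.penalty_total <- function(spec, lambda) {
  Sl <- matrix(0, spec$p, spec$p)
  nm <- names(spec$term_idx)
  for (j in seq_along(nm)) {
    idx <- spec$term_idx[[nm[j]]]
    Sl[idx, idx] <- Sl[idx, idx] + lambda[j] * spec$S_emb[[nm[j]]]
  }
  Sl
}

.gamma_deviance <- function(y, mu) 2 * sum(-log(y / mu) + (y - mu) / mu)

#' Penalized IRLS fit at fixed smoothing parameters
#'
#' Maximises the penalized log-likelihood of a [gam_model_spec()] at fixed
#' smoothing parameters.  For the gaussian/identity family this is a single
#' penalized least-squares solve; for Gamma/log it iterates on the working
#' response `z = eta + (y - mu)/mu` (working weights are 1 for this family)
#' until the relative deviance change falls below `1e-8`.
#'
#' @param spec a `gam_spec`.
#' @param y response vector (strictly positive for the Gamma family).
#' @param lambda numeric vector of smoothing parameters, one per smooth.
#' @return an object of class `fitted_gam`; see Details.
#' @details The returned object carries coefficients, fitted means, linear
#'   predictor, per-term and total effective degrees of freedom, dispersion
#'   (residual-variance estimator for gaussian, Pearson estimator for
#'   Gamma, both on `n - total e.d.f.` denominator), the Bayesian posterior
#'   covariance `Vb = phi * (X'WX + S_lambda)^{-1}`, deviance, and a
#'   convergence record.
#' @export
pirls_fit <- function(spec, y, lambda = numeric(0)) {
  stopifnot(inherits(spec, "gam_spec"))
  nsm <- length(spec$term_idx)
  if (length(lambda) != nsm)
    stop(sprintf("need %d smoothing parameter(s), got %d", nsm,
                 length(lambda)), call. = FALSE)
  if (length(y) != spec$n) stop("response length mismatch", call. = FALSE)
  if (any(!is.finite(y))) stop("response must be finite", call. = FALSE)
  if (spec$family == "gamma" && any(y <= 0))
    stop(sprintf("Gamma family requires strictly positive response; offending rows: %s",
                 paste(utils::head(which(y <= 0), 20), collapse = ", ")),
         call. = FALSE)
  X <- spec$X
  Sl <- .penalty_total(spec, lambda)
  H <- spec$XtX + Sl
  R <- tryCatch(chol(H), error = function(e)
    stop("penalized design is rank deficient; cannot factorise X'WX + S",
         call. = FALSE))
  solveH <- function(v) backsolve(R, forwardsolve(t(R), v))

  trace <- numeric(0)
  if (spec$family == "gaussian") {
    z <- y
    beta <- solveH(crossprod(X, z))
    eta <- drop(X %*% beta)
    mu <- eta
    dev <- sum((y - mu)^2)
    trace <- dev
    iter <- 1L
    converged <- TRUE
  } else {
    mu <- y
    eta <- log(mu)
    dev <- .gamma_deviance(y, mu)
    converged <- FALSE
    iter <- 0L
    beta <- NULL
    while (iter < 200L) {
      iter <- iter + 1L
      z <- eta + (y - mu) / mu
      beta_new <- solveH(crossprod(X, z))
      eta_new <- drop(X %*% beta_new)
      # step-halving guard against overshoot of the log link
      step <- 1
      repeat {
        eta_try <- if (is.null(beta)) eta_new else eta + step * (eta_new - eta)
        mu_try <- exp(pmin(pmax(eta_try, -700), 700))
        dev_try <- .gamma_deviance(y, mu_try)
        if (is.finite(dev_try) || step < 1e-8) break
        step <- step / 2
      }
      beta <- if (step == 1) beta_new else (1 - step) * (if (is.null(beta)) beta_new else beta) + step * beta_new
      eta <- eta_try; mu <- mu_try
      trace <- c(trace, dev_try)
      if (is.finite(dev_try) && abs(dev_try - dev) < 1e-8 * (abs(dev_try) + 0.1)) {
        dev <- dev_try
        converged <- TRUE
        break
      }
      dev <- dev_try
    }
    if (!converged) {
      cond <- simpleError("PIRLS failed to converge in 200 iterations")
      cond$trace <- trace
      stop(cond)
    }
    z <- eta + (y - mu) / mu
  }

  Hinv <- chol2inv(R)
  Fdiag <- rowSums(Hinv * spec$XtX)   # diag of (X'WX + S)^{-1} X'WX
  edf_term <- vapply(spec$term_idx, function(idx) sum(Fdiag[idx]), 0)
  edf_total <- sum(Fdiag)
  resdf <- spec$n - edf_total
  phi <- if (spec$family == "gaussian") {
    sum((y - mu)^2) / max(resdf, 1e-8)
  } else {
    sum(((y - mu) / mu)^2) / max(resdf, 1e-8)
  }
  P <- sum((z - eta)^2) + drop(crossprod(beta, Sl %*% beta))
  structure(list(
    spec = spec, y = y, coefficients = drop(beta), lambda = lambda,
    eta = eta, fitted = mu, deviance = dev,
    edf = edf_term, edf_total = edf_total, residual_df = resdf,
    phi = phi, Vb = phi * Hinv, Hinv = Hinv, chol_H = R,
    penalized_ss = P, working = z,
    converged = converged, iterations = iter, trace = trace,
    boundary = FALSE, reml = NA_real_),
    class = "fitted_gam")
}

# Laplace-approximate restricted likelihood of the converged working model.
# Gaussian: exact REML of y ~ N(X beta, phi I) with improper prior on the
# penalty null space, phi profiled out.  Gamma: same expression applied to
# the converged PIRLS working response (performance-iteration REML).
.reml_score <- function(spec, y, lambda) {
  fit <- pirls_fit(spec, y, lambda)
  n <- spec$n
  Mp <- spec$p - sum(spec$s_rank)
  P <- fit$penalized_ss
  phi <- max(P / (n - Mp), 1e-300)
  ldetH <- 2 * sum(log(diag(fit$chol_H)))
  ldetS <- sum(spec$s_rank * log(lambda) + spec$s_ldet)
  score <- -P / (2 * phi) - (n - Mp) / 2 * log(2 * pi * phi) +
    ldetS / 2 - ldetH / 2
  list(score = score, fit = fit)
}

#' REML selection of smoothing parameters
#'
#' Chooses smoothing parameters to maximise the Laplace-approximate
#' restricted likelihood: for gaussian models the exact REML criterion of
#' the working mixed model (with dispersion profiled out); for Gamma models
#' the same criterion evaluated on the converged PIRLS working model
#' (performance iteration).  The search runs two sweeps of coordinate-wise
#' golden-section/Brent optimisation of `log10(lambda)` on `[-8, 8]`,
#' followed by a joint Nelder-Mead polish when there is more than one
#' smooth.  A smoothing parameter ending within numerical reach of the box
#' bound is flagged in the returned fit's `boundary` field.
#'
#' @param spec a `gam_spec` with at least the parametric block.
#' @param y response vector.
#' @return a `fitted_gam` (see [pirls_fit()]) with the achieved criterion
#'   in `$reml` and the selected parameters in `$lambda`.
#' @export
optimize_reml <- function(spec, y) {
  nsm <- length(spec$term_idx)
  if (nsm == 0L) return(pirls_fit(spec, y, numeric(0)))
  l10 <- rep(0, nsm)
  obj <- function(v) .reml_score(spec, y, 10^v)$score
  coarse <- seq(-8, 8, by = 0.5)
  for (sweep in 1:2) {
    for (j in seq_len(nsm)) {
      f1 <- function(x) { v <- l10; v[j] <- x; obj(v) }
      if (sweep == 1) {
        # the criterion can be multimodal in log10(lambda): bracket the
        # global maximum on a coarse grid before the Brent refinement
        sc <- vapply(coarse, f1, 0)
        jb <- which.max(sc)
        iv <- coarse[c(max(jb - 1L, 1L), min(jb + 1L, length(coarse)))]
      } else {
        iv <- c(max(l10[j] - 1, -8), min(l10[j] + 1, 8))
      }
      op <- stats::optimize(f1, interval = iv, maximum = TRUE, tol = 1e-4)
      l10[j] <- if (f1(op$maximum) >= f1(l10[j])) op$maximum else l10[j]
    }
  }
  if (nsm >= 2) {
    nm <- stats::optim(l10, function(v) -obj(pmin(pmax(v, -8), 8)),
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-8, maxit = 200))
    cand <- pmin(pmax(nm$par, -8), 8)
    if (-nm$value >= obj(l10)) l10 <- cand
  } else {
    op <- stats::optimize(function(x) obj(x),
                          interval = pmin(pmax(c(l10 - 0.5, l10 + 0.5), -8), 8),
                          maximum = TRUE, tol = 1e-6)
    if (op$objective >= obj(l10)) l10 <- op$maximum
  }
  sc <- .reml_score(spec, y, 10^l10)
  fit <- sc$fit
  fit$reml <- sc$score
  fit$boundary <- any(abs(l10) > 8 - 1e-3)
  fit
}

#' Per-term effective degrees of freedom
#'
#' The e.d.f. of each smooth is the sum of the diagonal entries of
#' `F = (X'WX + S_lambda)^{-1} X'WX` over that term's coefficient indices.
#' A value near 1 for a centred cubic regression smooth indicates an almost
#' linear fitted relationship; larger values indicate nonlinearity, up to
#' the basis dimension when the penalty vanishes.
#'
#' @param fit a `fitted_gam`.
#' @return named numeric vector of smooth-term e.d.f. values.
#' @export
edf_per_term <- function(fit) {
  stopifnot(inherits(fit, "fitted_gam"))
  fit$edf
}

#' Approximate significance test for a smooth term
#'
#' Wald-type statistic `f' V_f^- f` where `f` is the term evaluated at the
#' distinct design times of its support and `V_f^-` is the rank-`r`
#' eigen-pseudo-inverse of the term's posterior covariance there, with
#' `r = max(1, round(e.d.f.))`.  The statistic is referred to a
#' chi-squared(`r`) distribution for gaussian fits, and to `F(r, n - total
#' e.d.f.)` for Gamma fits (dispersion estimated).  These p-values are
#' approximate: the reference distribution ignores smoothing-parameter
#' estimation.
#'
#' @param fit a `fitted_gam`.
#' @param term name of a smooth term in the fit.
#' @return list with `p_value`, `statistic`, `rank` (reference dof),
#'   `edf`, and `degenerate` flag (p is `NA` when the term covariance is
#'   numerically null).
#' @export
approx_pvalue <- function(fit, term) {
  stopifnot(inherits(fit, "fitted_gam"))
  idx <- fit$spec$term_idx[[term]]
  if (is.null(idx)) stop(sprintf("no smooth term '%s' in fit", term),
                         call. = FALSE)
  sm <- NULL
  for (s in fit$spec$smooths) if (s$name == term) sm <- s
  tt <- if (is.null(sm$by)) sm$times else sm$times[sm$by == 1]
  grid <- sort(unique(tt))
  Xg <- eval_centered(sm$basis, grid)
  f <- drop(Xg %*% fit$coefficients[idx])
  Vf <- Xg %*% fit$Vb[idx, idx, drop = FALSE] %*% t(Xg)
  eg <- eigen((Vf + t(Vf)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-10
  npos <- sum(pos)
  edf <- fit$edf[[term]]
  if (npos == 0 || !is.finite(edf)) {
    return(list(p_value = NA_real_, statistic = NA_real_, rank = NA_integer_,
                edf = edf, degenerate = TRUE))
  }
  r <- min(max(1L, as.integer(round(edf))), npos)
  u <- crossprod(eg$vectors[, seq_len(r), drop = FALSE], f)
  stat <- sum(u^2 / eg$values[seq_len(r)])
  p <- if (fit$spec$family == "gaussian") {
    stats::pchisq(stat, df = r, lower.tail = FALSE)
  } else {
    stats::pf(stat / r, r, max(fit$residual_df, 1), lower.tail = FALSE)
  }
  list(p_value = p, statistic = stat, rank = r, edf = edf,
       degenerate = FALSE)
}

#' Pointwise credible band for a smooth term
#'
#' Returns the estimated smooth and a pointwise 95% band,
#' `estimate +/- 1.96 SE`, on the linear-predictor scale, using the
#' Bayesian posterior covariance of the coefficients restricted to the
#' term.  Grid points outside the knot range are evaluated by linear
#' extrapolation and flagged.
#'
#' @param fit a `fitted_gam`.
#' @param term smooth-term name.
#' @param grid numeric vector of times.
#' @param level coverage level of the band (default 0.95).
#' @return data.frame with columns `time`, `estimate`, `se`, `lower`,
#'   `upper`, `extrapolated`.
#' @export
confidence_band <- function(fit, term, grid, level = 0.95) {
  stopifnot(inherits(fit, "fitted_gam"))
  idx <- fit$spec$term_idx[[term]]
  if (is.null(idx)) stop(sprintf("no smooth term '%s' in fit", term),
                         call. = FALSE)
  sm <- NULL
  for (s in fit$spec$smooths) if (s$name == term) sm <- s
  Xg <- eval_centered(sm$basis, grid)
  est <- drop(Xg %*% fit$coefficients[idx])
  se <- sqrt(pmax(rowSums((Xg %*% fit$Vb[idx, idx, drop = FALSE]) * Xg), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = grid, estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se,
             extrapolated = attr(Xg, "extrapolated"))
}

#' Residual diagnostics for a fitted GAM
#'
#' Returns deviance and Pearson residuals, fitted values, a normal-QQ
#' summary of the deviance residuals, and a heteroscedasticity screen: the
#' slope (with p-value) of a plain linear regression of `|Pearson
#' residual|` on fitted value.
#'
#' @param fit a `fitted_gam`.
#' @return list with `fitted`, `pearson`, `deviance_residuals`,
#'   `qq_correlation`, `hetero_slope`, `hetero_p`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "fitted_gam"))
  y <- fit$y; mu <- fit$fitted
  if (fit$spec$family == "gaussian") {
    pearson <- y - mu
    devres <- y - mu
  } else {
    pearson <- (y - mu) / mu
    di <- 2 * (-log(y / mu) + (y - mu) / mu)
    devres <- sign(y - mu) * sqrt(pmax(di, 0))
  }
  sr <- sort(devres)
  qn <- stats::qnorm(stats::ppoints(length(sr)))
  qqcor <- if (stats::sd(sr) > 0) stats::cor(sr, qn) else NA_real_
  hfit <- stats::lm(abs(pearson) ~ mu)
  cf <- summary(hfit)$coefficients
  slope <- if (nrow(cf) >= 2) cf[2, 1] else NA_real_
  pval <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
  list(fitted = mu, pearson = pearson, deviance_residuals = devres,
       qq_correlation = qqcor, hetero_slope = slope, hetero_p = pval)
}

#' @export
print.fitted_gam <- function(x, ...) {
  cat(sprintf("GAM fit (%s family), n = %d\n", x$spec$family, x$spec$n))
  cat(sprintf("  deviance %.6g, dispersion %.6g, total e.d.f. %.3f\n",
              x$deviance, x$phi, x$edf_total))
  if (length(x$edf)) {
    for (nm in names(x$edf))
      cat(sprintf("  s(%s): e.d.f. %.3f  log10(lambda) %.2f\n",
                  nm, x$edf[[nm]], log10(x$lambda[[match(nm, names(x$spec$term_idx))]])))
  }
  if (x$boundary) cat("  note: a smoothing parameter hit its search bound\n")
  invisible(x)
}
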