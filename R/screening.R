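#' Pivot a long time-course table to a samples-by-metabolites matrix
#'
#' Rows are samples (group x day x replicate), columns are metabolites.
#' Every cell must be present exactly once.
#'
#' @param data long-format data.frame (`metabolite`, `day`, `replicate`,
#'   `group`, `concentration`).
#' @return numeric matrix with row names `group.day.replicate` and a
#'   `"sample_info"` attribute (data.frame of group/day/replicate).
#' @export
pivot_wide <- function(data) {
  d <- as.data.frame(data)
  mets <- sort(unique(as.character(d$metabolite)))
  info <- unique(d[, c("group", "day", "replicate")])
  info <- info[order(info$group, info$day, info$replicate), , drop = FALSE]
  rownames(info) <- NULL
  skey <- paste(info$group, info$day, info$replicate, sep = ".")
  dkey <- paste(d$group, d$day, d$replicate, sep = ".")
  M <- matrix(NA_real_, nrow(info), length(mets),
              dimnames = list(skey, mets))
  ij <- cbind(match(dkey, skey), match(as.character(d$metabolite), mets))
  if (anyDuplicated(ij))
    stop("duplicate (metabolite, day, replicate, group) observations",
         call. = FALSE)
  M[ij] <- d$concentration
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)
    stop(sprintf("missing cells after pivot, e.g. %s x %s",
                 rownames(M)[miss[1, 1]], colnames(M)[miss[1, 2]]),
         call. = FALSE)
  }
  attr(M, "sample_info") <- info
  M
}

#' Autoscale a samples-by-variables matrix
#'
#' Mean-centres each column and scales it to unit standard deviation
#' (denominator `n - 1`), the standard pretreatment before PCA when
#' variables have very different magnitudes.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape, each column with mean 0 and sd 1.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  zero <- which(sds < .Machine$double.eps^0.5 * pmax(abs(colMeans(x)), 1))
  if (length(zero) > 0)
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(x)[zero], collapse = ", ")), call. = FALSE)
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of an autoscaled matrix
#'
#' Singular value decomposition based PCA.  Loadings are orthonormal;
#' variance explained by component i is `100 * sigma_i^2 / sum(sigma^2)`.
#' For a reproducible orientation, each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param x numeric matrix, expected autoscaled (a warning is given if
#'   column means are visibly nonzero).
#' @param n_components number of components to return (default all).
#' @return list with `scores` (samples x components), `loadings`
#'   (variables x components, orthonormal), `variance_explained`
#'   (percentages over *all* components, summing to 100).
#' @export
pca_screen <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  r <- min(dim(x))
  if (is.null(n_components)) n_components <- r
  if (n_components > r)
    stop(sprintf("n_components (%d) exceeds min(dim) = %d",
                 n_components, r), call. = FALSE)
  if (max(abs(colMeans(x))) > 1e-6)
    warning("input does not look mean-centred; autoscale() it first")
  sv <- svd(x)
  varexp <- 100 * sv$d^2 / sum(sv$d^2)
  flip <- vapply(seq_len(n_components), function(i) {
    v <- sv$v[, i]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_components)], n_components),
                  2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings, variance_explained = varexp)
}

#' Pearson correlation matrix with pairwise p-values
#'
#' Pearson r for every column pair, with two-sided p-values from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.  Constant columns yield `NA` correlations and are flagged.
#'
#' @param x numeric matrix with at least 3 rows.
#' @return list with `r` (correlations, unit diagonal), `p` (p-values, NA
#'   on the diagonal), `n`, and `constant_columns`.
#' @export
correlation_screen <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows for correlation p-values",
                  call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  const <- colnames(x)[sds == 0]
  suppressWarnings(r <- stats::cor(x))
  r[is.nan(r)] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  list(r = r, p = p, n = n, constant_columns = const)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values (NA allowed, passed through).
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}

#' Per-timepoint Welch tests with FDR correction
#'
#' The pointwise comparator to the trend model: at each day, a Welch
#' two-sample t-test of treated vs control concentrations, with
#' Benjamini-Hochberg adjustment across days and a significance flag at
#' adjusted p below `alpha` (default 0.01).  Days where either group has
#' fewer than 2 replicates are reported as `NA`, not dropped.
#'
#' @param data long-format data.frame.
#' @param metabolite response label.
#' @param alpha FDR significance level.
#' @return data.frame with one row per day: `day`, `n_control`,
#'   `n_treated`, `mean_control`, `mean_treated`, `t`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
pointwise_tests <- function(data, metabolite, alpha = 0.01) {
  d <- as.data.frame(data)
  d <- d[d$metabolite == metabolite, , drop = FALSE]
  if (nrow(d) == 0)
    stop(sprintf("metabolite '%s' not found in data", metabolite),
         call. = FALSE)
  days <- sort(unique(d$day))
  rows <- lapply(days, function(dy) {
    xc <- d$concentration[d$day == dy & d$group == "control"]
    xt <- d$concentration[d$day == dy & d$group == "treated"]
    base <- data.frame(day = dy, n_control = length(xc),
                       n_treated = length(xt),
                       mean_control = if (length(xc)) mean(xc) else NA_real_,
                       mean_treated = if (length(xt)) mean(xt) else NA_real_)
    if (length(xc) < 2 || length(xt) < 2) {
      cbind(base, t = NA_real_, df = NA_real_, p = NA_real_)
    } else if (stats::sd(c(xc - mean(xc), xt - mean(xt))) == 0) {
      # degenerate: all values equal within groups
      cbind(base, t = 0, df = length(xc) + length(xt) - 2,
            p = if (mean(xc) == mean(xt)) 1 else 0)
    } else {
      tt <- stats::t.test(xt, xc, var.equal = FALSE)
      cbind(base, t = unname(tt$statistic), df = unname(tt$parameter),
            p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Compare the trend-model and pointwise analyses for one metabolite
#'
#' Runs [fit_trend_model()] and [pointwise_tests()] on the same response
#' and reports, side by side, which days are pointwise-significant (BH at
#' `alpha`) and at which days the differential smoother's band excludes
#' zero.  On smooth-divergence data the pointwise analysis is typically
#' sparser and more erratic than the trend-level one.
#'
#' @inheritParams fit_trend_model
#' @param alpha FDR level for the pointwise tests (default 0.01).
#' @return object of class `trend_comparison`: `trend` (the `trend_fit`),
#'   `pointwise` (test table), `days_pointwise_significant`,
#'   `days_band_excludes_zero`, and their counts.
#' @export
compare_gam_vs_pointwise <- function(data, metabolite, k = 10,
                                     family = c("gamma", "gaussian-log"),
                                     alpha = 0.01,
                                     elicitation_day = NA_real_) {
  family <- match.arg(family)
  tf <- fit_trend_model(data, metabolite, k = k, family = family,
                        elicitation_day = elicitation_day)
  pw <- pointwise_tests(data, metabolite, alpha = alpha)
  bd <- tf$differential$band
  excl <- bd$time[bd$lower > 0 | bd$upper < 0]
  sig <- pw$day[pw$significant]
  structure(list(trend = tf, pointwise = pw,
                 days_pointwise_significant = sig,
                 days_band_excludes_zero = excl,
                 n_pointwise_significant = length(sig),
                 n_band_excludes_zero = length(excl),
                 alpha = alpha), class = "trend_comparison")
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat(sprintf("Trend vs pointwise comparison for %s\n", x$trend$response))
  cat(sprintf("  pointwise BH-significant days (alpha = %g): %d [%s]\n",
              x$alpha, x$n_pointwise_significant,
              paste(x$days_pointwise_significant, collapse = ", ")))
  cat(sprintf("  days where differential band excludes 0: %d [%s]\n",
              x$n_band_excludes_zero,
              paste(x$days_band_excludes_zero, collapse = ", ")))
  invisible(x)
}
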