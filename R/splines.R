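#' Cubic regression spline basis with second-derivative penalty
#'
#' Constructs a cubic regression spline basis of dimension `k` with knots at
#' quantiles of the distinct sampling times.  The basis is parameterised by
#' the function values at the knots: a coefficient vector is interpreted as
#' the natural cubic spline interpolating those values, and the penalty
#' matrix is the exact integral of the squared second derivative of that
#' interpolant.  Consequently the penalty is symmetric positive
#' semi-definite with rank `k - 2`; its null space is spanned by the
#' constant and linear functions.
#'
#' Evaluation outside the knot range extrapolates linearly (natural spline
#' behaviour) and is flagged by [eval_basis()].
#'
#' @param times numeric vector of sampling times (days); duplicates allowed,
#'   knots are placed on the distinct values only.
#' @param k basis dimension (number of knots), at least 3 and at most the
#'   number of distinct times.
#' @return an object of class `cr_basis` with components `knots`, `k`,
#'   `penalty` (k x k), and the internal second-derivative map `F_full`.
#' @examples
#' bs <- cr_basis(1:20, k = 10)
#' X <- eval_basis(bs, seq(1, 20, by = 0.5))
#' @export
cr_basis <- function(times, k = 10) {
  if (!is.numeric(times) || any(!is.finite(times)))
    stop("'times' must be finite numeric values", call. = FALSE)
  ut <- sort(unique(times))
  if (k < 3) stop("basis dimension k must be at least 3", call. = FALSE)
  if (length(ut) < k)
    stop(sprintf("cannot place %d knots on %d distinct times; reduce k",
                 k, length(ut)), call. = FALSE)
  knots <- as.numeric(stats::quantile(ut, probs = seq(0, 1, length.out = k),
                                      type = 7, names = FALSE))
  if (any(diff(knots) <= 0)) {
    # quantiles collided; fall back to evenly spaced order statistics
    knots <- ut[unique(round(seq(1, length(ut), length.out = k)))]
    if (length(knots) < k)
      stop("distinct times too clustered to place k distinct knots",
           call. = FALSE)
  }
  h <- diff(knots)
  m <- k - 2L
  # D maps knot values to second-difference contrasts; B is the tridiagonal
  # Gram matrix of the second-derivative hat functions.  F = B^{-1} D maps
  # knot values to second derivatives at interior knots (natural spline:
  # zero at the boundary knots); S = D' B^{-1} D is the exact penalty.
  D <- matrix(0, m, k)
  B <- matrix(0, m, m)
  for (i in seq_len(m)) {
    D[i, i]     <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < m) B[i, i + 1] <- B[i + 1, i] <- h[i + 1] / 6
  }
  Fmap <- solve(B, D)
  S <- crossprod(D, Fmap)
  S <- (S + t(S)) / 2
  structure(list(knots = knots, k = k, penalty = S,
                 F_full = rbind(0, Fmap, 0)),
            class = "cr_basis")
}

#' Evaluate a cubic regression spline basis
#'
#' Returns the basis matrix (rows = evaluation points, columns = basis
#' functions) of a [cr_basis()].  Points outside the knot range are handled
#' by linear extrapolation from the nearest boundary knot and recorded in
#' the `"extrapolated"` attribute.
#'
#' @param basis a `cr_basis` object.
#' @param t numeric vector of evaluation times.
#' @param deriv 0 for function values, 1 for first derivatives.
#' @return numeric matrix `length(t)` x `k` with attribute `extrapolated`,
#'   a logical vector flagging out-of-range points.
#' @export
eval_basis <- function(basis, t, deriv = 0L) {
  stopifnot(inherits(basis, "cr_basis"))
  if (any(!is.finite(t))) stop("evaluation times must be finite", call. = FALSE)
  kn <- basis$knots
  k <- basis$k
  lo <- kn[1]; hi <- kn[k]
  out <- t < lo | t > hi
  tc <- pmin(pmax(t, lo), hi)
  X <- .cr_rows(basis, tc, deriv = deriv)
  if (deriv == 0L && any(out)) {
    # linear extension: f(t) = f(b) + (t - b) f'(b) at the nearer boundary
    Xd <- .cr_rows(basis, tc[out], deriv = 1L)
    X[out, ] <- X[out, , drop = FALSE] + (t[out] - tc[out]) * Xd
  } else if (deriv == 1L && any(out)) {
    X[out, ] <- .cr_rows(basis, tc[out], deriv = 1L)
  }
  attr(X, "extrapolated") <- out
  X
}

# basis rows for points inside the knot range
.cr_rows <- function(basis, t, deriv = 0L) {
  kn <- basis$knots
  k <- basis$k
  Ff <- basis$F_full
  j <- findInterval(t, kn, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), k - 1L)
  h <- kn[j + 1L] - kn[j]
  dl <- kn[j + 1L] - t      # distance to right knot
  dr <- t - kn[j]           # distance to left knot
  if (deriv == 0L) {
    am <- dl / h
    ap <- dr / h
    cm <- (dl^3 / h - h * dl) / 6
    cp <- (dr^3 / h - h * dr) / 6
  } else {
    am <- -1 / h
    ap <- 1 / h
    cm <- (-3 * dl^2 / h + h) / 6
    cp <- (3 * dr^2 / h - h) / 6
  }
  X <- matrix(0, length(t), k)
  idx <- seq_along(t)
  X[cbind(idx, j)] <- X[cbind(idx, j)] + am
  X[cbind(idx, j + 1L)] <- X[cbind(idx, j + 1L)] + ap
  X <- X + cm * Ff[j, , drop = FALSE] + cp * Ff[j + 1L, , drop = FALSE]
  X
}

#' Absorb a sum-to-zero constraint into a spline basis
#'
#' Reparameterises a [cr_basis()] so that every basis column, evaluated at
#' the supplied design times, sums to zero.  This makes a smooth term
#' identifiable alongside an intercept (or a treatment factor, for a
#' treatment-specific smoother centred over the treated observations only).
#' The penalty is transformed congruently; the constrained dimension is
#' `k - 1`.
#'
#' @param basis a `cr_basis` object.
#' @param design_times numeric vector of times over which centering is
#'   enforced (the observation times the term applies to).
#' @return an object of class `centered_basis`: `parent`, `transform`
#'   (k x (k-1) constraint null-space basis), `penalty` ((k-1) x (k-1)),
#'   `design_times`.
#' @export
center_basis <- function(basis, design_times) {
  stopifnot(inherits(basis, "cr_basis"))
  X <- eval_basis(basis, design_times)
  cvec <- colSums(X)
  qrd <- qr(matrix(cvec, ncol = 1))
  Z <- qr.Q(qrd, complete = TRUE)[, -1, drop = FALSE]
  Sp <- crossprod(Z, basis$penalty %*% Z)
  Sp <- (Sp + t(Sp)) / 2
  structure(list(parent = basis, transform = Z, penalty = Sp,
                 design_times = design_times),
            class = "centered_basis")
}

#' Evaluate a centred spline basis
#'
#' @param cb a `centered_basis` from [center_basis()].
#' @param t evaluation times.
#' @return matrix `length(t)` x `(k-1)` with `extrapolated` attribute.
#' @export
eval_centered <- function(cb, t) {
  stopifnot(inherits(cb, "centered_basis"))
  X <- eval_basis(cb$parent, t)
  out <- attr(X, "extrapolated")
  Xc <- X %*% cb$transform
  attr(Xc, "extrapolated") <- out
  Xc
}
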