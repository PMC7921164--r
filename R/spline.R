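#' Fit a cubic smoothing spline (Reinsch form)
#'
#' Minimizes `q * sum_i w_i (v_i - s(t_i))^2 + (1 - q) * Int s''(t)^2 dt`
#' over natural cubic splines with knots at the data times, with error
#' weights `w_i = (1 / sd_i)^2` (SDs floored to avoid infinite weights).
#' At `q = 1` the spline interpolates the anchors exactly, which is the
#' default used for each Monte Carlo realization of the data. The cubic
#' coefficients are retained so value and derivatives evaluate analytically.
#'
#' @param times strictly increasing knot locations (>= 2, no duplicates).
#' @param values anchor values at `times`.
#' @param sds optional standard deviations defining the weights; `NULL` means
#'   unit weights (irrelevant at `q = 1`).
#' @param q smoothing level in `[0, 1]`: 1 interpolates, smaller values trade
#'   fidelity for curvature.
#' @return an object of class `smoothing_spline`; evaluate it with
#'   [predict.smoothing_spline()].
#' @export
fit_smoothing_spline <- function(times, values, sds = NULL, q = 1) {
  stopifnot(length(times) == length(values), q >= 0, q <= 1)
  n <- length(times)
  if (n < 2L) stop("need at least 2 points to fit a spline")
  if (anyDuplicated(times)) stop("duplicate times are not allowed")
  ord <- order(times)
  x <- as.numeric(times[ord])
  y <- as.numeric(values[ord])
  if (n < 4L) {
    warning("fewer than 4 points: spline degrades toward a low-order polynomial")
  }
  if (n == 2L) {
    # a straight line: exact fit, zero roughness, weights immaterial
    return(structure(list(x = x, g = y, M = c(0, 0)), class = "smoothing_spline"))
  }
  w <- if (is.null(sds)) rep(1, n) else {
    s <- as.numeric(sds)[ord]
    s <- pmax(s, 1e-6 * abs(y) + 1e-12) # floor: sd = 0 would give infinite weight
    1 / s^2
  }
  h <- diff(x)
  # Green-Silverman band matrices: Q (n x n-2), R (n-2 x n-2)
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in 2:(n - 1L)) {
    k <- j - 1L
    Q[j - 1L, k] <- 1 / h[j - 1L]
    Q[j, k] <- -1 / h[j - 1L] - 1 / h[j]
    Q[j + 1L, k] <- 1 / h[j]
    R[k, k] <- (h[j - 1L] + h[j]) / 3
    if (k < n - 2L) {
      R[k, k + 1L] <- h[j] / 6
      R[k + 1L, k] <- h[j] / 6
    }
  }
  if (q == 1) {
    g <- y
  } else {
    alpha <- (1 - q) / q
    K <- Q %*% solve(R, t(Q))
    g <- solve(diag(w) + alpha * K, w * y)
  }
  M <- c(0, solve(R, drop(t(Q) %*% g)), 0) # natural: zero end curvature
  structure(list(x = x, g = as.numeric(g), M = as.numeric(M)),
            class = "smoothing_spline")
}

#' Evaluate a smoothing spline or its derivatives
#'
#' Analytic evaluation from the stored cubic pieces. Queries outside the
#' fitted time range raise an error: the trajectory estimator never needs
#' extrapolation, and silently extrapolating a cubic would fabricate data.
#'
#' @param object a [fit_smoothing_spline()] result.
#' @param t evaluation times within the fitted range.
#' @param deriv derivative order 0, 1 or 2.
#' @param ... unused.
#' @return numeric vector of values.
#' @export
predict.smoothing_spline <- function(object, t, deriv = 0, ...) {
  x <- object$x; g <- object$g; M <- object$M
  n <- length(x)
  tol <- 1e-9 * max(1, abs(x[n]) + abs(x[1]))
  t <- as.numeric(t)
  if (any(t < x[1] - tol | t > x[n] + tol)) {
    stop(sprintf("evaluation outside the spline domain [%g, %g]", x[1], x[n]))
  }
  t <- pmin(pmax(t, x[1]), x[n])
  i <- findInterval(t, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  h <- x[i + 1L] - x[i]
  dl <- t - x[i]        # distance from left knot
  dr <- x[i + 1L] - t   # distance to right knot
  if (deriv == 0) {
    M[i] * dr^3 / (6 * h) + M[i + 1L] * dl^3 / (6 * h) +
      (g[i] / h - M[i] * h / 6) * dr + (g[i + 1L] / h - M[i + 1L] * h / 6) * dl
  } else if (deriv == 1) {
    -M[i] * dr^2 / (2 * h) + M[i + 1L] * dl^2 / (2 * h) -
      (g[i] / h - M[i] * h / 6) + (g[i + 1L] / h - M[i + 1L] * h / 6)
  } else if (deriv == 2) {
    (M[i] * dr + M[i + 1L] * dl) / h
  } else {
    stop("deriv must be 0, 1 or 2")
  }
}

#' @export
print.smoothing_spline <- function(x, ...) {
  cat("<smoothing_spline> ", length(x$x), " knots on [",
      x$x[1], ", ", x$x[length(x$x)], "]\n", sep = "")
  invisible(x)
}

# roughness integral Int s''^2 of a fitted spline (exact, since s'' is
# piecewise linear): used by tests and diagnostics
.spline_roughness <- function(object) {
  h <- diff(object$x)
  M <- object$M
  n <- length(object$x)
  sum(h / 3 * (M[-n]^2 + M[-n] * M[-1] + M[-1]^2))
}
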