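#' Local polynomial regression with tricube weights
#'
#' Classic nearest-neighbour LOESS smoother used by the residual-correction
#' steps: for each point, the `ceiling(span * n)` nearest neighbours in `x`
#' (ties broken by input order) receive tricube weights
#' `w = (1 - (d/h)^3)^3` scaled by the window's maximum distance `h`, and a
#' weighted polynomial of the given degree is fit; the returned value is the
#' local fit evaluated at the point itself. No robustifying iterations are
#' performed.
#'
#' @param x,y Numeric vectors of equal length, no missing values.
#' @param span Fraction of points in each local window (default 0.4).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @return Numeric vector of fitted values, aligned with the input order.
#' @export
loess_smooth <- function(x, y, span = 0.4, degree = 2) {
  n <- length(x)
  stopifnot(length(y) == n, degree >= 1)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite")
  }
  q <- ceiling(span * n)
  if (q < degree + 1) {
    stop("span * n = ", span * n, " gives fewer than degree + 1 = ",
         degree + 1, " points per window")
  }
  q <- min(q, n)
  ord <- order(x)  # stable: ties keep input order
  xs <- x[ord]
  ys <- y[ord]
  fit_s <- numeric(n)
  l <- 1L
  for (i in seq_len(n)) {
    # slide the q-wide window so it stays the nearest-neighbour set of xs[i]
    if (l > i) l <- i
    while (l + q - 1L < i) l <- l + 1L
    while (l + q <= n && l < i &&
           (xs[l + q] - xs[i]) < (xs[i] - xs[l])) {
      l <- l + 1L
    }
    idx <- l:(l + q - 1L)
    z <- xs[idx] - xs[i]
    h <- max(abs(z))
    w <- if (h > 0) (1 - pmin(abs(z) / h, 1)^3)^3 else rep(1, q)
    zm <- matrix(1, q, degree + 1L)
    for (p in seq_len(degree)) zm[, p + 1L] <- z^p
    fit <- stats::lm.wfit(zm, ys[idx], w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    fit_s[i] <- beta[1L]  # local polynomial evaluated at z = 0
  }
  out <- numeric(n)
  out[ord] <- fit_s
  out
}
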