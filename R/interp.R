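## Shape-preserving piecewise-cubic Hermite interpolation
## (Fritsch-Carlson slope limiting) with optional prescribed endpoint
## slopes.  Used by the surrogate-surface builder, where only a handful
## of calibration anchors per electronic state are available and any
## interpolation overshoot would create spurious wells or barriers.
## Hand-rolled because the stock monotone spline interfaces do not let
## the caller pin the endpoint derivatives, which the harmonic-wall
## extensions require to vanish.

## Fritsch-Carlson tangents; endpoints optionally forced.
fc_slopes <- function(x, y, end_slopes = c(NA_real_, NA_real_)) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  m <- numeric(n)
  if (n == 2) {
    m[] <- delta
  } else {
    for (i in 2:(n - 1)) {
      if (delta[i - 1] * delta[i] <= 0) {
        m[i] <- 0
      } else {
        ## weighted harmonic mean keeps the limited slope within 3*delta
        w1 <- 2 * h[i] + h[i - 1]
        w2 <- h[i] + 2 * h[i - 1]
        m[i] <- (w1 + w2) / (w1 / delta[i - 1] + w2 / delta[i])
      }
    }
    m[1] <- ((2 * h[1] + h[2]) * delta[1] - h[1] * delta[2]) / (h[1] + h[2])
    if (sign(m[1]) != sign(delta[1])) m[1] <- 0
    else if (abs(m[1]) > 3 * abs(delta[1])) m[1] <- 3 * delta[1]
    m[n] <- ((2 * h[n - 1] + h[n - 2]) * delta[n - 1] - h[n - 1] * delta[n - 2]) /
      (h[n - 1] + h[n - 2])
    if (sign(m[n]) != sign(delta[n - 1])) m[n] <- 0
    else if (abs(m[n]) > 3 * abs(delta[n - 1])) m[n] <- 3 * delta[n - 1]
  }
  if (!is.na(end_slopes[1])) m[1] <- end_slopes[1]
  if (!is.na(end_slopes[2])) m[n] <- end_slopes[2]
  m
}

## Monotone piecewise-cubic interpolant; returns an evaluator
## f(x, deriv = 0L | 1L).  A zero prescribed endpoint slope is always
## admissible for the Fritsch-Carlson monotonicity condition, so the
## interpolant stays monotone on every interval.
pchip_fun <- function(x, y, end_slopes = c(NA_real_, NA_real_)) {
  stopifnot(length(x) == length(y), length(x) >= 2, !is.unsorted(x, strictly = TRUE))
  m <- fc_slopes(x, y, end_slopes)
  n <- length(x)
  force(y)
  function(xq, deriv = 0L) {
    i <- findInterval(xq, x, rightmost.closed = TRUE)
    i[i < 1] <- 1L
    i[i > n - 1] <- n - 1L
    h <- x[i + 1] - x[i]
    t <- (xq - x[i]) / h
    if (deriv == 0L) {
      h00 <- (1 + 2 * t) * (1 - t)^2
      h10 <- t * (1 - t)^2
      h01 <- t^2 * (3 - 2 * t)
      h11 <- t^2 * (t - 1)
      h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
    } else if (deriv == 1L) {
      d00 <- 6 * t * (t - 1)
      d10 <- (1 - t) * (1 - 3 * t)
      d01 <- -6 * t * (t - 1)
      d11 <- t * (3 * t - 2)
      (d00 * y[i] + d01 * y[i + 1]) / h + d10 * m[i] + d11 * m[i + 1]
    } else {
      stop("deriv must be 0 or 1")
    }
  }
}
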