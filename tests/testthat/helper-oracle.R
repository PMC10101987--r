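# Independent brute-force oracle for DSS integration: evaluates the 4PL
# inhibition curve on a dense grid and integrates by the trapezoid rule.
# Deliberately shares no code with the package's closed-form integrator.

oracle_4pl <- function(x, top, bottom, log_ec50, slope) {
  bottom + (top - bottom) / (1 + 10^(slope * (x - log_ec50)))
}

oracle_dss <- function(top, bottom, log_ec50, slope,
                       x_lo = 0, x_hi = 4, t = 10, f = 10,
                       tail_rule = "cap", n_grid = 10001) {
  x <- seq(x_lo, x_hi, length.out = n_grid)
  h <- x[2] - x[1]
  y <- pmin(pmax(100 - oracle_4pl(x, top, bottom, log_ec50, slope), 0), 100)
  cap <- 100 - f

  # first grid crossing of t, linearly interpolated
  above_t <- which(y >= t)
  if (length(above_t) == 0) {
    return(list(area = 0, x1 = NA_real_, dss1 = 0, mdss3 = 0))
  }
  i <- above_t[1]
  x1 <- if (i == 1) x_lo else {
    x[i - 1] + h * (t - y[i - 1]) / (y[i] - y[i - 1])
  }

  above_c <- which(y >= cap)
  x2 <- if (length(above_c) == 0) x_hi else {
    j <- above_c[1]
    if (j == 1) x_lo else x[j - 1] + h * (cap - y[j - 1]) / (y[j] - y[j - 1])
  }

  # re-grid over the actual integration bounds so the trapezoid rule sees
  # no partial cells at x1/x2 (the integrand is continuous inside them)
  trap <- function(a, b, f) {
    if (b <= a) return(0)
    xg <- seq(a, b, length.out = n_grid)
    g <- f(pmin(pmax(100 - oracle_4pl(xg, top, bottom, log_ec50, slope),
                     0), 100))
    sum((g[-1] + g[-n_grid]) / 2) * (xg[2] - xg[1])
  }
  area <- if (tail_rule == "cap") {
    trap(x1, x_hi, function(y) pmax(pmin(y, cap) - t, 0))
  } else {
    trap(x1, x2, function(y) pmax(y - t, 0))
  }
  span <- x_hi - x_lo
  dss1 <- 100 * area / ((100 - t) * span)
  list(area = area, x1 = x1, x2 = x2, dss1 = dss1,
       mdss3 = dss1 * (x_hi - x1) / span)
}
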