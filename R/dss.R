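# Drug sensitivity scores (DSS family) from a fitted 4PL viability curve.
#
# On the log10-dose window [x_lo, x_hi] defined by the tested series, the
# inhibition curve is y(x) = clip(100 - v(x), 0, 100). With activity
# threshold t (inhibition percentage points) and viability floor f (so the
# inhibition cap is c = 100 - f), the score integrates the excess
# inhibition above t:
#
#   x1 = first x with y(x) >= t   (none -> score 0, inactive)
#   x2 = first x with y(x) >= c   (none -> x_hi)
#   cap rule:      A = int_{x1}^{x_hi} (min(y, c) - t)+ dx
#   truncate rule: A = int_{x1}^{x2}  (y - t)+ dx
#
#   DSS1  = 100 A / ((100 - t) (x_hi - x_lo))
#   DSS2  = DSS1 / log10(d),  d = min(max window inhibition, 100); d <= 10 -> 0
#   w     = (x_hi - x1) / (x_hi - x_lo)      (width factor)
#   DSS3  = DSS2 w
#   mDSS3 = DSS1 w   (DSS3 without the top-asymptote logarithm divisor)
#
# Integration is exact: the logistic is integrated in closed form between
# the analytically-known clip/threshold crossing points.

#' DSS scoring configuration
#'
#' @param t Activity threshold in inhibition percentage points (default
#'   10): inhibition below `t` never accrues score, suppressing
#'   noise-level dips.
#' @param f Viability floor in percent (default 10). The inhibition cap is
#'   `c = 100 - f`; the concentration window for full activity runs from
#'   the lowest tested dose to the dose where viability reaches `f`.
#' @param tail_rule `"cap"` (default) counts the capped rectangle
#'   `c - t` beyond the viability-`f` crossing, so maximally potent drugs
#'   score maximally; `"truncate"` stops accrual at the crossing.
#' @param metric Which score [dss()] reports as `score`: `"mdss3"`
#'   (default; the modified DSS3), `"dss1"`, `"dss2"` or `"dss3"`.
#' @return A list of class `dss_config`.
#' @export
dss_config <- function(t = 10, f = 10,
                       tail_rule = c("cap", "truncate"),
                       metric = c("mdss3", "dss1", "dss2", "dss3")) {
  tail_rule <- match.arg(tail_rule)
  metric <- match.arg(metric)
  if (!(t >= 0 && t < 100 - f && 100 - f <= 100)) {
    abort("Require 0 <= t < 100 - f <= 100.")
  }
  structure(list(t = t, f = f, tail_rule = tail_rule, metric = metric),
            class = "dss_config")
}

# x where v(x) = V on the logistic, or NA if never attained.
fourpl_inverse <- function(fit, V) {
  num <- fit$top - V
  den <- V - fit$bottom
  if (!is.finite(num) || !is.finite(den) || num * den <= 0) return(NA_real_)
  fit$log_ec50 + log10(num / den) / fit$slope
}

# Stable log(1 + exp(u))
log1pexp <- function(u) pmax(u, 0) + log1p(exp(-abs(u)))

# int_a^b v(x) dx in closed form.
fourpl_integral <- function(fit, a, b) {
  if (b <= a) return(0)
  s <- fit$slope
  k <- s * log(10)
  u <- function(x) k * (x - fit$log_ec50)
  I <- (b - a) - (log1pexp(u(b)) - log1pexp(u(a))) / k
  fit$bottom * (b - a) + (fit$top - fit$bottom) * I
}

# int_a^b (min(clip(100 - v, 0, 100), cap) - t)+ dx, exact piecewise.
integrate_excess <- function(fit, a, b, t, cap) {
  if (b <= a) return(0)
  # clip/threshold statuses change only where v crosses these values
  vals <- unique(c(0, 100, 100 - t, 100 - cap))
  breaks <- sort(unique(c(a, b, stats::na.omit(
    vapply(vals, function(V) fourpl_inverse(fit, V), numeric(1))
  ))))
  breaks <- breaks[breaks >= a & breaks <= b]
  if (breaks[1] > a) breaks <- c(a, breaks)
  if (breaks[length(breaks)] < b) breaks <- c(breaks, b)
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    if (hi - lo < 1e-12) next
    mid <- (lo + hi) / 2
    y_mid <- clamp(100 - fourpl(mid, fit$top, fit$bottom,
                                fit$log_ec50, fit$slope), 0, 100)
    if (y_mid <= t) next
    if (y_mid >= cap) {
      total <- total + (cap - t) * (hi - lo)
    } else {
      # t < y < cap <= 100: clip inactive, integrate (100 - t) - v exactly
      total <- total + (100 - t) * (hi - lo) - fourpl_integral(fit, lo, hi)
    }
  }
  total
}

inhibition_at <- function(fit, x) {
  clamp(100 - fourpl(x, fit$top, fit$bottom, fit$log_ec50, fit$slope), 0, 100)
}

# First x in [x_lo, x_hi] with inhibition >= level, or NA.
first_crossing <- function(fit, x_lo, x_hi, level) {
  y_lo <- inhibition_at(fit, x_lo)
  if (y_lo >= level) return(x_lo)
  y_hi <- inhibition_at(fit, x_hi)
  if (y_hi < level) return(NA_real_)
  # y increasing across the window: crossing is where v = 100 - level
  xc <- fourpl_inverse(fit, 100 - level)
  if (is.na(xc)) return(NA_real_)
  clamp(xc, x_lo, x_hi)
}

#' Drug sensitivity score of a fitted curve
#'
#' Summarizes a fitted concentration-response curve as a scalar
#' sensitivity score by integrating excess inhibition over the tested
#' log10-dose window (see the package vignette for the full model). The
#' default metric is the modified DSS3 (`mdss3`): the DSS3 width-scaled
#' area without the division by the logarithm of the curve's upper
#' asymptote, with an activity window on the viability axis from 100% down
#' to `f` = 10% and the concentration window running from the lowest
#' tested dose to the dose where viability reaches 10%. Higher scores mean
#' higher ex vivo sensitivity.
#'
#' @param fit A [fit_4pl()] object.
#' @param series The [conc_series()] defining the integration window.
#' @param cfg A [dss_config()].
#' @param entry_id Optional entry label carried into the output.
#' @return A one-row tibble: `entry_id`, `score` (the configured metric),
#'   `dss1`, `dss2`, `dss3`, `mdss3`, `area`, `x1`, `x2`, `width`,
#'   `rmse`, `converged` and `flags` (comma-separated subset of
#'   `inactive`, `complete_kill_at_min`, `poor_fit`, or `""`).
#' @export
#' @examples
#' s <- conc_series_log(1, 10000, 5)
#' v <- fit_4pl(s, c(99, 91, 50, 9, 1))
#' dss(v, s)
dss <- function(fit, series, cfg = dss_config(), entry_id = NA_character_) {
  stopifnot(inherits(fit, "fit4pl"))
  w <- series_window(series)
  x_lo <- w[1]; x_hi <- w[2]
  if (x_hi <= x_lo) abort("Degenerate integration window: x_hi must exceed x_lo.")
  t <- cfg$t
  cap <- 100 - cfg$f

  flags <- character(0)
  if (!fit$converged || fit$rmse > 15) flags <- c(flags, "poor_fit")

  x1 <- first_crossing(fit, x_lo, x_hi, t)
  if (is.na(x1)) {
    out <- score_row(entry_id, cfg, dss1 = 0, dss2 = 0, dss3 = 0, mdss3 = 0,
                     area = 0, x1 = NA_real_, x2 = NA_real_, width = 0,
                     fit = fit, flags = c(flags, "inactive"))
    return(out)
  }
  if (inhibition_at(fit, x_lo) >= cap) {
    flags <- c(flags, "complete_kill_at_min")
  }
  x2 <- first_crossing(fit, x_lo, x_hi, cap)
  x2_eff <- if (is.na(x2)) x_hi else x2

  area <- if (cfg$tail_rule == "cap") {
    integrate_excess(fit, x1, x_hi, t, cap)
  } else {
    integrate_excess(fit, x1, x2_eff, t, 100)
  }

  span <- x_hi - x_lo
  dss1 <- 100 * area / ((100 - t) * span)
  width <- (x_hi - x1) / span
  d <- min(max(inhibition_at(fit, x_lo), inhibition_at(fit, x_hi)), 100)
  dss2 <- if (d <= 10) 0 else dss1 / log10(d)
  score_row(entry_id, cfg, dss1 = dss1, dss2 = dss2, dss3 = dss2 * width,
            mdss3 = dss1 * width, area = area, x1 = x1, x2 = x2_eff,
            width = width, fit = fit, flags = flags)
}

score_row <- function(entry_id, cfg, dss1, dss2, dss3, mdss3, area,
                      x1, x2, width, fit, flags) {
  scores <- c(dss1 = dss1, dss2 = dss2, dss3 = dss3, mdss3 = mdss3)
  tibble(
    entry_id = entry_id,
    score = unname(scores[cfg$metric]),
    metric = cfg$metric,
    dss1 = dss1, dss2 = dss2, dss3 = dss3, mdss3 = mdss3,
    area = area, x1 = x1, x2 = x2, width = width,
    rmse = fit$rmse, converged = fit$converged,
    flags = paste(flags, collapse = ",")
  )
}

#' Score every library entry of a screen
#'
#' Fits a 4PL curve per entry from its aggregated viability values and
#' scores it with [dss()]. Single agents and combinations are scored
#' identically: a combination is one curve on its shared fixed-molar
#' concentration series. Entries whose dose series is incomplete in the
#' viability table are skipped with a warning.
#'
#' @param viab Viability tibble from [normalize_viability()] (may span
#'   several plates).
#' @param library Library tibble from [read_library()] /
#'   [validate_library()].
#' @param cfg A [dss_config()].
#' @return A tibble with one [dss()] row per scored entry plus `kind`,
#'   sorted by descending `score` (ties broken by `entry_id`).
#' @export
score_screen <- function(viab, library, cfg = dss_config()) {
  rows <- purrr::map(seq_len(nrow(library)), function(i) {
    id <- library$entry_id[i]
    series <- library$series[[i]]
    v <- viab[viab$entry_id == id, ]
    v <- v[order(v$conc_index), ]
    n_doses <- length(series$values_nM)
    if (nrow(v) != n_doses ||
        !identical(sort(unique(v$conc_index)), 0:(n_doses - 1))) {
      warn(paste0("Entry ", id, " has an incomplete dose series (",
                  nrow(v), "/", n_doses, " doses); skipped."))
      return(NULL)
    }
    fit <- fit_4pl(series, v$viability_percent)
    res <- dss(fit, series, cfg, entry_id = id)
    res$kind <- library$kind[i]
    res
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$entry_id)
}

#' Waterfall plot of screen scores
#'
#' Ranked bar chart of drug sensitivity scores, the standard single-screen
#' report figure (one bar per library entry, most sensitive first).
#'
#' @param scores Tibble from [score_screen()] or [run_pipeline()].
#' @param top_n Show only the `top_n` highest-scoring entries (default
#'   all).
#' @return A ggplot object.
#' @export
plot_screen_waterfall <- function(scores, top_n = nrow(scores)) {
  df <- head(dplyr::arrange(scores, dplyr::desc(.data$score)), top_n)
  df$entry_id <- factor(df$entry_id, levels = rev(df$entry_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$entry_id, .data$score)) +
    ggplot2::geom_col(fill = "#c2185b") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("Drug sensitivity score (",
                                       df$metric[1], ")")) +
    ggplot2::theme_minimal()
}
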