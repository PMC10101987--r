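#' Construct a concentration series
#'
#' A concentration series is the ordered set of tested doses (in nM) that
#' defines the integration window of the drug sensitivity score: the window
#' runs from `log10(min)` to `log10(max)` on the log10-nM axis. The standard
#' screen design tests five concentrations in ten-fold increments from 1 to
#' 10,000 nM (0.1 to 1,000 nM for a few highly potent compounds).
#'
#' @param values_nM Numeric vector of concentrations in nM, strictly
#'   increasing, all positive, length >= 2.
#' @param label Optional series name.
#' @return An object of class `conc_series`: a list with `values_nM`,
#'   `log10_values` and `label`.
#' @export
#' @examples
#' conc_series(c(1, 10, 100, 1000, 10000))
conc_series <- function(values_nM, label = NULL) {
  values_nM <- as.numeric(values_nM)
  if (length(values_nM) < 2) {
    abort("A concentration series needs at least 2 doses.")
  }
  if (anyNA(values_nM) || any(!is.finite(values_nM)) || any(values_nM <= 0)) {
    abort("Concentrations must be finite and strictly positive.")
  }
  if (any(diff(values_nM) <= 0)) {
    abort("Concentrations must be strictly increasing.")
  }
  structure(
    list(
      values_nM = values_nM,
      log10_values = log10(values_nM),
      label = label %||% paste0(min(values_nM), "-", max(values_nM), " nM")
    ),
    class = "conc_series"
  )
}

#' Log-equispaced concentration series
#'
#' Builds `n_points` doses equally spaced in log10 between `min_nM` and
#' `max_nM`. The default reproduces the standard five-point, ten-fold
#' design (1, 10, 100, 1000, 10000 nM).
#'
#' @param min_nM,max_nM Lowest and highest dose in nM (`min_nM < max_nM`).
#' @param n_points Number of doses (default 5).
#' @inheritParams conc_series
#' @return A `conc_series`.
#' @export
#' @examples
#' conc_series_log(0.1, 1000)   # copanlisib / dasatinib series
conc_series_log <- function(min_nM = 1, max_nM = 10000, n_points = 5,
                            label = NULL) {
  if (!is.finite(min_nM) || !is.finite(max_nM) || min_nM <= 0) {
    abort("Dose range must be finite and positive.")
  }
  if (min_nM >= max_nM) {
    abort("`min_nM` must be strictly less than `max_nM`.")
  }
  if (n_points < 2) abort("`n_points` must be at least 2.")
  conc_series(10^seq(log10(min_nM), log10(max_nM), length.out = n_points),
              label = label)
}

#' @export
print.conc_series <- function(x, ...) {
  cat("<conc_series> ", x$label, ": ",
      paste(signif(x$values_nM, 4), collapse = ", "), " nM\n", sep = "")
  invisible(x)
}

# Integration window on the log10(nM) axis.
series_window <- function(series) {
  range(series$log10_values)
}
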