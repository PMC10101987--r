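# Phospho-flow summaries: arcsinh ratios of median fluorescence
# intensities relative to a reference (isotype or unstimulated control),
# the standard effect scale for intracellular signaling readouts.

#' Arcsinh ratio of a signal relative to a reference
#'
#' `asinh(signal / cofactor) - asinh(reference / cofactor)`. The reference
#' (isotype control or unstimulated control) maps to zero by construction.
#' For signals well below the cofactor the transform is approximately
#' linear, `(signal - reference) / cofactor`; far above it, approximately
#' a log-ratio.
#'
#' @param signal,reference Non-negative median fluorescence intensities.
#' @param cofactor Arcsinh scale cofactor (> 0, default 150, a common
#'   choice for conventional fluorescence cytometry).
#' @return Dimensionless arcsinh ratio(s).
#' @export
#' @examples
#' arcsinh_ratio(1500, 150)        # asinh(10) - asinh(1)
#' arcsinh_ratio(150, 150)         # 0
arcsinh_ratio <- function(signal, reference, cofactor = 150) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || !is.finite(cofactor) ||
      cofactor <= 0) {
    abort("`cofactor` must be a single positive number.")
  }
  if (any(signal < 0, na.rm = TRUE) || any(reference < 0, na.rm = TRUE)) {
    abort("Median intensities must be non-negative.")
  }
  asinh(signal / cofactor) - asinh(reference / cofactor)
}

#' Percent of a later value relative to an earlier value
#'
#' `100 * later / earlier`, rounded half-away-from-zero to an integer
#' percent — the convention under which a marker rising from arcsinh
#' ratio 0.28 to 1.97 is reported as 704%.
#'
#' @param later,earlier Finite numbers; `earlier` must be non-zero.
#' @return Integer percent(s).
#' @export
#' @examples
#' percent_relative(1.97, 0.28)  # 704
percent_relative <- function(later, earlier) {
  if (any(!is.finite(later)) || any(!is.finite(earlier))) {
    abort("Both values must be finite.")
  }
  if (any(earlier == 0)) {
    abort("Undefined relative change: `earlier` is zero.")
  }
  p <- 100 * later / earlier
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Arcsinh-ratio table from marker medians
#'
#' Joins a long table of per-sample, per-marker median intensities with a
#' per-marker reference median and computes [arcsinh_ratio()] for every
#' pair.
#'
#' @param medians Tibble with columns `sample`, `marker`, `median`.
#' @param reference Tibble with columns `marker`, `median` (one row per
#'   marker; the isotype/unstimulated reference).
#' @param cofactor Arcsinh cofactor (default 150).
#' @return `medians` with an added `arcsinh_ratio` column.
#' @export
flow_arcsinh <- function(medians, reference, cofactor = 150) {
  missing_ref <- setdiff(unique(medians$marker), reference$marker)
  if (length(missing_ref) > 0) {
    abort(paste0("No reference median for marker(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  ref <- dplyr::rename(reference[, c("marker", "median")],
                       ref_median = "median")
  out <- dplyr::left_join(as_tibble(medians), ref, by = "marker")
  out$arcsinh_ratio <- arcsinh_ratio(out$median, out$ref_median, cofactor)
  out
}

#' Sample-by-marker arcsinh-ratio matrix with clustering orders
#'
#' Builds the heatmap matrix of arcsinh ratios (samples in rows, markers
#' in columns) and hierarchically clusters both rows and columns with
#' Manhattan distance and Ward linkage (`ward.D` on the raw
#' dissimilarity, matching ClustVis). Leaf orders are deterministic given
#' the input order; a dimension that cannot be clustered (fewer than two
#' levels, or a constant matrix) keeps its input order with a warning.
#'
#' @param medians Tibble with `sample`, `marker`, `median` columns, or a
#'   precomputed table from [flow_arcsinh()] (its `arcsinh_ratio` column
#'   is then used directly).
#' @param reference Per-marker reference tibble (ignored when `medians`
#'   already carries `arcsinh_ratio`).
#' @param cofactor Arcsinh cofactor (default 150).
#' @return A list of class `marker_matrix`: `matrix` (samples x markers),
#'   `row_order`, `col_order` (integer leaf orders), `cofactor`.
#' @export
marker_heatmap_matrix <- function(medians, reference = NULL, cofactor = 150) {
  if (!"arcsinh_ratio" %in% names(medians)) {
    if (is.null(reference)) {
      abort("Provide `reference` medians or a precomputed `arcsinh_ratio` column.")
    }
    medians <- flow_arcsinh(medians, reference, cofactor)
  }
  samples <- unique(medians$sample)
  markers <- unique(medians$marker)
  if (length(samples) < 2) abort("Need at least 2 samples to build the matrix.")
  wide <- tidyr::pivot_wider(
    medians[, c("sample", "marker", "arcsinh_ratio")],
    names_from = "marker", values_from = "arcsinh_ratio"
  )
  m <- as.matrix(wide[, markers, drop = FALSE])
  rownames(m) <- wide$sample
  m <- m[samples, , drop = FALSE]
  structure(
    list(
      matrix = m,
      row_order = cluster_order(m, "rows"),
      col_order = cluster_order(t(m), "columns"),
      cofactor = cofactor
    ),
    class = "marker_matrix"
  )
}

# Ward.D linkage on Manhattan distance; ties resolved by input index
# (hclust is deterministic for a given distance matrix and input order).
cluster_order <- function(m, what) {
  if (nrow(m) < 2) {
    warn(paste0("Fewer than 2 ", what, "; clustering skipped."))
    return(seq_len(nrow(m)))
  }
  d <- dist(m, method = "manhattan")
  if (all(d == 0)) {
    warn(paste0("Constant matrix: ", what, " clustering skipped, input order kept."))
    return(seq_len(nrow(m)))
  }
  hclust(d, method = "ward.D")$order
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("<marker_matrix> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " markers (arcsinh cofactor ", x$cofactor, ")\n", sep = "")
  invisible(x)
}

#' Heatmap of a clustered marker matrix
#'
#' @param object A `marker_matrix` from [marker_heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot tile heatmap with rows/columns in clustered order.
#' @export
autoplot.marker_matrix <- function(object, ...) {
  m <- object$matrix[object$row_order, object$col_order, drop = FALSE]
  df <- tibble(
    sample = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    marker = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$marker, .data$sample,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "arcsinh ratio") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
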