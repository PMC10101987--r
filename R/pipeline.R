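#' Run the full screen-analysis pipeline
#'
#' Orchestrates one screen end to end: per-plate control summaries and
#' Z'-factor QC, control-anchored viability normalization, 4PL fitting
#' and DSS scoring of every library entry. Plates failing QC do not stop
#' the analysis by default; their entries carry a `qc_fail` flag so that
#' the score table stays complete (set `strict = TRUE` to abort instead).
#'
#' @param plates Long raw-plate tibble (`plate_id`, `well`, `value`)
#'   covering all plates of the screen, or a `sim_screen` object from
#'   [simulate_screen()] (in which case `plate_maps` and `library` are
#'   taken from it).
#' @param plate_maps Long plate-map tibble covering the same plates.
#' @param library Library tibble from [read_library()].
#' @param cfg A [dss_config()].
#' @param zprime_min Z'-factor pass threshold (default 0.5).
#' @param strict Abort if any plate fails QC (default `FALSE`).
#' @return A list of class `screen_result`: `scores` (the [score_screen()]
#'   table plus `zprime` and `qc_fail` per entry) and `qc` (per-plate
#'   control summary with `zprime` and `pass`).
#' @export
#' @examples
#' sim <- simulate_screen(sim_screen_config(n_singles = 6, n_combos = 0,
#'                                          seed = 7))
#' res <- run_pipeline(sim)
#' head(res$scores)
run_pipeline <- function(plates, plate_maps = NULL, library = NULL,
                         cfg = dss_config(), zprime_min = 0.5,
                         strict = FALSE) {
  if (inherits(plates, "sim_screen")) {
    plate_maps <- plate_maps %||% plates$plate_maps
    library <- library %||% plates$library
    plates <- plates$plates
  }
  if (is.null(plate_maps) || is.null(library)) {
    abort("`plate_maps` and `library` are required.")
  }
  plate_ids <- unique(plates$plate_id)
  qc <- purrr::map(plate_ids, function(pid) {
    p <- plates[plates$plate_id == pid, ]
    m <- plate_maps[plate_maps$plate_id == pid, ]
    cs <- summarize_controls(p, m)
    dplyr::left_join(cs, zprime(cs, threshold = zprime_min), by = "plate_id")
  }) |> dplyr::bind_rows()
  if (strict && any(!qc$pass)) {
    abort(paste0("Plate(s) failed QC (Z' < ", zprime_min, "): ",
                 paste(qc$plate_id[!qc$pass], collapse = ", "),
                 ". Rerun without `strict` to score anyway."))
  }
  viab <- purrr::map(plate_ids, function(pid) {
    p <- plates[plates$plate_id == pid, ]
    m <- plate_maps[plate_maps$plate_id == pid, ]
    normalize_viability(p, m, qc[qc$plate_id == pid, ])
  }) |> dplyr::bind_rows()

  scores <- score_screen(viab, library, cfg)
  entry_plate <- plate_maps[plate_maps$role == "treatment",
                            c("entry_id", "plate_id")] |>
    dplyr::distinct() |>
    dplyr::left_join(qc[, c("plate_id", "zprime", "pass")], by = "plate_id") |>
    dplyr::group_by(.data$entry_id) |>
    dplyr::summarise(zprime = min(.data$zprime),
                     qc_fail = any(!.data$pass), .groups = "drop")
  scores <- dplyr::left_join(scores, entry_plate, by = "entry_id")
  structure(list(scores = scores, qc = qc), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x$scores), " entries scored on ",
      nrow(x$qc), " plate(s); Z' range ",
      paste(signif(range(x$qc$zprime), 3), collapse = " to "), "\n", sep = "")
  print(head(x$scores[, c("entry_id", "score", "metric", "flags")], 5))
  invisible(x)
}

#' Compare drug-sensitivity scores across serial screens
#'
#' Aligns two or more score tables (e.g. one per sampling time-point) on
#' their shared entries, computes score differences against a declared
#' baseline time-point, and clusters both entries and time-points with
#' Manhattan distance and Ward linkage for heatmap display. Entries not
#' shared by all tables are dropped from the aligned matrix (missing
#' scores are reported, never imputed); shared entries are ordered
#' lexicographically so the result does not depend on input table order
#' beyond the baseline choice.
#'
#' @param tables Named list (>= 2) of score tibbles with `entry_id` and
#'   `score` columns; names are the time-point labels.
#' @param baseline Name of the baseline table (default the first).
#' @return A list of class `screen_comparison`: `scores` (entries x
#'   time-points matrix), `delta` (same shape, score minus baseline
#'   score), `baseline`, `row_order`, `col_order`, `dropped` (entry ids
#'   not shared by all tables).
#' @export
compare_screens <- function(tables, baseline = names(tables)[1]) {
  if (length(tables) < 2) abort("Need at least 2 score tables to compare.")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a named list (names = time-point labels).")
  }
  if (!baseline %in% names(tables)) {
    abort(paste0("Baseline '", baseline, "' is not among the tables: ",
                 paste(names(tables), collapse = ", ")))
  }
  ids <- purrr::map(tables, function(tb) unique(tb$entry_id))
  shared <- sort(purrr::reduce(ids, intersect))
  if (length(shared) == 0) abort("No entry is shared by all tables.")
  dropped <- sort(setdiff(purrr::reduce(ids, union), shared))
  m <- vapply(tables, function(tb) {
    tb$score[match(shared, tb$entry_id)]
  }, numeric(length(shared)))
  m <- matrix(m, nrow = length(shared),
              dimnames = list(shared, names(tables)))
  delta <- m - m[, baseline]
  structure(
    list(scores = m, delta = delta, baseline = baseline,
         row_order = cluster_order(m, "entries"),
         col_order = cluster_order(t(m), "time-points"),
         dropped = dropped),
    class = "screen_comparison"
  )
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat("<screen_comparison> ", nrow(x$scores), " shared entries x ",
      ncol(x$scores), " time-points (baseline ", x$baseline, ")\n", sep = "")
  if (length(x$dropped) > 0) {
    cat("  dropped (not shared): ", length(x$dropped), " entries\n", sep = "")
  }
  invisible(x)
}

#' Tidy a screen comparison into a long table
#'
#' @param x A `screen_comparison`.
#' @param ... Unused.
#' @return A tibble with `entry_id`, `time_point`, `score`,
#'   `delta_vs_baseline`.
#' @export
tidy.screen_comparison <- function(x, ...) {
  tibble(
    entry_id = rep(rownames(x$scores), times = ncol(x$scores)),
    time_point = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores),
    delta_vs_baseline = as.vector(x$delta)
  )
}

#' Heatmap of serial screen scores
#'
#' @param object A `screen_comparison` from [compare_screens()].
#' @param ... Unused.
#' @return A ggplot tile heatmap, rows/columns in clustered order.
#' @export
autoplot.screen_comparison <- function(object, ...) {
  m <- object$scores[object$row_order, object$col_order, drop = FALSE]
  df <- tibble(
    entry_id = factor(rep(rownames(m), times = ncol(m)),
                      levels = rev(rownames(m))),
    time_point = factor(rep(colnames(m), each = nrow(m)),
                        levels = colnames(m)),
    score = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_point, .data$entry_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#c2185b",
                                 name = "DSS") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Normalize a viability time-course to an anchor day
#'
#' Divides each signal by the signal at the anchor day, so the anchor maps
#' to exactly 1.0 — e.g. a 10-day survival course anchored at day 0, or a
#' restimulation series re-anchored at R0. Extra columns (e.g. a culture
#' condition) group the normalization: each group is anchored to its own
#' anchor-day value.
#'
#' @param signals Tibble with columns `day` and `value` plus optional
#'   grouping columns.
#' @param anchor_day The anchor day label (must be present in every
#'   group, with a positive value).
#' @return `signals` with an added `fraction` column (`value` divided by
#'   the group's anchor value).
#' @export
#' @examples
#' tc <- tibble::tibble(day = c(0, 3), value = c(2e6, 1e6))
#' timecourse_normalize(tc, 0)
timecourse_normalize <- function(signals, anchor_day) {
  signals <- as_tibble(signals)
  if (!all(c("day", "value") %in% names(signals))) {
    abort("`signals` must have `day` and `value` columns.")
  }
  group_cols <- setdiff(names(signals), c("day", "value", "fraction"))
  out <- signals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(g, key) {
      anchor <- g$value[g$day == anchor_day]
      if (length(anchor) == 0) {
        abort(paste0("Anchor day '", anchor_day, "' absent from the series."))
      }
      if (length(anchor) > 1) anchor <- mean(anchor)
      if (!is.finite(anchor) || anchor <= 0) {
        abort("Anchor value must be positive.")
      }
      g$fraction <- g$value / anchor
      g
    }) |>
    dplyr::ungroup()
  out[, c(group_cols, "day", "value", "fraction")]
}
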