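#' Summarize control wells of a plate
#'
#' Computes mean and sample standard deviation (n - 1 denominator) of the
#' negative-control (vehicle, 100% viability) and positive-control (full
#' kill, 0% viability) luminescence on one plate. At least two wells of
#' each role are required so that the Z'-factor has a dispersion estimate.
#'
#' @param plate Raw-plate tibble (`plate_id`, `well`, `value`) from
#'   [read_raw_plate()] or [simulate_screen()].
#' @param map Companion plate-map tibble.
#' @return A one-row tibble: `plate_id`, `mu_neg`, `sigma_neg`, `n_neg`,
#'   `mu_pos`, `sigma_pos`, `n_pos`.
#' @export
summarize_controls <- function(plate, map) {
  joined <- dplyr::inner_join(plate, map[, c("well", "role")], by = "well")
  neg <- joined$value[joined$role == "negative_control"]
  pos <- joined$value[joined$role == "positive_control"]
  if (length(neg) < 2 || length(pos) < 2) {
    abort(paste0("Insufficient controls on plate ", plate$plate_id[1],
                 ": need >= 2 negative and >= 2 positive control wells ",
                 "(have ", length(neg), " / ", length(pos), ")."))
  }
  tibble(
    plate_id = plate$plate_id[1],
    mu_neg = mean(neg), sigma_neg = sd(neg), n_neg = length(neg),
    mu_pos = mean(pos), sigma_pos = sd(pos), n_pos = length(pos)
  )
}

#' Z'-factor plate quality statistic
#'
#' The Z'-factor (Zhang, Chung & Oldenburg 1999) combines control
#' separation and control noise:
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{neg} - \mu_{pos}|}}
#' It is at most 1 (noiseless controls); values >= 0.5 conventionally mark
#' an excellent assay window and are the pass threshold used here.
#'
#' @param cs Control summary (one row per plate) from
#'   [summarize_controls()].
#' @param threshold Pass threshold (default 0.5).
#' @return A tibble `plate_id`, `zprime`, `pass`.
#' @export
#' @examples
#' cs <- tibble::tibble(plate_id = "p1", mu_neg = 100, sigma_neg = 5,
#'                      n_neg = 16, mu_pos = 0, sigma_pos = 5, n_pos = 16)
#' zprime(cs)  # 1 - 3*10/100 = 0.7
zprime <- function(cs, threshold = 0.5) {
  if (any(cs$mu_neg == cs$mu_pos)) {
    abort("Degenerate controls: mu_neg equals mu_pos, Z' undefined.")
  }
  z <- 1 - 3 * (cs$sigma_pos + cs$sigma_neg) / abs(cs$mu_neg - cs$mu_pos)
  tibble(plate_id = cs$plate_id, zprime = z, pass = z >= threshold)
}

#' Normalize raw luminescence to percent viability
#'
#' Anchors the readout on the plate's own controls:
#' \deqn{viability = 100 (L - \mu_{pos}) / (\mu_{neg} - \mu_{pos})}
#' so the negative-control mean maps to 100% and the positive-control mean
#' to 0%. Values are deliberately not clipped here (wells above 100% or
#' below 0% stay visible for QC); clipping to the activity window happens
#' inside the scoring step. Replicate wells of the same (entry,
#' concentration) pair are averaged.
#'
#' @param plate Raw-plate tibble.
#' @param map Companion plate-map tibble.
#' @param cs Control summary from [summarize_controls()]; computed from
#'   `plate` if omitted.
#' @return A viability tibble: one row per (entry_id, conc_index) with
#'   columns `plate_id`, `entry_id`, `conc_index`, `viability_percent`,
#'   `n_wells`.
#' @export
normalize_viability <- function(plate, map, cs = summarize_controls(plate, map)) {
  if (cs$mu_neg <= cs$mu_pos) {
    abort("Signal polarity inverted: negative-control mean must exceed positive-control mean.")
  }
  joined <- dplyr::inner_join(
    plate, map[, c("well", "role", "entry_id", "conc_index")], by = "well"
  )
  trt <- joined[joined$role == "treatment", ]
  trt$viability_percent <-
    100 * (trt$value - cs$mu_pos) / (cs$mu_neg - cs$mu_pos)
  trt |>
    dplyr::group_by(.data$plate_id, .data$entry_id, .data$conc_index) |>
    dplyr::summarise(
      viability_percent = mean(.data$viability_percent),
      n_wells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$entry_id, .data$conc_index)
}

# Normalized control wells (QC view): negative controls average to 100,
# positive to 0, by construction.
normalize_controls <- function(plate, map, cs = summarize_controls(plate, map)) {
  joined <- dplyr::inner_join(plate, map[, c("well", "role")], by = "well")
  ctl <- joined[joined$role %in% c("negative_control", "positive_control"), ]
  ctl$viability_percent <- 100 * (ctl$value - cs$mu_pos) / (cs$mu_neg - cs$mu_pos)
  as_tibble(ctl)
}
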