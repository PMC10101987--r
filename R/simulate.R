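# Synthetic screen generator. Emulates the screen design the analysis
# assumes: 94 single agents and 87 fixed-molar two-drug combinations,
# each on five ten-fold doses (1-10,000 nM), printed across up to four
# 384-well plates with vehicle and full-kill control wells, read out as
# luminescence with multiplicative lognormal noise. The generating 4PL
# parameters travel with the output as a truth table so every pipeline
# stage can be checked end to end.

#' Configuration for a simulated drug-sensitivity screen
#'
#' Defaults mirror the standard screen design: 94 single agents plus 87
#' combinations at five ten-fold concentrations from 1 to 10,000 nM on up
#' to four 384-well plates. Each plate carries 16 negative-control
#' (vehicle) and 16 positive-control (full kill) wells. Luminescence noise
#' is multiplicative lognormal with coefficient of variation `noise_cv`
#' (default 5%, typical well-to-well reproducibility of luminescent
#' viability assays); control wells are drawn from normals with the stated
#' means and SDs. The default control SDs (4% and 1% of the assay window
#' for negative and positive controls) give an expected Z'-factor of
#' 0.85, comfortably inside the >= 0.5 pass regime reported for this kind
#' of screen. True per-entry curve parameters are drawn uniformly from
#' the stated ranges.
#'
#' @param n_singles,n_combos Number of single-agent and combination
#'   entries (defaults 94 and 87).
#' @param min_nM,max_nM,n_points Concentration series design (defaults
#'   1-10,000 nM, 5 points).
#' @param noise_cv Multiplicative lognormal CV of treatment-well
#'   luminescence (default 0.05; 0 = noiseless).
#' @param mu_neg,sigma_neg,mu_pos,sigma_pos Control luminescence truth
#'   (relative luminescence units).
#' @param n_control_wells Control wells per role per plate (default 16).
#' @param max_plates Plate budget (default 4).
#' @param ec50_range,slope_range,top_range,bottom_range Uniform draw
#'   ranges for the true curve parameters (`ec50_range` on log10 nM).
#' @param seed Mandatory integer seed: identical configuration and seed
#'   reproduce identical output.
#' @return A list of class `sim_screen_config`.
#' @export
sim_screen_config <- function(n_singles = 94, n_combos = 87,
                              min_nM = 1, max_nM = 10000, n_points = 5,
                              noise_cv = 0.05,
                              mu_neg = 200000, sigma_neg = 7840,
                              mu_pos = 4000, sigma_pos = 1960,
                              n_control_wells = 16, max_plates = 4,
                              ec50_range = c(0.5, 3.5),
                              slope_range = c(0.8, 1.5),
                              top_range = c(98, 102),
                              bottom_range = c(0, 10),
                              seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  if (noise_cv < 0 || sigma_neg < 0 || sigma_pos < 0) {
    abort("Noise parameters must be non-negative.")
  }
  if (mu_neg <= mu_pos) abort("`mu_neg` must exceed `mu_pos`.")
  structure(
    list(n_singles = n_singles, n_combos = n_combos,
         min_nM = min_nM, max_nM = max_nM, n_points = n_points,
         noise_cv = noise_cv,
         mu_neg = mu_neg, sigma_neg = sigma_neg,
         mu_pos = mu_pos, sigma_pos = sigma_pos,
         n_control_wells = n_control_wells, max_plates = max_plates,
         ec50_range = ec50_range, slope_range = slope_range,
         top_range = top_range, bottom_range = bottom_range,
         seed = as.integer(seed)),
    class = "sim_screen_config"
  )
}

# Truth + library draw. Deterministic given cfg$seed.
sim_truth <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_singles + cfg$n_combos
  single_ids <- sprintf("drug_%03d", seq_len(cfg$n_singles))
  combo_ids <- sprintf("combo_%03d", seq_len(cfg$n_combos))
  ids <- c(single_ids, combo_ids)
  library <- tibble(
    entry_id = ids,
    kind = rep(c("single", "combination"), c(cfg$n_singles, cfg$n_combos)),
    component_1 = c(single_ids, sprintf("agent_%03d", seq_len(cfg$n_combos))),
    component_2 = c(rep(NA_character_, cfg$n_singles),
                    sprintf("agent_%03d", seq_len(cfg$n_combos) %% max(cfg$n_combos, 1) + 1)),
    min_nM = cfg$min_nM, max_nM = cfg$max_nM, n_points = as.integer(cfg$n_points)
  )
  library <- validate_library(library)
  truth <- tibble(
    entry_id = ids,
    kind = library$kind,
    top = runif(n, cfg$top_range[1], cfg$top_range[2]),
    bottom = runif(n, cfg$bottom_range[1], cfg$bottom_range[2]),
    log_ec50 = runif(n, cfg$ec50_range[1], cfg$ec50_range[2]),
    slope = runif(n, cfg$slope_range[1], cfg$slope_range[2])
  )
  list(library = library, truth = truth)
}

# Assign treatment wells (columns 1-22) and control wells (column 23 =
# negative, column 24 = positive) across plates.
sim_layout <- function(cfg, library) {
  n_assign <- sum(vapply(library$series, function(s) length(s$values_nM),
                         numeric(1)))
  per_plate <- 16 * 22
  n_plates <- ceiling(n_assign / per_plate)
  if (n_plates > cfg$max_plates) {
    abort(paste0("Screen needs ", n_plates, " plates for ", n_assign,
                 " treatment wells but only ", cfg$max_plates,
                 " are allowed."))
  }
  trt_wells <- as.vector(t(outer(PLATE_ROWS, 1:22, paste0)))
  assignments <- tidyr::unnest(
    tibble(
      entry_id = library$entry_id,
      conc_index = purrr::map(library$series,
                              function(s) seq_along(s$values_nM) - 1L)
    ),
    "conc_index"
  )
  assignments$plate_id <- sprintf("plate_%d", (seq_len(n_assign) - 1) %/% per_plate + 1)
  assignments$well <- trt_wells[(seq_len(n_assign) - 1) %% per_plate + 1]
  ctl_rows <- PLATE_ROWS[seq_len(cfg$n_control_wells)]
  controls <- tidyr::expand_grid(
    plate_id = sprintf("plate_%d", seq_len(n_plates)),
    tibble(
      well = c(paste0(ctl_rows, 23), paste0(ctl_rows, 24)),
      role = rep(c("negative_control", "positive_control"),
                 each = cfg$n_control_wells)
    )
  )
  dplyr::bind_rows(
    tibble(plate_id = assignments$plate_id, well = assignments$well,
           role = "treatment", entry_id = assignments$entry_id,
           conc_index = assignments$conc_index),
    tibble(plate_id = controls$plate_id, well = controls$well,
           role = controls$role, entry_id = NA_character_,
           conc_index = NA_integer_)
  )
}

#' Simulate a full drug-sensitivity screen
#'
#' Generates plate maps, raw luminescence plates, the drug library, and
#' the generating truth table for one screen. Treatment-well luminescence
#' is `mu_pos + (mu_neg - mu_pos) * v_true(x) / 100` times lognormal
#' noise with the configured CV (mean-1 parameterization); control wells
#' are drawn from the configured normals, floored at zero (plate readers
#' report non-negative luminescence).
#'
#' @param cfg A [sim_screen_config()].
#' @param truth Optional truth override (tibble like the generated one);
#'   used by [simulate_serial()] to drift potencies while keeping the
#'   rest of the screen identical.
#' @return A list of class `sim_screen`: `plate_maps`, `plates` (long
#'   tibble `plate_id`, `well`, `value`), `library`, `truth`, `cfg`.
#' @export
#' @examples
#' sim <- simulate_screen(sim_screen_config(n_singles = 4, n_combos = 2,
#'                                          seed = 1))
#' sim$truth
simulate_screen <- function(cfg, truth = NULL) {
  base <- sim_truth(cfg)
  library <- base$library
  if (is.null(truth)) truth <- base$truth
  map <- sim_layout(cfg, library)
  set.seed(cfg$seed + 1L)

  trt <- map[map$role == "treatment", ]
  idx <- match(trt$entry_id, truth$entry_id)
  x <- log10(purrr::map2_dbl(
    library$series[match(trt$entry_id, library$entry_id)],
    trt$conc_index,
    function(s, ci) s$values_nM[ci + 1]
  ))
  v_true <- fourpl(x, truth$top[idx], truth$bottom[idx],
                   truth$log_ec50[idx], truth$slope[idx])
  signal <- cfg$mu_pos + (cfg$mu_neg - cfg$mu_pos) * v_true / 100
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    signal <- signal * rlnorm(length(signal), meanlog = -sdlog^2 / 2,
                              sdlog = sdlog)
  }
  ctl <- map[map$role != "treatment", ]
  ctl_mu <- ifelse(ctl$role == "negative_control", cfg$mu_neg, cfg$mu_pos)
  ctl_sd <- ifelse(ctl$role == "negative_control", cfg$sigma_neg, cfg$sigma_pos)
  ctl_val <- if (all(ctl_sd == 0)) ctl_mu else rnorm(nrow(ctl), ctl_mu, ctl_sd)
  plates <- dplyr::bind_rows(
    tibble(plate_id = trt$plate_id, well = trt$well, value = pmax(signal, 0)),
    tibble(plate_id = ctl$plate_id, well = ctl$well, value = pmax(ctl_val, 0))
  ) |>
    dplyr::arrange(.data$plate_id, well_row(.data$well), well_col(.data$well))

  structure(
    list(plate_maps = map, plates = plates, library = library,
         truth = truth, cfg = cfg),
    class = "sim_screen"
  )
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("<sim_screen> ", nrow(x$truth), " entries (",
      sum(x$truth$kind == "single"), " single / ",
      sum(x$truth$kind == "combination"), " combination) on ",
      length(unique(x$plate_maps$plate_id)), " plate(s), seed ",
      x$cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Configuration for simulated serial samples
#'
#' Emulates the longitudinal design: one screen plus one phospho-flow
#' marker panel per sampling time-point (default T0-T4). Acquired
#' resistance and its reversal after treatment stop are modeled as
#' additive per-entry shifts of the true log-EC50 at each time-point
#' (`drift`); marker evolution as per-time-point multipliers on baseline
#' medians. The default marker panel follows the anti-apoptotic proteins
#' whose upregulation accompanies venetoclax resistance, with medians
#' rising sharply at T1 and partially reverting by T4.
#'
#' @param time_points Time-point labels (default `T0`...`T4`).
#' @param drift Tibble `entry_id`, `time_point`, `drift` of log10-EC50
#'   shifts; entries/time-points not listed drift by 0.
#' @param markers Tibble `marker`, `baseline`, `reference` of median
#'   fluorescence truth.
#' @param multipliers Tibble `marker`, `time_point`, `multiplier`
#'   (> 0) applied to the baseline median; defaults rise at T1 and decay
#'   toward baseline by T4.
#' @param flow_noise_cv Lognormal CV on simulated marker medians
#'   (default 0.05; 0 = noiseless). Reference medians are noiseless.
#' @param cofactor Arcsinh cofactor carried to downstream analysis.
#' @return A list of class `sim_serial_config`.
#' @export
sim_serial_config <- function(time_points = paste0("T", 0:4),
                              drift = NULL,
                              markers = NULL,
                              multipliers = NULL,
                              flow_noise_cv = 0.05,
                              cofactor = 150) {
  if (is.null(markers)) {
    markers <- tibble(
      marker = c("Bcl-2 (pS70)", "Bcl-2", "Mcl-1", "Bcl-xL"),
      baseline = c(50, 600, 55, 500),
      reference = c(10, 10, 10, 10)
    )
  }
  if (is.null(multipliers)) {
    multipliers <- tidyr::expand_grid(
      marker = markers$marker,
      tibble(time_point = time_points,
             multiplier = pmax(1, c(1, 5, 3.5, 2.5, 1.5))[seq_along(time_points)])
    )
  }
  if (is.null(drift)) {
    drift <- tibble(entry_id = character(0), time_point = character(0),
                    drift = numeric(0))
  }
  if (any(!is.finite(drift$drift))) abort("Drift shifts must be finite.")
  if (any(multipliers$multiplier <= 0)) abort("Multipliers must be > 0.")
  structure(
    list(time_points = time_points, drift = drift, markers = markers,
         multipliers = multipliers, flow_noise_cv = flow_noise_cv,
         cofactor = cofactor),
    class = "sim_serial_config"
  )
}

#' Simulate serial screens and flow tables across time-points
#'
#' One [simulate_screen()] per time-point with the configured potency
#' drift applied to the shared base truth (so only the drifted entries
#' change), plus a long flow-median table and its constant per-marker
#' reference medians.
#'
#' @param cfg A [sim_serial_config()].
#' @param screen_cfg A [sim_screen_config()]; its seed drives all
#'   randomness (per-time-point seeds are derived from it).
#' @return A list of class `sim_serial`: `screens` (named list of
#'   `sim_screen`), `flow` (tibble `sample`, `marker`, `median`),
#'   `flow_reference` (tibble `marker`, `median`), `cfg`, `screen_cfg`.
#' @export
simulate_serial <- function(cfg, screen_cfg) {
  base <- sim_truth(screen_cfg)
  screens <- list()
  for (i in seq_along(cfg$time_points)) {
    tp <- cfg$time_points[i]
    truth <- base$truth
    d <- cfg$drift[cfg$drift$time_point == tp, ]
    if (nrow(d) > 0) {
      j <- match(d$entry_id, truth$entry_id)
      truth$log_ec50[j] <- truth$log_ec50[j] + d$drift
    }
    cfg_t <- screen_cfg
    cfg_t$seed <- screen_cfg$seed + 1000L * i
    screens[[tp]] <- simulate_screen(cfg_t, truth = truth)
  }
  set.seed(screen_cfg$seed + 99L)
  flow <- tidyr::expand_grid(sample = cfg$time_points,
                             marker = cfg$markers$marker)
  flow <- dplyr::left_join(flow, cfg$markers, by = "marker")
  flow <- dplyr::left_join(
    flow, cfg$multipliers,
    by = c(sample = "time_point", "marker")
  )
  flow$median <- flow$baseline * flow$multiplier
  if (cfg$flow_noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$flow_noise_cv^2))
    flow$median <- flow$median *
      rlnorm(nrow(flow), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  structure(
    list(
      screens = screens,
      flow = flow[, c("sample", "marker", "median")],
      flow_reference = tibble(marker = cfg$markers$marker,
                              median = cfg$markers$reference),
      cfg = cfg, screen_cfg = screen_cfg
    ),
    class = "sim_serial"
  )
}

#' Write a simulated screen to disk
#'
#' Emits per-plate map CSVs, raw-plate CSVs (long dialect), the library
#' TSV and the truth table in exactly the formats the readers consume, so
#' a simulated screen can exercise the full file-based pipeline.
#'
#' @param sim A `sim_screen` from [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_sim_screen <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(library = file.path(dir, "library.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_library(sim$library, paths$library)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  for (pid in unique(sim$plate_maps$plate_id)) {
    mp <- file.path(dir, paste0(pid, "_map.csv"))
    rp <- file.path(dir, paste0(pid, ".csv"))
    write_plate_map(sim$plate_maps[sim$plate_maps$plate_id == pid, ], mp)
    readr::write_csv(
      sim$plates[sim$plates$plate_id == pid, c("well", "value")], rp,
      progress = FALSE
    )
    paths[[paste0(pid, "_map")]] <- mp
    paths[[pid]] <- rp
  }
  invisible(paths)
}
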