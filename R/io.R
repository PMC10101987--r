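VALID_ROLES <- c("treatment", "negative_control", "positive_control", "empty")

#' Read a plate map
#'
#' A plate map binds every used well of a 384-well plate to its role:
#' a drug treatment (library entry + concentration index), a negative
#' control (0.1% DMSO vehicle, defining 100% viability), a positive
#' control (100 uM benzethonium chloride full kill, defining 0% viability),
#' or empty. The file is a CSV with columns `well,role,entry_id,conc_index`
#' (header required; `conc_index` is 0-based into the entry's concentration
#' series; roles are parsed case-insensitively).
#'
#' @param path Path to the plate-map CSV.
#' @param plate_id Plate identifier; defaults to the file name without
#'   extension.
#' @return A tibble with columns `plate_id`, `well`, `role`, `entry_id`,
#'   `conc_index`.
#' @export
read_plate_map <- function(path, plate_id = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df) <- tolower(names(df))
  required <- c("well", "role")
  if (!all(required %in% names(df))) {
    abort("Plate map must have columns `well` and `role` (plus `entry_id`, `conc_index`).")
  }
  if (!"entry_id" %in% names(df)) df$entry_id <- NA_character_
  if (!"conc_index" %in% names(df)) df$conc_index <- NA_character_
  out <- tibble(
    plate_id = plate_id %||% sub("\\.[^.]*$", "", basename(path)),
    well = normalize_well(df$well),
    role = tolower(trimws(df$role)),
    entry_id = dplyr::na_if(trimws(dplyr::coalesce(df$entry_id, "")), ""),
    conc_index = suppressWarnings(as.integer(df$conc_index))
  )
  validate_plate_map(out)
}

validate_plate_map <- function(map) {
  dup <- map$well[duplicated(map$well)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate well(s) in plate map: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_role <- setdiff(unique(map$role), VALID_ROLES)
  if (length(bad_role) > 0) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", "),
                 ". Valid roles: ", paste(VALID_ROLES, collapse = ", ")))
  }
  trt <- map$role == "treatment"
  if (any(trt & (is.na(map$entry_id) | is.na(map$conc_index)))) {
    abort("Treatment wells must carry both `entry_id` and `conc_index`.")
  }
  map
}

#' Write a plate map
#'
#' Inverse of [read_plate_map()]: the written file read back reproduces the
#' well-to-role mapping exactly.
#'
#' @param map Plate-map tibble as returned by [read_plate_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(map, path) {
  readr::write_csv(map[, c("well", "role", "entry_id", "conc_index")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a drug library
#'
#' The library table mirrors the screen's compound annotation: one row per
#' entry (single agent or two-drug combination) with its concentration
#' range. Each entry is tested at `n_points` log-equispaced doses from
#' `min_nM` to `max_nM`; the standard design is five ten-fold steps over
#' 1-10,000 nM. Combinations use one fixed molar concentration series
#' shared by both components, identical to the single-agent series, so a
#' combination is scored as a single curve on that shared dose axis.
#'
#' @param path Path to a TSV with columns
#'   `entry_id,kind,component_1,component_2,min_nM,max_nM,n_points`.
#' @return A tibble with those columns plus a `series` list-column of
#'   [conc_series()] objects.
#' @export
read_library <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    entry_id = "c", kind = "c", component_1 = "c", component_2 = "c",
    min_nM = "d", max_nM = "d", n_points = "i"
  ), progress = FALSE)
  validate_library(df)
}

#' Validate a drug-library table built in code
#'
#' Checks and completes a library tibble (defaults: 5 points, 1-10,000
#' nM) and attaches the `series` list-column. [read_library()] is this
#' applied to a TSV.
#'
#' @param df Tibble with columns `entry_id`, `kind`, `component_1`,
#'   `component_2`, `min_nM`, `max_nM`, `n_points`.
#' @return The validated tibble with a `series` list-column.
#' @export
validate_library <- function(df) {
  df <- as_tibble(df)
  df$kind <- tolower(df$kind)
  bad_kind <- setdiff(unique(df$kind), c("single", "combination"))
  if (length(bad_kind) > 0) {
    abort(paste0("Unknown library entry kind(s): ",
                 paste(bad_kind, collapse = ", ")))
  }
  df$n_points <- ifelse(is.na(df$n_points), 5L, as.integer(df$n_points))
  df$min_nM <- ifelse(is.na(df$min_nM), 1, df$min_nM)
  df$max_nM <- ifelse(is.na(df$max_nM), 10000, df$max_nM)
  combo_missing <- df$kind == "combination" &
    (is.na(df$component_2) | df$component_2 == "")
  if (any(combo_missing)) {
    abort(paste0("Combination entries missing a second component: ",
                 paste(df$entry_id[combo_missing], collapse = ", ")))
  }
  if (any(df$min_nM >= df$max_nM)) {
    abort("Library entries must have min_nM < max_nM.")
  }
  if (anyDuplicated(df$entry_id)) {
    abort("Duplicate entry_id in library.")
  }
  df$series <- purrr::pmap(
    list(df$min_nM, df$max_nM, df$n_points, df$entry_id),
    function(lo, hi, n, id) conc_series_log(lo, hi, n, label = id)
  )
  df
}

#' Write a drug library
#'
#' @param library Library tibble as returned by [read_library()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  cols <- c("entry_id", "kind", "component_1", "component_2",
            "min_nM", "max_nM", "n_points")
  readr::write_tsv(library[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a raw plate of luminescence readouts
#'
#' Accepts either a long CSV (`well,value`) or a 16 x 24 matrix CSV whose
#' first column holds row letters A-P and whose header holds column numbers
#' 1-24; the dialect is auto-detected from the header. Values are relative
#' luminescence units (CellTiter-Glo readout) and must be non-negative and
#' numeric. Wells present in the file but absent from the plate map are
#' kept and flagged with a warning, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param plate_map Optional companion plate map (tibble from
#'   [read_plate_map()]) used to warn about unmapped wells.
#' @param plate_id Plate identifier; defaults to the file name without
#'   extension.
#' @return A tibble with columns `plate_id`, `well`, `value`.
#' @export
read_raw_plate <- function(path, plate_map = NULL, plate_id = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  plate_id <- plate_id %||% sub("\\.[^.]*$", "", basename(path))
  nm <- tolower(names(df))
  if (all(c("well", "value") %in% nm)) {
    names(df) <- nm
    wells <- normalize_well(df$well)
    values <- df$value
  } else {
    # matrix dialect: first column = row letters, remaining headers = 1..24
    col_heads <- suppressWarnings(as.integer(names(df)[-1]))
    if (anyNA(col_heads)) {
      abort("Unrecognized raw-plate format: expected `well,value` columns or a 16x24 matrix with numeric column headers.")
    }
    rows <- toupper(trimws(df[[1]]))
    wells <- as.vector(t(outer(rows, col_heads, paste0)))
    values <- as.vector(t(as.matrix(df[, -1])))
    wells <- normalize_well(wells)
  }
  parsed <- suppressWarnings(as.numeric(values))
  bad <- is.na(parsed)
  if (any(bad)) {
    abort(paste0("Non-numeric luminescence at well(s): ",
                 paste(wells[bad], collapse = ", ")))
  }
  if (any(parsed < 0)) {
    abort(paste0("Negative luminescence at well(s): ",
                 paste(wells[parsed < 0], collapse = ", ")))
  }
  out <- tibble(plate_id = plate_id, well = wells, value = parsed)
  if (anyDuplicated(out$well)) {
    abort(paste0("Duplicate well(s) in raw plate: ",
                 paste(unique(out$well[duplicated(out$well)]), collapse = ", ")))
  }
  if (!is.null(plate_map)) {
    unmapped <- setdiff(out$well, plate_map$well)
    if (length(unmapped) > 0) {
      warn(paste0(length(unmapped), " well(s) not in plate map (kept): ",
                  paste(head(unmapped, 10), collapse = ", ")))
    }
  }
  out
}
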