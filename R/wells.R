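# 384-well plate addressing: rows A-P, columns 1-24, no leading zeros.

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

#' All well addresses of a 384-well plate
#'
#' Addresses are generated row-major (A1, A2, ..., A24, B1, ...), the
#' dominant plate-reader convention.
#'
#' @return Character vector of length 384 (`"A1"` ... `"P24"`).
#' @export
#' @examples
#' head(plate_wells())
plate_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Validate and normalize well addresses
#'
#' Parses well addresses like `"B07"`-free `"B7"` or `"p24"` against the
#' 16 x 24 (384-well) layout. Parsing is case-insensitive; leading zeros in
#' the column number are rejected.
#'
#' @param well Character vector of well addresses.
#' @return Character vector of canonical addresses (upper-case row letter,
#'   no leading zeros).
#' @export
#' @examples
#' normalize_well(c("a1", "P24"))
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- stringr::str_match(well, "^([A-P])([1-9][0-9]?)$")
  bad <- is.na(m[, 1]) | suppressWarnings(as.integer(m[, 3])) > 24
  if (any(bad)) {
    abort(paste0(
      "Invalid well address(es) for a 384-well plate: ",
      paste(unique(well[bad]), collapse = ", ")
    ))
  }
  paste0(m[, 2], as.integer(m[, 3]))
}

well_row <- function(well) match(substr(well, 1, 1), PLATE_ROWS)
well_col <- function(well) as.integer(substr(well, 2, nchar(well)))
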