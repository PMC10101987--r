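# In-code fixtures: small plates, maps, and libraries built at test time.

# A minimal one-plate screen: n_entries entries x 5 doses in columns
# 1-22, controls in columns 23/24.
tiny_map <- function(n_entries = 4, n_doses = 5, n_ctl = 4) {
  rows <- LETTERS[1:16]
  trt_wells <- as.vector(t(outer(rows, 1:22, paste0)))
  n <- n_entries * n_doses
  stopifnot(n <= length(trt_wells))
  dplyr::bind_rows(
    tibble::tibble(
      plate_id = "p1",
      well = trt_wells[seq_len(n)],
      role = "treatment",
      entry_id = rep(sprintf("e%02d", seq_len(n_entries)), each = n_doses),
      conc_index = rep(0:(n_doses - 1), times = n_entries)
    ),
    tibble::tibble(
      plate_id = "p1",
      well = c(paste0(rows[seq_len(n_ctl)], 23), paste0(rows[seq_len(n_ctl)], 24)),
      role = rep(c("negative_control", "positive_control"), each = n_ctl),
      entry_id = NA_character_, conc_index = NA_integer_
    )
  )
}

# Raw plate matching tiny_map with exactly prescribed viability values
# (noiseless controls at mu_neg / mu_pos).
tiny_plate <- function(map, viability_by_entry, mu_neg = 100000, mu_pos = 2000) {
  trt <- map[map$role == "treatment", ]
  v <- mapply(function(id, ci) viability_by_entry[[id]][ci + 1],
              trt$entry_id, trt$conc_index)
  ctl <- map[map$role != "treatment", ]
  tibble::tibble(
    plate_id = map$plate_id[1],
    well = c(trt$well, ctl$well),
    value = c(mu_pos + (mu_neg - mu_pos) * v / 100,
              ifelse(ctl$role == "negative_control", mu_neg, mu_pos))
  )
}

tiny_library <- function(n_entries = 4, min_nM = 1, max_nM = 10000,
                         n_points = 5) {
  validate_library(tibble::tibble(
    entry_id = sprintf("e%02d", seq_len(n_entries)),
    kind = "single",
    component_1 = sprintf("e%02d", seq_len(n_entries)),
    component_2 = NA_character_,
    min_nM = min_nM, max_nM = max_nM, n_points = as.integer(n_points)
  ))
}
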