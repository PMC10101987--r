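test_that("well addresses parse case-insensitively and reject invalid ones", {
  expect_equal(normalize_well(c("a1", "P24", "h12")), c("A1", "P24", "H12"))
  expect_length(plate_wells(), 384)
  expect_error(normalize_well("Q1"), "Invalid well")
  expect_error(normalize_well("A25"), "Invalid well")
  expect_error(normalize_well("A01"), "Invalid well")  # no leading zeros
})

test_that("plate maps read, validate and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "well,role,entry_id,conc_index",
    "A1,negative_control,,",
    "A2,Positive_Control,,",
    "B1,treatment,ibrutinib,0",
    "b2,treatment,ibrutinib,1"
  ), path)
  map <- read_plate_map(path, plate_id = "p1")
  expect_equal(map$role[map$well == "A1"], "negative_control")
  expect_equal(map$role[map$well == "A2"], "positive_control")  # case-insensitive
  expect_equal(map$well[3:4], c("B1", "B2"))
  expect_equal(map$conc_index[map$well == "B2"], 1L)

  # round trip reproduces the well -> role mapping exactly
  out <- withr::local_tempfile(fileext = ".csv")
  write_plate_map(map, out)
  map2 <- read_plate_map(out, plate_id = "p1")
  expect_equal(map2, map)
})

test_that("plate map errors name the offending well", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,role,entry_id,conc_index",
               "A1,empty,,", "a1,empty,,"), dup)
  expect_error(read_plate_map(dup), "A1")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,role,entry_id,conc_index",
               "Z9,treatment,ibrutinib,1"), bad)
  expect_error(read_plate_map(bad), "Z9")
})

test_that("a full screen layout maps 94 x 5 treatment assignments", {
  map <- cllscreen:::sim_layout(
    sim_screen_config(n_singles = 94, n_combos = 0, seed = 1),
    tiny_library(94)
  )
  trt <- map[map$role == "treatment", ]
  expect_equal(nrow(trt), 94 * 5)
  expect_equal(nrow(dplyr::distinct(trt, entry_id, conc_index)), 470)
})

test_that("concentration series are validated and log-equispaced", {
  s <- conc_series_log(1, 10000, 5)
  expect_equal(s$values_nM, c(1, 10, 100, 1000, 10000))
  expect_equal(s$log10_values, 0:4)
  s2 <- conc_series_log(0.1, 1000, 5)  # copanlisib/dasatinib design
  expect_equal(s2$values_nM, c(0.1, 1, 10, 100, 1000), tolerance = 1e-12)
  expect_error(conc_series(c(10, 1)), "increasing")
  expect_error(conc_series(c(-1, 10)), "positive")
  expect_error(conc_series(5), "at least 2")
})

test_that("library TSVs parse singles and combinations with shared series", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "entry_id\tkind\tcomponent_1\tcomponent_2\tmin_nM\tmax_nM\tn_points",
    "venetoclax\tsingle\tvenetoclax\t\t1\t10000\t5",
    "copanlisib\tsingle\tcopanlisib\t\t0.1\t1000\t5",
    "idela+ven\tcombination\tidelalisib\tvenetoclax\t1\t10000\t5"
  ), path)
  lib <- read_library(path)
  expect_equal(nrow(lib), 3)
  expect_equal(lib$series[[1]]$values_nM, c(1, 10, 100, 1000, 10000))
  expect_equal(lib$series[[2]]$values_nM, c(0.1, 1, 10, 100, 1000),
               tolerance = 1e-12)
  expect_equal(lib$kind[3], "combination")
  expect_equal(lib$component_2[3], "venetoclax")
  # combination shares the single-agent series
  expect_equal(lib$series[[3]]$values_nM, lib$series[[1]]$values_nM)
})

test_that("library validation rejects bad entries", {
  bad_combo <- tibble::tibble(
    entry_id = "a+b", kind = "combination", component_1 = "a",
    component_2 = NA_character_, min_nM = 1, max_nM = 10000, n_points = 5L
  )
  expect_error(validate_library(bad_combo), "second component")
  bad_range <- tibble::tibble(
    entry_id = "x", kind = "single", component_1 = "x",
    component_2 = NA_character_, min_nM = 100, max_nM = 10, n_points = 5L
  )
  expect_error(validate_library(bad_range), "min_nM < max_nM")
})

test_that("generated library series have equal log10 dose ratios", {
  for (n in c(3, 5, 9)) {
    lib <- tiny_library(3, min_nM = 0.5, max_nM = 5000, n_points = n)
    for (s in lib$series) {
      expect_length(s$values_nM, n)
      steps <- diff(s$log10_values)
      expect_lt(max(abs(steps - steps[1])), 1e-9)
    }
  }
})

test_that("raw plates read in long and matrix dialects", {
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,value", "B2,154000", "B3,1000"), long)
  p <- read_raw_plate(long, plate_id = "p1")
  expect_equal(p$value[p$well == "B2"], 154000)

  mat <- withr::local_tempfile(fileext = ".csv")
  vals <- matrix(seq_len(384), nrow = 16, byrow = TRUE)
  writeLines(c(
    paste(c("row", 1:24), collapse = ","),
    sapply(1:16, function(i) paste(c(LETTERS[i], vals[i, ]), collapse = ","))
  ), mat)
  pm <- read_raw_plate(mat, plate_id = "m1")
  expect_equal(nrow(pm), 384)
  expect_equal(pm$value[pm$well == "A1"], 1)
  expect_equal(pm$value[pm$well == "P24"], 384)
  expect_equal(pm$value[pm$well == "B3"], 27)
})

test_that("raw plate errors name the bad well and unmapped wells warn", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,value", "C3,NA"), bad)
  expect_error(read_raw_plate(bad), "C3")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,value", "D4,-5"), neg)
  expect_error(read_raw_plate(neg), "D4")

  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,value", "A1,100", "F9,200"), ok)
  map <- tibble::tibble(plate_id = "p", well = "A1", role = "empty",
                        entry_id = NA_character_, conc_index = NA_integer_)
  expect_warning(p <- read_raw_plate(ok, plate_map = map), "F9")
  expect_equal(nrow(p), 2)  # kept, not dropped
})
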