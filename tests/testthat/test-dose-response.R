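std_series <- conc_series_log(1, 10000, 5)

test_that("4PL parameters are recovered exactly from noiseless curves", {
  v <- oracle_4pl(std_series$log10_values, 100, 0, 2, 1)
  expect_equal(v, c(99.0099009901, 90.9090909091, 50, 9.0909090909,
                    0.9900990099), tolerance = 1e-9)
  fit <- fit_4pl(std_series, v)
  expect_true(fit$converged)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$log_ec50, 2, tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6)
})

test_that("4PL fitting validates its inputs", {
  expect_error(fit_4pl(conc_series(c(1, 10, 100)), c(100, 50, 0)),
               "at least 4")
  expect_error(fit_4pl(std_series, c(100, 50, 0, NA, 1)), "finite")
  expect_error(fit_4pl(std_series, c(100, 50)), "one value per dose")
})

test_that("flat viability gives a flat fit and zero score", {
  fit <- fit_4pl(std_series, rep(100, 5))
  expect_true(fit$converged)
  expect_equal(predict(fit), rep(100, 5))
  res <- dss(fit, std_series)
  expect_equal(res$score, 0)
  expect_match(res$flags, "inactive")
  expect_true(is.na(res$x1))
})

test_that("median log-EC50 recovery stays within 0.25 under 5% noise", {
  set.seed(202)
  sdlog <- sqrt(log(1 + 0.05^2))
  errs <- replicate(200, {
    v_true <- oracle_4pl(std_series$log10_values, 100, 0, 2, 1.2)
    v <- v_true * rlnorm(5, -sdlog^2 / 2, sdlog)
    fit_4pl(std_series, v)$log_ec50 - 2
  })
  expect_lte(median(abs(errs)), 0.25)
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- fit_4pl(std_series, oracle_4pl(std_series$log10_values, 100, 0, 2, 1))
  td <- tidy(fit)
  expect_equal(td$term, c("top", "bottom", "log_ec50", "slope"))
  gl <- glance(fit)
  expect_equal(gl$ec50_nM, 100, tolerance = 1e-5)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a fully lethal curve scores at the cap with its flag", {
  fit <- fit_4pl(std_series, rep(0, 5))  # 100% inhibition everywhere
  res <- dss(fit, std_series)
  expect_equal(res$mdss3, 100 * 80 / 90, tolerance = 1e-9)  # 88.89 cap
  expect_match(res$flags, "complete_kill_at_min")
  expect_equal(res$x1, 0)
})

test_that("analytic DSS area matches the worked mid-window example", {
  fit <- fit_4pl(std_series, oracle_4pl(std_series$log10_values, 100, 0, 2, 1))
  res <- dss(fit, std_series)
  orc <- oracle_dss(100, 0, 2, 1)
  expect_equal(res$area, orc$area, tolerance = 1e-4)
  expect_equal(res$mdss3, orc$mdss3, tolerance = 1e-4)
  expect_equal(res$x1, orc$x1, tolerance = 1e-4)
})

test_that("analytic integration matches the trapezoid oracle on random curves", {
  set.seed(77)
  for (i in 1:100) {
    top <- runif(1, 60, 115)
    bottom <- runif(1, -10, min(top - 5, 60))
    m <- runif(1, -1, 5)
    slope <- runif(1, 0.2, 5)
    fit <- cllscreen:::new_fit4pl(top, bottom, m, slope, 0, TRUE,
                                  std_series$log10_values,
                                  oracle_4pl(std_series$log10_values,
                                             top, bottom, m, slope))
    for (rule in c("cap", "truncate")) {
      res <- dss(fit, std_series, dss_config(tail_rule = rule))
      orc <- oracle_dss(top, bottom, m, slope, tail_rule = rule)
      expect_equal(res$area, orc$area, tolerance = 1e-4)
    }
  }
})

test_that("scores respect the capped range and metric identities", {
  set.seed(88)
  for (i in 1:50) {
    top <- runif(1, 60, 115)
    bottom <- runif(1, -10, min(top - 5, 60))
    m <- runif(1, -1, 5)
    slope <- runif(1, 0.2, 5)
    fit <- cllscreen:::new_fit4pl(top, bottom, m, slope, 0, TRUE,
                                  std_series$log10_values,
                                  oracle_4pl(std_series$log10_values,
                                             top, bottom, m, slope))
    res <- dss(fit, std_series)
    expect_gte(res$score, 0)
    expect_lte(res$score, 100 * 80 / 90 + 1e-9)
    # width-factor identities hold by construction
    expect_equal(res$mdss3, res$dss1 * res$width, tolerance = 1e-12)
    expect_equal(res$dss3, res$dss2 * res$width, tolerance = 1e-12)
  }
})

test_that("mDSS3 never decreases as potency increases", {
  scores <- sapply(seq(4.5, -1.5, by = -0.5), function(m) {
    fit <- cllscreen:::new_fit4pl(100, 0, m, 1, 0, TRUE,
                                  std_series$log10_values,
                                  oracle_4pl(std_series$log10_values,
                                             100, 0, m, 1))
    dss(fit, std_series)$mdss3
  })
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("curves reaching threshold only near the top dose score near zero", {
  # push the EC50 beyond the window: x1 -> x_hi, width factor -> 0
  m_vals <- c(4.2, 4.5, 4.8)
  scores <- sapply(m_vals, function(m) {
    fit <- cllscreen:::new_fit4pl(100, 0, m, 1, 0, TRUE,
                                  std_series$log10_values,
                                  oracle_4pl(std_series$log10_values,
                                             100, 0, m, 1))
    dss(fit, std_series)$mdss3
  })
  expect_true(all(diff(scores) < 0))
  expect_lt(scores[3], 0.2)
})

test_that("truncate rule accrues no area beyond the viability-10 crossing", {
  fit <- cllscreen:::new_fit4pl(100, 0, 1, 2, 0, TRUE,
                                std_series$log10_values,
                                oracle_4pl(std_series$log10_values,
                                           100, 0, 1, 2))
  capd <- dss(fit, std_series, dss_config(tail_rule = "cap"))
  trun <- dss(fit, std_series, dss_config(tail_rule = "truncate"))
  expect_lt(trun$area, capd$area)
  expect_equal(capd$x2, trun$x2)
  # beyond x2 the capped integrand contributes exactly (c - t) = 80
  # inhibition points per log10 unit
  expect_equal(capd$area - trun$area, 80 * (4 - capd$x2), tolerance = 1e-9)
})

test_that("dss_config validates the activity window", {
  expect_error(dss_config(t = 95, f = 10), "Require")
  expect_error(dss_config(t = -1), "Require")
  expect_silent(dss_config(t = 0, f = 0))
})

test_that("score_screen ranks by potency and handles degenerate entries", {
  lib <- tiny_library(10)
  ec50 <- seq(0.2, 3.8, length.out = 10)
  viab <- purrr::map_dfr(1:10, function(i) {
    tibble::tibble(
      plate_id = "p1", entry_id = sprintf("e%02d", i), conc_index = 0:4,
      viability_percent = oracle_4pl(0:4, 100, 0, ec50[i], 1.1),
      n_wells = 1L
    )
  })
  scores <- score_screen(viab, lib)
  expect_equal(nrow(scores), 10)
  # DSS ranking matches the potency ordering
  expect_equal(scores$entry_id, sprintf("e%02d", 1:10))
  # identical curves score identically; all-100% entries stay with score 0
  lib2 <- tiny_library(3)
  viab2 <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(
      plate_id = "p1", entry_id = sprintf("e%02d", i), conc_index = 0:4,
      viability_percent = if (i == 3) rep(100, 5) else
        oracle_4pl(0:4, 100, 0, 2, 1),
      n_wells = 1L
    )
  })
  s2 <- score_screen(viab2, lib2)
  expect_equal(s2$score[s2$entry_id == "e01"], s2$score[s2$entry_id == "e02"])
  expect_equal(s2$score[s2$entry_id == "e03"], 0)
  expect_match(s2$flags[s2$entry_id == "e03"], "inactive")
  # incomplete dose series is skipped with a warning
  expect_warning(s3 <- score_screen(viab2[-1, ], lib2), "incomplete")
  expect_equal(nrow(s3), 2)
})
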