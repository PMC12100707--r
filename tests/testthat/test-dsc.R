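trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("baseline subtraction removes polynomial drift", {
  # pure linear ramp, no peak: residual indistinguishable from zero
  temp <- seq(-10, 60, length.out = 512)
  tg <- thermogram(temp, 0.3 + 0.01 * temp, scan_rate = 5)
  out <- subtract_baseline(tg, exclusion_window = c(15, 35))
  expect_lt(max(abs(out$heat_flow)), 1e-10)
  expect_true(out$baseline_corrected)
  # peak area preserved on a sloped baseline (trapezoid oracle)
  truth <- thermal_ground_truth(tm_true = 25, enthalpy = 30,
                                baseline_coeffs = c(0.5, 0.01))
  tg2 <- generate_thermogram(truth, scan_rate = 5, n_points = 4096)
  ref <- generate_thermogram(thermal_ground_truth(tm_true = 25,
                                                  enthalpy = 30),
                             scan_rate = 5, n_points = 4096)
  corr <- subtract_baseline(tg2, exclusion_window = c(10, 40))
  expect_equal(trapz(corr$temperature, corr$heat_flow),
               trapz(ref$temperature, ref$heat_flow),
               tolerance = 0.01)
  # degenerate windows
  expect_error(subtract_baseline(tg, c(-20, 70)), "inside")
  expect_error(subtract_baseline(tg, c(-9.9, 59.9)), "fewer than 8")
})

test_that("transition detection reads Tm at the peak maximum", {
  truth <- thermal_ground_truth(tm_true = 24, B = 0, enthalpy = 30)
  tg <- generate_thermogram(truth, scan_rate = 5, n_points = 2048)
  tg <- subtract_baseline(tg, c(14, 34))
  tr <- find_transition(tg, search_window = c(14, 34))
  expect_equal(tr$tm_measured, 24, tolerance = 0.01)
  expect_equal(tr$enthalpy, 30, tolerance = 0.02 * 30)
  expect_equal(tr$peak_height, peak_height_of(truth, 5), tolerance = 1e-3)
})

test_that("a skewed peak is read at its mode, not its centroid", {
  truth <- thermal_ground_truth(tm_true = 24, skew = 4, enthalpy = 30)
  tg <- generate_thermogram(truth, scan_rate = 5, n_points = 8192)
  tg <- subtract_baseline(tg, c(10, 45))
  tr <- find_transition(tg, search_window = c(10, 45))
  # brute-force argmax oracle on a dense analytic grid
  s <- truth$peak_width / (2 * sqrt(2 * log(2)))
  grid <- seq(20, 30, by = 1e-4)
  u <- (grid - 24) / s
  mode_oracle <- grid[which.max(dnorm(u) * pnorm(truth$skew * u))]
  centroid <- 24 + s * truth$skew / sqrt(1 + truth$skew^2) * sqrt(2 / pi)
  expect_lt(abs(tr$tm_measured - mode_oracle), 0.15)
  expect_lt(abs(tr$tm_measured - mode_oracle),
            abs(tr$tm_measured - centroid))
})

test_that("absence of a transition is an error, not a number", {
  temp <- seq(-10, 60, length.out = 512)
  set.seed(1)
  tg <- thermogram(temp, rnorm(512, 0, 0.01), scan_rate = 5,
                   baseline_corrected = TRUE)
  expect_error(find_transition(tg, search_window = c(15, 35)),
               "no transition")
})

test_that("scan-rate model recovers kinetic parameters", {
  # rate-independent limit
  m0 <- fit_scan_rate_model(data.frame(scan_rate = c(2, 5, 10),
                                       tm = c(21, 21, 21)))
  expect_equal(m0$B, 0, tolerance = 1e-8)
  expect_equal(m0$tm_equilibrium, 21, tolerance = 1e-8)
  # z fixed: closed-form linear fit, exact on noise-free data
  rates <- c(2, 5, 10)
  mz <- fit_scan_rate_model(data.frame(scan_rate = rates,
                                       tm = 20 + 0.5 * rates),
                            fix_z = 1)
  expect_equal(mz$tm_equilibrium, 20, tolerance = 1e-10)
  expect_equal(mz$B, 0.5, tolerance = 1e-10)
  # z free: compare against a dense grid-search oracle
  rates2 <- c(1, 2, 5, 10)
  tm2 <- 20 + 0.3 * rates2^1.5
  mf <- fit_scan_rate_model(data.frame(scan_rate = rates2, tm = tm2))
  zgrid <- seq(0.5, 2.5, by = 1e-5)
  sse <- vapply(zgrid, function(z) {
    X <- cbind(1, rates2^z)
    sum(stats::lm.fit(X, tm2)$residuals^2)
  }, numeric(1))
  z_oracle <- zgrid[which.min(sse)]
  expect_equal(mf$z, 1.5, tolerance = 1e-6)
  expect_equal(z_oracle, 1.5, tolerance = 1e-4)
  expect_equal(mf$tm_equilibrium, 20, tolerance = 1e-6)
  expect_equal(mf$B, 0.3, tolerance = 1e-6)
  # replicates at duplicate rates are averaged, not rejected
  dup <- data.frame(scan_rate = rep(rates, each = 2),
                    tm = 20 + 0.5 * rep(rates, each = 2) + c(-0.01, 0.01))
  md <- fit_scan_rate_model(dup, fix_z = 1)
  expect_equal(md$tm_equilibrium, 20, tolerance = 1e-6)
  expect_error(fit_scan_rate_model(data.frame(scan_rate = c(2, 5),
                                              tm = c(21, 22))),
               "at least 3")
})

test_that("kinetic correction removes the scan-rate shift", {
  m <- fit_scan_rate_model(data.frame(scan_rate = c(2, 5, 10),
                                      tm = 20 + 0.5 * c(2, 5, 10)),
                           fix_z = 1)
  expect_equal(correct_tm(22.5, 5, m), 20, tolerance = 1e-8)
  expect_equal(correct_tm(21.3, 0, m), 21.3)  # beta = 0: unchanged
  # sub-zero corrected values are physical (e.g. pure POPG)
  expect_lt(correct_tm(1.0, 10, m), 0)
})

test_that("candidate screening applies the cap and tolerance rule", {
  refs <- data.frame(name = c("Native", "Polar"), tm = c(22.7, 20.7),
                     uncertainty = c(0.3, 0.4))
  sel <- select_candidates(c(A = 21.0, B = 28.0, C = 12.0), refs,
                           tolerance = 1.5, tm_max = 30)
  expect_identical(sel$mixture, "A")
  # exact match ranks first with distance 0
  sel2 <- select_candidates(c(X = 22.7, Y = 21.5), refs, tolerance = 1.5)
  expect_identical(sel2$mixture[1], "X")
  expect_equal(sel2$distance[1], 0)
  # hard cap beats any tolerance
  sel3 <- select_candidates(c(H = 35), data.frame(tm = 35, uncertainty = 1),
                            tolerance = 50, tm_max = 30)
  expect_equal(nrow(sel3), 0L)
  expect_equal(nrow(select_candidates(numeric(0), refs, 1.5)), 0L)
})

test_that("full DSC chain round-trips the generated ground truth", {
  truth <- thermal_ground_truth(tm_true = 21, B = 0.4, z = 1.2)
  rates <- c(2, 5, 10)
  tms <- vapply(rates, function(beta) {
    tg <- generate_thermogram(truth, scan_rate = beta, n_points = 2048)
    tg <- subtract_baseline(tg, c(11, 36))
    find_transition(tg, search_window = c(11, 36))$tm_measured
  }, numeric(1))
  expect_equal(tms, truth$tm_true + truth$B * rates^truth$z,
               tolerance = 0.02)
  model <- fit_scan_rate_model(data.frame(scan_rate = rates, tm = tms))
  expect_lt(abs(model$tm_equilibrium - 21), 0.1)
  expect_lt(abs(correct_tm(tms[2], 5, model) - 21), 0.1)
})

test_that("enthalpy estimate is invariant to baseline slope", {
  slopes <- c(-0.06, -0.01, 0, 0.01, 0.06)  # up to ~10x peak height / 10 degC
  ents <- vapply(slopes, function(sl) {
    truth <- thermal_ground_truth(tm_true = 25, enthalpy = 30,
                                  baseline_coeffs = c(0.2, sl))
    tg <- generate_thermogram(truth, scan_rate = 5, n_points = 4096)
    tg <- subtract_baseline(tg, c(15, 35))
    find_transition(tg, search_window = c(15, 35))$enthalpy
  }, numeric(1))
  expect_true(all(abs(ents - 30) / 30 < 0.02))
})
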