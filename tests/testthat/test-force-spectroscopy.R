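make_hard_curve <- function(invols = 20, z0 = 100, noise_frac = 0,
                            n = 600, z_max = 160, seed = 1) {
  # rigid wall: deflection (nm) = z - z0 past contact; stored in volts
  z <- seq(0, z_max, length.out = n)
  d_nm <- pmax(z - z0, 0)
  d_v <- d_nm / invols
  if (noise_frac > 0) {
    set.seed(seed)
    d_v <- d_v + rnorm(n, 0, noise_frac * max(d_v))
  }
  force_curve(z, d_v, rep("approach", n), spring_constant = 0.35,
              invols = NA, deflection_unit = "V")
}

test_that("InvOLS calibration inverts the rigid-contact slope", {
  expect_equal(calibrate_invols(make_hard_curve(invols = 20)), 20,
               tolerance = 1e-10)
  # unit slope: deflection already calibrated
  expect_equal(calibrate_invols(make_hard_curve(invols = 1)), 1,
               tolerance = 1e-10)
  # 1% noise: least-squares oracle agreement within 2%
  noisy <- make_hard_curve(invols = 20, noise_frac = 0.01, seed = 4)
  est <- calibrate_invols(noisy)
  expect_lt(abs(est - 20) / 20, 0.02)
  # all-baseline curve has no contact region
  flat <- force_curve(seq(0, 100, length.out = 200), rep(0, 200),
                      rep("approach", 200), spring_constant = 0.35)
  expect_error(calibrate_invols(flat), "contact region")
})

make_sho_psd <- function(k = 0.35, f0 = 10e3, Q = 3, floor = 1e-10,
                         temperature = 300, noise_frac = 0, seed = 1) {
  kb <- 1.380649e-5  # nN nm / K
  x2 <- kb * temperature / k            # nm^2
  A <- 2 * x2 / (pi * f0 * Q)
  f <- seq(2e3, 30e3, length.out = 2000)
  S <- floor + A * f0^4 / ((f^2 - f0^2)^2 + (f * f0 / Q)^2)
  if (noise_frac > 0) {
    set.seed(seed)
    S <- S * (1 + rnorm(length(f), 0, noise_frac))
  }
  data.frame(frequency = f, power = S)
}

test_that("thermal calibration recovers the spring constant", {
  psd <- make_sho_psd(k = 0.35)
  k <- spring_constant_thermal(psd, temperature = 300)
  expect_lt(abs(as.numeric(k) - 0.35) / 0.35, 0.05)
  # equipartition scaling: doubling <x^2> halves k
  psd2 <- psd
  psd2$power <- 2 * psd2$power
  k2 <- spring_constant_thermal(psd2, temperature = 300)
  expect_equal(as.numeric(k) / as.numeric(k2), 2, tolerance = 0.02)
  # flat spectrum has no resonance
  flat <- data.frame(frequency = psd$frequency,
                     power = rep(1e-10, nrow(psd)))
  expect_error(spring_constant_thermal(flat), "no resonance")
})

test_that("contact point detection finds the changepoint", {
  truth <- mechanical_ground_truth(force_noise_sd = 0)
  fc <- generate_force_curve(truth, seed = 1, retract = FALSE)
  dz <- 130 / 1299
  expect_lt(abs(detect_contact_point(fc) - 100), dz)
  # Monte-Carlo at 50 pN noise: median error below 2 nm
  noisy_truth <- mechanical_ground_truth(force_noise_sd = 0.05)
  errs <- vapply(1:60, function(s) {
    fc <- generate_force_curve(noisy_truth, seed = 400 + s,
                               retract = FALSE)
    detect_contact_point(fc) - 100
  }, numeric(1))
  expect_lt(median(abs(errs)), 2)
  # curve that starts in contact has no usable baseline
  in_contact <- generate_force_curve(
    mechanical_ground_truth(contact_point = 1, rupture_force = Inf,
                            force_noise_sd = 0),
    ramp = c(0, 20, 400), retract = FALSE)
  expect_error(detect_contact_point(in_contact), "in contact")
})

test_that("force-indentation transform obeys its limiting cases", {
  n <- 300
  z <- seq(0, 150, length.out = n)
  # rigid sample: all travel past contact goes into deflection -> delta = 0
  rigid <- force_curve(z, pmax(z - 100, 0), rep("approach", n),
                       spring_constant = 0.35)
  expect_true(all(abs(to_force_indentation(rigid, 100)$delta) < 1e-10))
  # free travel: no deflection -> delta = z - z0 (clipped at 0)
  free <- force_curve(z, rep(0, n), rep("approach", n),
                      spring_constant = 0.35)
  expect_equal(to_force_indentation(free, 100)$delta, pmax(z - 100, 0))
  # generator round trip: stored (delta, force) pairs are reproduced
  truth <- mechanical_ground_truth(force_noise_sd = 0)
  fc <- generate_force_curve(truth, seed = 2, retract = FALSE)
  di <- to_force_indentation(fc, truth$contact_point)
  expect_equal(di$delta, fc$meta$delta_model, tolerance = 1e-10)
  expect_equal(di$force, fc$meta$force_model, tolerance = 1e-10)
})

test_that("thin-film force matches an independent term-by-term evaluation", {
  # independent oracle: evaluate each polynomial term separately
  oracle <- function(d, Y, R, h) {
    hertz <- 16 / 9 * (Y * 1e-3) * sqrt(R) * d^1.5
    chi <- sqrt(R * d) / h
    terms <- cbind(1, 1.133 * chi, 1.497 * chi^2, 1.469 * chi^3,
                   0.755 * chi^4)
    hertz * rowSums(terms)
  }
  set.seed(42)
  n <- 1000
  Y <- runif(n, 1, 100); R <- runif(n, 5, 50); h <- runif(n, 2, 10)
  d <- runif(n) * pmin(R, h)
  got <- mapply(function(d, Y, R, h) thin_film_force(d, Y, R, h),
                d, Y, R, h)
  want <- oracle(d, Y, R, h)
  expect_lt(max(abs(got - want) / want), 1e-12)
  # limits and validity
  expect_identical(thin_film_force(0, 17.5, 12, 4.7), 0)
  hertz1 <- 16 / 9 * 17.5e-3 * sqrt(12) * 0.01^1.5
  expect_lt(abs(thin_film_force(0.01, 17.5, 12, 1e6) / hertz1 - 1), 1e-6)
  expect_equal(thin_film_force(1, 17.5, 12, 4.7), 0.3728, tolerance = 1e-3)
  expect_error(thin_film_force(13, 17.5, 12, 4.7), "validity")
})

test_that("thin-film force is monotonic in its physical arguments", {
  set.seed(7)
  for (i in 1:20) {
    Y <- runif(1, 5, 50); R <- runif(1, 8, 30); h <- runif(1, 3, 8)
    d <- seq(0.05, min(R, h), length.out = 50)
    f <- thin_film_force(d, Y, R, h)
    expect_true(all(diff(f) > 0))                               # delta up
    expect_true(all(thin_film_force(d, Y * 1.1, R, h) > f))     # Y up
    expect_true(all(thin_film_force(d, Y, R * 1.1, h) > f))     # R up
    expect_true(all(thin_film_force(d, Y, R, h * 1.1) < f))     # h up
  }
})

test_that("modulus fit recovers the generated Y", {
  truth <- mechanical_ground_truth(young_modulus = 20, force_noise_sd = 0)
  fc <- generate_force_curve(truth, seed = 1, retract = FALSE)
  di <- to_force_indentation(fc, truth$contact_point)
  rup <- detect_rupture(fc)
  keep <- seq_len(rup$index - 1L)
  fit <- fit_young_modulus(di$delta[keep], di$force[keep])
  expect_lt(abs(fit$young_modulus - 20) / 20, 0.001)
  # z-domain fit equally exact on noise-free data
  fitz <- fit_young_modulus(di$delta[keep], di$force[keep],
                            spring_constant = 0.35, float_contact = TRUE)
  expect_lt(abs(fitz$young_modulus - 20) / 20, 0.005)
  # data entirely beyond the tip radius is outside model validity
  expect_error(fit_young_modulus(seq(13, 20, by = 0.1),
                                 seq(1, 8, length.out = 71)),
               "validity window empty")
})

test_that("modulus recovery is unbiased at instrument-level noise", {
  mc <- mc_curve_recovery(17.5, 3.0, 60, base_seed = 7000L)
  expect_lt(abs(mean(mc$y) - 17.5) / 17.5, 0.05)
})

test_that("fitted moduli preserve the generative ordering", {
  ys <- c(5, 10, 17.5, 25.8, 40)
  fitted <- vapply(ys, function(y) {
    truth <- mechanical_ground_truth(young_modulus = y,
                                     rupture_force = Inf,
                                     force_noise_sd = 0)
    fc <- generate_force_curve(truth, ramp = c(0, 112, 1200),
                               retract = FALSE)
    di <- to_force_indentation(fc, truth$contact_point)
    fit_young_modulus(di$delta, di$force)$young_modulus
  }, numeric(1))
  expect_identical(order(fitted), seq_along(ys))
  expect_equal(cor(fitted, ys, method = "spearman"), 1)
})

test_that("rupture detector reads the force before the drop", {
  # monotonic elastic curve: no event
  truth_nr <- mechanical_ground_truth(rupture_force = Inf,
                                      force_noise_sd = 0)
  fc_nr <- generate_force_curve(truth_nr, ramp = c(0, 110, 800),
                                retract = FALSE)
  expect_false(detect_rupture(fc_nr)$detected)
  # constructed discontinuity at 3.0 nN, noise-free: exact
  truth <- mechanical_ground_truth(rupture_force = 3.0,
                                   force_noise_sd = 0)
  fc <- generate_force_curve(truth, retract = FALSE)
  rup <- detect_rupture(fc)
  expect_true(rup$detected)
  expect_equal(rup$rupture_force, 3.0)
  expect_gt(rup$drop_magnitude, 0.5)
  expect_lte(rup$drop_magnitude, rup$rupture_force)
})

test_that("rupture recovery is unbiased at instrument-level noise", {
  mc <- mc_curve_recovery(17.5, 3.4, 60, base_seed = 8000L)
  mc_sigma <- sd(mc$fr) / sqrt(length(mc$fr))
  expect_lt(abs(mean(mc$fr) - 3.4), 3 * mc_sigma)
})
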