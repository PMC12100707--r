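# shared fixtures, built in code

# checkerboard / circular masks
checkerboard <- function(rows, cols = rows) {
  outer(seq_len(rows), seq_len(cols), function(r, c) (r + c) %% 2 == 0)
}

circle_mask <- function(rows, cols = rows, radius = rows / 4) {
  outer(seq_len(rows) - rows / 2, seq_len(cols) - cols / 2,
        function(r, c) r^2 + c^2 <= radius^2)
}

# expected peak height (mW) of a noise-free synthetic thermogram
peak_height_of <- function(truth, scan_rate, lipid_amount = 1.3e-7) {
  s <- truth$peak_width / (2 * sqrt(2 * log(2)))
  area <- truth$enthalpy * lipid_amount * 1e6 * scan_rate / 60
  area * stats::dnorm(0, 0, s)
}

# single-curve analysis chain: contact point -> transform -> rupture ->
# thin-film fit on pre-rupture samples
analyze_curve <- function(curve, thickness = 4.7, min_drop = 0.5,
                          float_contact = TRUE) {
  z0 <- detect_contact_point(curve)
  di <- to_force_indentation(curve, z0)
  rup <- detect_rupture(curve, min_drop = min_drop)
  keep <- if (rup$detected) seq_len(rup$index - 1L) else seq_along(di$delta)
  fit <- fit_young_modulus(di$delta[keep], di$force[keep],
                           tip_radius = curve$tip_radius,
                           thickness = thickness,
                           float_contact = float_contact,
                           spring_constant = curve$spring_constant)
  list(z0 = z0, fit = fit, rupture = rup)
}

# Monte-Carlo batch of synthetic curves through the full chain, cached so
# the modulus and rupture checks share one simulation
.mc_cache <- new.env(parent = emptyenv())
mc_curve_recovery <- function(young_modulus, rupture_force, n_curves,
                              base_seed = 1000L) {
  key <- paste(young_modulus, rupture_force, n_curves, base_seed, sep = "|")
  if (!is.null(.mc_cache[[key]])) return(.mc_cache[[key]])
  truth <- mechanical_ground_truth(young_modulus = young_modulus,
                                   rupture_force = rupture_force)
  y <- fr <- rep(NA_real_, n_curves)
  for (i in seq_len(n_curves)) {
    curve <- generate_force_curve(truth, seed = base_seed + i,
                                  retract = FALSE)
    res <- analyze_curve(curve)
    if (res$fit$converged) y[i] <- res$fit$young_modulus
    if (res$rupture$detected) fr[i] <- res$rupture$rupture_force
  }
  out <- list(y = y[!is.na(y)], fr = fr[!is.na(fr)], truth = truth)
  .mc_cache[[key]] <- out
  out
}
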