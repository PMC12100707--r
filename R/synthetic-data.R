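#' Generate a synthetic DSC thermogram
#'
#' Simulates a heating scan of a lipid vesicle suspension: a polynomial
#' instrument baseline, an endothermic transition peak whose apparent
#' position is kinetically shifted to \code{tm_true + B * scan_rate^z}, and
#' additive Gaussian noise. The peak is a (optionally skewed) Gaussian whose
#' area encodes the transition enthalpy: in mW against deg C, the area
#' equals \code{enthalpy * lipid_amount * 1e6 * scan_rate / 60}, so that
#' integrating heat flow over time recovers \code{enthalpy * lipid_amount}.
#'
#' @param truth a [thermal_ground_truth()]
#' @param scan_rate heating rate beta (deg C/min), >= 0
#' @param t_range c(min, max) temperature window (deg C)
#' @param n_points number of samples
#' @param lipid_amount moles of lipid in the cell (mol)
#' @param seed integer seed; identical seeds give identical output
#' @param sample_id,replicate labels passed to the container
#' @return a [thermogram()] with \code{ground_truth} attached
#' @export
generate_thermogram <- function(truth, scan_rate, t_range = c(-10, 60),
                                n_points = 1024, lipid_amount = 1.3e-7,
                                seed = NULL, sample_id = "synthetic",
                                replicate = 1L) {
  stopifnot(inherits(truth, "thermal_ground_truth"))
  if (scan_rate < 0) stop("scan_rate must be non-negative")
  if (lipid_amount <= 0) stop("lipid_amount must be positive")
  tc <- truth$tm_true + truth$B * scan_rate^truth$z
  if (tc <= t_range[1] + truth$peak_width ||
      tc >= t_range[2] - truth$peak_width)
    stop(sprintf(paste0("apparent peak at %.2f degC falls outside the usable ",
                        "part of t_range [%g, %g]"), tc, t_range[1], t_range[2]))
  temp <- seq(t_range[1], t_range[2], length.out = n_points)
  s <- truth$peak_width / (2 * sqrt(2 * log(2)))
  # unit-area peak profile; area in mW*degC set by enthalpy normalisation
  area <- truth$enthalpy * lipid_amount * 1e6 * scan_rate / 60
  if (truth$skew == 0) {
    shape <- stats::dnorm(temp, tc, s)
  } else {
    u <- (temp - tc) / s
    shape <- 2 / s * stats::dnorm(u) * stats::pnorm(truth$skew * u)
  }
  baseline <- outer(temp, seq_along(truth$baseline_coeffs) - 1, `^`) %*%
    truth$baseline_coeffs
  noise <- with_seed(seed, rnorm(n_points, 0, truth$noise_sd))
  hf <- as.numeric(baseline) + area * shape + noise
  tg <- thermogram(temp, hf, scan_rate, sample_id = sample_id,
                   replicate = replicate, ground_truth = truth)
  tg$lipid_amount <- lipid_amount
  tg
}

# noise-free approach deflection (nm) at piezo positions z for a membrane
# with optional breakthrough; returns deflection, model (delta, force) pairs
# and the rupture sample index (NA if none)
.force_curve_model <- function(truth, z) {
  z0 <- truth$contact_point
  k <- truth$spring_constant
  h <- truth$thickness
  R <- truth$tip_radius
  Y <- truth$young_modulus
  Fr <- truth$rupture_force
  ftf <- function(d) thin_film_force(d, Y, R, h)

  delta_r <- NA_real_
  z_r <- Inf
  if (is.finite(Fr) && ftf(R) >= Fr) {
    delta_r <- uniroot(function(d) ftf(d) - Fr, c(0, R), tol = 1e-13)$root
    z_r <- z0 + delta_r + Fr / k
  }

  n <- length(z)
  d <- numeric(n)
  delta <- numeric(n)
  force <- numeric(n)
  membrane <- z > z0 & z < z_r
  substrate <- z >= z_r
  for (i in which(membrane)) {
    zz <- z[i] - z0
    up <- min(R, zz)
    g <- function(dd) dd + ftf(dd) / k - zz
    if (g(up) < 0)
      stop("ramp indents beyond model validity (delta > R) without rupture")
    delta[i] <- uniroot(g, c(0, up), tol = 1e-13)$root
    force[i] <- ftf(delta[i])
    d[i] <- force[i] / k
  }
  rupture_idx <- NA_integer_
  if (any(substrate)) {
    # constructed discontinuity: the last membrane sample carries exactly F_r
    im <- max(which(membrane), 0L)
    if (im > 0L) {
      d[im] <- Fr / k
      force[im] <- Fr
      delta[im] <- (z[im] - z0) - d[im]
      rupture_idx <- im
    }
    sub <- which(substrate)
    d[sub] <- pmax(0, z[sub] - z0 - h)
    force[sub] <- k * d[sub]
    delta[sub] <- pmin(z[sub] - z0 - d[sub], h)
  }
  list(deflection = d, delta = delta, force = force,
       ruptured = any(substrate) && !is.na(rupture_idx),
       rupture_idx = rupture_idx, z_rupture = z_r, delta_rupture = delta_r)
}

#' Generate a synthetic AFM force curve
#'
#' Simulates an approach/retract ramp on a supported membrane: a flat noisy
#' pre-contact baseline, an elastic thin-film contact branch obtained by
#' solving the force balance \code{k d = F(z - z0 - d)} with the
#' finite-thickness Hertz model [thin_film_force()], a discontinuous
#' breakthrough once the load reaches the rupture force (the tip lands on a
#' rigid substrate branch of cantilever-limited compliance), and a retract
#' segment without adhesion. Gaussian force noise is added to every sample.
#'
#' If the ramp ends before the rupture force is reached the curve is
#' generated without a breakthrough and \code{meta$ruptured} is FALSE.
#'
#' @param truth a [mechanical_ground_truth()]
#' @param ramp c(z_min, z_max, n_points) piezo ramp (nm, nm, count)
#' @param seed integer seed
#' @param retract logical; also generate the retract segment
#' @param position optional (x, y) map position (um)
#' @return a [force_curve()]; \code{meta} holds the ground truth, the
#'   noise-free per-sample (delta, force) model pairs for the approach, and
#'   the rupture flag
#' @export
generate_force_curve <- function(truth, ramp = c(0, 130, 1300), seed = NULL,
                                 retract = TRUE,
                                 position = c(NA_real_, NA_real_)) {
  stopifnot(inherits(truth, "mechanical_ground_truth"), length(ramp) == 3)
  n <- as.integer(ramp[3])
  if (n < 10L) stop("ramp needs at least 10 points")
  z_app <- seq(ramp[1], ramp[2], length.out = n)
  model <- .force_curve_model(truth, z_app)

  k <- truth$spring_constant
  d_app <- model$deflection
  if (retract) {
    z_ret <- rev(z_app)
    if (model$ruptured) {
      d_ret <- pmax(0, z_ret - truth$contact_point - truth$thickness)
    } else {
      d_ret <- rev(d_app)
    }
    z <- c(z_app, z_ret)
    d <- c(d_app, d_ret)
    segment <- rep(c("approach", "retract"), each = n)
  } else {
    z <- z_app
    d <- d_app
    segment <- rep("approach", n)
  }
  d <- d + with_seed(seed, rnorm(length(d), 0, truth$force_noise_sd / k))
  force_curve(z, d, segment, spring_constant = k,
              tip_radius = truth$tip_radius, position = position,
              meta = list(truth = truth, ruptured = model$ruptured,
                          rupture_idx = model$rupture_idx,
                          delta_model = model$delta,
                          force_model = model$force,
                          z_rupture = model$z_rupture))
}

#' Generate a synthetic AFM force map
#'
#' A grid of force curves drawn from two mechanical ground truths according
#' to a domain mask (TRUE pixels take \code{truth_b}, the taller
#' post-transition phase), plus a height channel offset by
#' \code{height_offset} on mask pixels with Gaussian height noise.
#' Ground-truth labels are stored alongside.
#'
#' @param truth_a [mechanical_ground_truth()] for mask == FALSE pixels
#'   (pre-transition phase)
#' @param truth_b [mechanical_ground_truth()] for mask == TRUE pixels
#'   (post-transition phase)
#' @param grid c(rows, cols)
#' @param domain_pattern logical rows x cols matrix
#' @param height_offset extra height of mask pixels (nm)
#' @param height_noise_sd height channel noise (nm)
#' @param ramp piezo ramp passed to [generate_force_curve()]
#' @param area scanned area (um^2)
#' @param seed integer seed controlling all pixels
#' @return a [force_map()] with \code{labels_true} filled
#' @export
generate_force_map <- function(truth_a, truth_b, grid = c(32, 32),
                               domain_pattern = NULL, height_offset = 0.6,
                               height_noise_sd = 0.05,
                               ramp = c(0, 130, 1300), area = 25,
                               seed = NULL) {
  rows <- grid[1]; cols <- grid[2]
  if (is.null(domain_pattern))
    domain_pattern <- matrix(FALSE, rows, cols)
  if (!all(dim(domain_pattern) == c(rows, cols)))
    stop("domain_pattern dimensions must equal the grid")
  npix <- rows * cols
  with_seed(seed, {
    pixel_seeds <- sample.int(.Machine$integer.max, npix)
    heights <- truth_a$thickness + height_offset * domain_pattern +
      matrix(rnorm(npix, 0, height_noise_sd), rows, cols)
  })
  # pixel spacing for (x, y) positions, map assumed square
  pitch <- sqrt(area) / cols
  curves <- vector("list", npix)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- (r - 1L) * cols + c
    truth <- if (domain_pattern[r, c]) truth_b else truth_a
    curves[[i]] <- generate_force_curve(truth, ramp = ramp,
                                        seed = pixel_seeds[i],
                                        retract = FALSE,
                                        position = c((c - 1) * pitch,
                                                     (r - 1) * pitch))
  }
  labels_true <- matrix(ifelse(domain_pattern, "post", "pre"), rows, cols)
  force_map(curves, dims = c(rows, cols), heights = heights, area = area,
            labels_true = labels_true,
            truth = list(pre = truth_a, post = truth_b,
                         mask = domain_pattern,
                         height_offset = height_offset))
}

#' Generate a synthetic AFM topography image
#'
#' Height field = planar tilt + patch step + Gaussian noise. The tilt is
#' specified in nm per um of lateral travel along x (columns) and y (rows).
#'
#' @param size c(rows, cols)
#' @param pixel_size lateral pixel size (nm/pixel)
#' @param patch_mask logical matrix marking membrane-patch pixels
#' @param patch_height patch step height (nm)
#' @param tilt c(x, y) plane slope (nm/um)
#' @param noise_sd height noise (nm)
#' @param seed integer seed
#' @return a [topo_image()] with the ground truth attached
#' @export
generate_topo_image <- function(size = c(512, 512), pixel_size = 2,
                                patch_mask = NULL, patch_height = 4.7,
                                tilt = c(0, 0), noise_sd = 0,
                                seed = NULL) {
  rows <- size[1]; cols <- size[2]
  if (is.null(patch_mask)) patch_mask <- matrix(FALSE, rows, cols)
  if (!all(dim(patch_mask) == c(rows, cols)))
    stop("patch_mask dimensions must equal size")
  x_um <- (seq_len(cols) - 1) * pixel_size / 1000
  y_um <- (seq_len(rows) - 1) * pixel_size / 1000
  plane <- outer(y_um * tilt[2], x_um * tilt[1], `+`)
  noise <- with_seed(seed, matrix(rnorm(rows * cols, 0, noise_sd), rows, cols))
  heights <- plane + patch_height * patch_mask + noise
  topo_image(heights, pixel_size,
             truth = list(patch_mask = patch_mask,
                          patch_height = patch_height, tilt = tilt,
                          noise_sd = noise_sd))
}
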