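#' Calibrate the inverse optical lever sensitivity (InvOLS)
#'
#' On an effectively rigid substrate (bare mica) all piezo travel past
#' contact converts to cantilever deflection, so the contact branch of the
#' raw deflection signal is a straight line in z. The InvOLS is the inverse
#' of that slope, estimated by a robust linear fit over the upper half of
#' the contact region (the part least affected by the contact onset).
#'
#' @param hard_curve a [force_curve()] acquired on a rigid substrate;
#'   deflection may be in volts or nm
#' @return InvOLS in nm/V (or a dimensionless deflection scale factor if
#'   the input deflection is already in nm)
#' @export
calibrate_invols <- function(hard_curve) {
  stopifnot(inherits(hard_curve, "force_curve"))
  i <- which(hard_curve$segment == "approach")
  i <- i[order(hard_curve$z_piezo[i])]
  z <- hard_curve$z_piezo[i]
  d <- hard_curve$deflection[i]
  nb <- max(10L, floor(length(d) * 0.25))
  m <- mean(d[seq_len(nb)]); s <- sd(d[seq_len(nb)])
  contact <- which(d > m + 5 * s + 1e-12)
  if (length(contact) < 10L)
    stop("contact region has fewer than 10 points; cannot calibrate InvOLS")
  # upper 50% of the contact branch by deflection
  upper <- contact[d[contact] >= median(d[contact])]
  if (length(upper) < 5L) upper <- contact
  ols <- lm(d[upper] ~ z[upper])
  slope <- if (sd(stats::residuals(ols)) < 1e-10 * max(abs(d[upper]))) {
    coef(ols)[[2]]  # perfect line: IRLS scale estimation cannot converge
  } else {
    coef(MASS::rlm(d[upper] ~ z[upper], maxit = 50))[[2]]
  }
  if (!is.finite(slope) || slope <= 0)
    stop("contact branch has non-positive slope; not a rigid-contact curve")
  1 / slope
}

#' Cantilever spring constant from the thermal noise spectrum
#'
#' Fits a simple-harmonic-oscillator line shape plus a white noise floor,
#' \deqn{S(f) = S_0 + \frac{A f_0^4}{(f^2 - f_0^2)^2 + (f f_0 / Q)^2},}
#' to the fundamental resonance of the deflection power spectral density.
#' The mean-square thermal displacement is the analytic area under the
#' fitted resonance, \eqn{\langle x^2\rangle = \pi A f_0 Q / 2}, and
#' equipartition gives \eqn{k = k_B T / \langle x^2\rangle}.
#'
#' @param psd data.frame with columns \code{frequency} (Hz) and
#'   \code{power} (one-sided PSD, nm^2/Hz, or V^2/Hz with \code{invols})
#' @param temperature absolute temperature (K)
#' @param invols nm/V conversion applied to the PSD when it is in V^2/Hz
#' @return spring constant k in N/m, with the fitted resonance parameters
#'   attached as attribute \code{"fit"}
#' @export
spring_constant_thermal <- function(psd, temperature = 300, invols = NULL) {
  psd <- as.data.frame(psd)
  if (!all(c("frequency", "power") %in% names(psd)))
    stop("psd must have columns frequency and power")
  f <- psd$frequency
  S <- psd$power
  if (!is.null(invols)) S <- S * invols^2
  floor0 <- median(S)
  imax <- which.max(S)
  if (S[imax] < 3 * floor0)
    stop("no resonance peak at least 3x above the noise floor")
  f0_0 <- f[imax]
  Q0 <- 3
  A0 <- (S[imax] - floor0) / Q0^2
  dat <- data.frame(f = f, S = S)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      S ~ S0 + A * f0^4 / ((f^2 - f0^2)^2 + (f * f0 / Q)^2),
      data = dat,
      start = list(S0 = floor0, A = A0, f0 = f0_0, Q = Q0),
      lower = c(S0 = 0, A = 0, f0 = min(f), Q = 0.1),
      upper = c(S0 = Inf, A = Inf, f0 = max(f), Q = 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("thermal spectrum fit failed: ", conditionMessage(e),
           call. = FALSE))
  p <- coef(fit)
  x2 <- pi * p[["A"]] * p[["f0"]] * p[["Q"]] / 2   # nm^2
  if (x2 <= 0) stop("fitted thermal displacement is non-positive")
  k <- .KB_NN_NM * temperature / x2                # nN/nm = N/m
  attr(k, "fit") <- list(S0 = p[["S0"]], A = p[["A"]], f0 = p[["f0"]],
                         Q = p[["Q"]], x2_mean = x2)
  k
}

#' Detect the tip-sample contact point of an approach curve
#'
#' Two-stage scheme: (1) baseline statistics from the first 25% of the
#' approach give a force threshold (mean + 2 sd); scanning backwards from
#' full indentation, the first sample whose force falls below that
#' threshold marks the coarse contact position. (2) The estimate is
#' refined by a piecewise constant-baseline / power-law changepoint fit,
#' \code{F = a} below z0 and \code{F = a + b (z - z0)^{3/2}} above,
#' minimising the residual sum of squares over a window around the coarse
#' position.
#'
#' @param curve a [force_curve()] with an approach segment of at least 200
#'   samples (so the baseline region holds the required >= 50 points)
#' @param refine_window c(below, above): fit window extent (nm) on either
#'   side of the coarse estimate
#' @return contact point z0 (nm)
#' @export
detect_contact_point <- function(curve, refine_window = c(15, 2)) {
  app <- approach_segment(curve)
  z <- app$z; fz <- app$force
  n <- length(z)
  nb <- floor(n * 0.25)
  if (nb < 50L)
    stop("approach segment lacks a usable baseline region ",
         "(need >= 50 pre-contact points)")
  m <- mean(fz[seq_len(nb)]); s <- sd(fz[seq_len(nb)])
  thr <- m + 2 * s + 1e-12
  i <- n
  while (i >= 1L && fz[i] >= thr) i <- i - 1L
  if (i == n)
    stop("no contact region: the curve never exceeds the baseline threshold")
  if (i <= nb)
    stop("curve appears to start in contact: the detected contact lies ",
         "inside the baseline region")
  z_coarse <- z[i]
  # changepoint refinement
  lo <- z_coarse - refine_window[1]
  hi <- z_coarse + refine_window[2]
  win <- which(z >= lo & z <= hi)
  if (length(win) < 10L) return(z_coarse)
  zw <- z[win]; fw <- fz[win]
  sse <- function(z0c) {
    u <- pmax(zw - z0c, 0)^1.5
    fit <- stats::lm.fit(cbind(1, u), fw)
    sum(fit$residuals^2)
  }
  cand <- seq(max(lo, z_coarse - 5), min(hi, z_coarse + 2),
              length.out = 81)
  vals <- vapply(cand, sse, numeric(1))
  best <- cand[which.min(vals)]
  step <- diff(cand[1:2])
  opt <- optimize(sse, interval = c(best - step, best + step))
  opt$minimum
}

#' Convert a raw approach curve to force-indentation data
#'
#' Standard AFM transform: force \code{F = k d}; indentation
#' \code{delta = (z - z0) - d}, clipped at zero before contact (the tip
#' cannot indent a sample it has not reached).
#'
#' @param curve a calibrated [force_curve()]
#' @param z0 contact point (nm), e.g. from [detect_contact_point()]
#' @return list with aligned arrays \code{delta} (nm), \code{force} (nN),
#'   and \code{z} (nm, approach order)
#' @export
to_force_indentation <- function(curve, z0) {
  app <- approach_segment(curve)
  d <- app$force / curve$spring_constant
  delta <- pmax((app$z - z0) - d, 0)
  list(delta = delta, force = app$force, z = app$z)
}

# thin-film force without the validity stop, for optimisers that probe
# slightly beyond delta = R
.thin_film_force_unchecked <- function(delta, Y, R, h) {
  delta <- pmax(delta, 0)
  chi <- sqrt(R * delta) / h
  corr <- 1 + 1.133 * chi + 1.497 * chi^2 + 1.469 * chi^3 + 0.755 * chi^4
  (16 / 9) * (Y * .MPA_PER_NN_NM2) * sqrt(R) * delta^1.5 * corr
}

# predicted force at piezo separations zeta = z - z0 for modulus Y:
# solves F = ftf(zeta - F/k) by tabulating zeta(delta) on a dense grid
# and interpolating back
.force_vs_separation <- function(zeta, Y, R, h, k, delta_max) {
  dg <- seq(0, delta_max, length.out = 512L)
  fg <- .thin_film_force_unchecked(dg, Y, R, h)
  zg <- dg + fg / k
  approx(c(-1e6, zg), c(0, fg), xout = zeta, rule = 2)$y
}

#' Fit the Young's modulus from force-indentation data
#'
#' Least-squares fit of the finite-thickness contact model
#' [thin_film_force()] over the validity window
#' \code{0 < delta <= min(R, max_fraction_of_h * h)} (indentation must stay
#' below the tip radius and shallow enough to remain in the linear elastic
#' regime of the film).
#'
#' When the spring constant is supplied, the fit is performed against the
#' piezo separation \code{zeta = delta + F/k = z - z0}, which is free of
#' deflection noise: for a membrane whose contact stiffness exceeds the
#' cantilever's, deflection noise contaminates the measured indentation
#' anticorrelated with the force, and a naive F-vs-delta regression is
#' attenuated. Refitting in the z-domain removes that errors-in-variables
#' bias. Without a spring constant the model is linear in Y and solved in
#' closed form directly against delta (exact on noise-free data).
#'
#' With \code{float_contact = TRUE} a small contact-point offset (bounded
#' +/- 2 nm) is fitted jointly, absorbing residual contact-detection error.
#'
#' @param delta indentation (nm)
#' @param force force (nN), same length; pass only pre-rupture samples
#' @param tip_radius R (nm)
#' @param thickness membrane thickness h (nm)
#' @param max_fraction_of_h upper fit bound as a fraction of h
#' @param float_contact also fit a contact offset (nm, bounded +/- 2 nm)
#' @param spring_constant cantilever k (N/m); enables the unbiased
#'   z-domain fit
#' @return object of class \code{indentation_fit}: \code{young_modulus}
#'   (MPa), \code{contact_offset} (nm), \code{fit_window} (nm),
#'   \code{rss} (nN^2), \code{converged}, \code{n_points}
#' @export
fit_young_modulus <- function(delta, force, tip_radius = 12,
                              thickness = 4.7, max_fraction_of_h = 0.75,
                              float_contact = FALSE,
                              spring_constant = NULL) {
  if (length(delta) != length(force))
    stop("delta and force must have equal length")
  upper <- min(tip_radius, max_fraction_of_h * thickness)
  sel <- which(delta > 0 & delta <= upper)
  if (!length(sel))
    stop("validity window empty: no samples with 0 < delta <= ",
         signif(upper, 3), " nm")
  if (length(sel) < 20L)
    stop("fewer than 20 samples inside the fit window")
  dd <- delta[sel]; ff <- force[sel]
  g <- .thin_film_force_unchecked(dd, 1, tip_radius, thickness)
  y_lin <- sum(ff * g) / sum(g^2)
  out <- list(young_modulus = y_lin, contact_offset = 0,
              fit_window = c(min(dd), max(dd)),
              rss = sum((ff - y_lin * g)^2), converged = TRUE,
              n_points = length(sel))
  y_start <- if (is.finite(y_lin) && y_lin > 0) y_lin else 1
  if (!is.null(spring_constant)) {
    # z-domain fit: abscissa zeta carries no deflection noise
    k <- spring_constant
    zeta <- dd + ff / k
    dmax <- upper * 1.5
    dat <- data.frame(zeta = zeta, ff = ff)
    lower <- c(Y = 1e-6, dz = if (float_contact) -2 else 0)
    upper_b <- c(Y = Inf, dz = if (float_contact) 2 else 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ff ~ .force_vs_separation(zeta - dz, Y, tip_radius, thickness,
                                  k, dmax),
        data = dat, start = list(Y = y_start, dz = 0),
        lower = lower, upper = upper_b,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- coef(fit)
      out$young_modulus <- p[["Y"]]
      out$contact_offset <- p[["dz"]]
      out$rss <- sum(stats::residuals(fit)^2)
    } else {
      out$converged <- FALSE
    }
  } else if (float_contact) {
    dat <- data.frame(dd = dd, ff = ff)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ff ~ .thin_film_force_unchecked(dd - dz, Y, tip_radius, thickness),
        data = dat,
        start = list(Y = y_start, dz = 0),
        lower = c(Y = 1e-6, dz = -2), upper = c(Y = Inf, dz = 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- coef(fit)
      out$young_modulus <- p[["Y"]]
      out$contact_offset <- p[["dz"]]
      out$rss <- sum(stats::residuals(fit)^2)
    } else {
      out$converged <- FALSE
    }
  }
  if (!is.finite(out$young_modulus) || out$young_modulus <= 0)
    out$converged <- FALSE
  structure(out, class = "indentation_fit")
}

#' @export
print.indentation_fit <- function(x, ...) {
  cat(sprintf("<indentation_fit> Y = %.2f MPa (%s), %d points, delta %.2f-%.2f nm, rss = %.3g nN^2\n",
              x$young_modulus,
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$fit_window[1], x$fit_window[2], x$rss))
  invisible(x)
}

#' Detect a membrane breakthrough (rupture) event
#'
#' Scans the approach segment for the first force drop larger than
#' \code{min_drop} occurring within a window of fewer than 5 samples while
#' the piezo advances; the event is then localised at the largest
#' single-step drop inside that window. The rupture force is the force
#' immediately before the drop. Absence of an event is a valid result, not
#' an error.
#'
#' @param curve a [force_curve()]
#' @param min_drop detection threshold (nN); default 0.5 nN, roughly ten
#'   times a typical instrument noise floor
#' @return object of class \code{rupture_event}: \code{detected},
#'   \code{rupture_force} (nN), \code{z_at_rupture} (nm),
#'   \code{drop_magnitude} (nN), \code{index} (approach sample index)
#' @export
detect_rupture <- function(curve, min_drop = 0.5) {
  app <- approach_segment(curve)
  fz <- app$force; z <- app$z
  n <- length(fz)
  none <- structure(list(detected = FALSE, rupture_force = NA_real_,
                         z_at_rupture = NA_real_,
                         drop_magnitude = NA_real_, index = NA_integer_),
                    class = "rupture_event")
  if (n < 6L) return(none)
  first_hit <- n + 1L
  for (w in 1:4) {
    dr <- fz[1:(n - w)] - fz[(1 + w):n]
    hit <- which(dr > min_drop)
    if (length(hit)) first_hit <- min(first_hit, hit[1])
  }
  if (first_hit > n) return(none)
  # localise at the largest single-step drop inside the trigger window
  jwin <- first_hit:min(n - 1L, first_hit + 4L)
  j <- jwin[which.max(fz[jwin] - fz[jwin + 1L])]
  drop <- fz[j] - min(fz[(j + 1L):min(n, j + 4L)])
  if (drop <= min_drop) j <- first_hit
  drop <- fz[j] - min(fz[(j + 1L):min(n, j + 4L)])
  structure(list(detected = TRUE, rupture_force = fz[j],
                 z_at_rupture = z[j], drop_magnitude = drop, index = j),
            class = "rupture_event")
}

#' @export
print.rupture_event <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<rupture_event> F_r = %.3f nN at z = %.1f nm (drop %.3f nN)\n",
                x$rupture_force, x$z_at_rupture, x$drop_magnitude))
  else cat("<rupture_event> no breakthrough detected\n")
  invisible(x)
}
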