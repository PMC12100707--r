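#' Subtract an instrument baseline from a thermogram
#'
#' Fits a polynomial (linear by default) to the heat flow at temperatures
#' outside \code{exclusion_window} — the region bracketing the transition
#' peak — and subtracts it over the full scan.
#'
#' @param t a [thermogram()]
#' @param exclusion_window c(lo, hi) in deg C; must lie inside the scanned
#'   range and bracket the peak
#' @param order polynomial order of the baseline model (default 1, linear)
#' @return the baseline-corrected [thermogram()], with
#'   \code{baseline_model} holding the fitted coefficients (constant term
#'   first)
#' @export
subtract_baseline <- function(t, exclusion_window, order = 1) {
  stopifnot(inherits(t, "thermogram"), length(exclusion_window) == 2)
  lo <- exclusion_window[1]; hi <- exclusion_window[2]
  if (lo >= hi) stop("exclusion_window must be increasing")
  if (lo < min(t$temperature) || hi > max(t$temperature))
    stop("exclusion_window must lie inside the scanned temperature range")
  outside <- t$temperature < lo | t$temperature > hi
  if (sum(outside) < 8L)
    stop("fewer than 8 points outside the exclusion window; ",
         "cannot model the baseline")
  fit <- lm(hf ~ poly(temp, degree = order, raw = TRUE),
            data = data.frame(temp = t$temperature[outside],
                              hf = t$heat_flow[outside]))
  pred <- cbind(1, poly(t$temperature, degree = order, raw = TRUE)) %*%
    coef(fit)
  t$heat_flow <- t$heat_flow - as.numeric(pred)
  t$baseline_corrected <- TRUE
  t$baseline_model <- unname(coef(fit))
  t
}

#' Locate the main transition in a baseline-corrected thermogram
#'
#' The apparent melting temperature is read at the highest point of the
#' endothermic peak: the global maximum of the (endo-positive) corrected
#' heat flow inside \code{search_window}, refined by quadratic
#' interpolation through the three samples either side of the discrete
#' maximum. The transition enthalpy is the numerically integrated peak
#' area converted to energy per mole using the scan rate
#' (mW * degC * 60 / beta = mJ of transition heat).
#'
#' @param t a baseline-corrected [thermogram()]
#' @param search_window c(lo, hi) deg C window containing the peak;
#'   defaults to the full scan
#' @param moles moles of lipid in the cell; taken from the thermogram's
#'   \code{lipid_amount} when absent
#' @return a list of class \code{transition_result}: \code{tm_measured}
#'   (deg C), \code{enthalpy} (kJ/mol, NA if moles unknown),
#'   \code{peak_height} (mW), \code{baseline_model}, \code{fit_window}
#' @export
find_transition <- function(t, search_window = NULL, moles = NULL) {
  stopifnot(inherits(t, "thermogram"))
  if (!t$baseline_corrected)
    warning("thermogram is not baseline-corrected; ",
            "apparent Tm may be biased by drift")
  if (is.null(search_window))
    search_window <- range(t$temperature)
  if (is.null(moles)) moles <- t$lipid_amount
  hf <- if (t$endo_positive) t$heat_flow else -t$heat_flow
  inside <- t$temperature >= search_window[1] &
    t$temperature <= search_window[2]
  if (sum(inside) < 7L) stop("search_window contains too few points")
  # noise floor from outside the window when possible, else from
  # first differences (robust to the peak itself)
  if (sum(!inside) >= 8L) {
    noise <- mad(hf[!inside])
  } else {
    noise <- mad(diff(hf)) / sqrt(2)
  }
  idx_in <- which(inside)
  imax <- idx_in[which.max(hf[idx_in])]
  peak <- hf[imax]
  if (noise > 0 && peak < 5 * noise)
    stop("no transition: no maximum exceeding 5x the residual noise")
  # quadratic refinement around the discrete maximum; the window scales
  # with the peak width (half-maximum crossings) so the vertex estimate
  # averages noise over the cap of the peak
  half_lo <- which(hf[seq_len(imax)] < peak / 2)
  half_hi <- which(hf[imax:length(hf)] < peak / 2)
  fwhm <- if (length(half_lo) && length(half_hi)) {
    t$temperature[imax + min(half_hi) - 1L] - t$temperature[max(half_lo)]
  } else NA_real_
  spacing <- median(diff(t$temperature))
  halfw <- max(3 * spacing,
               if (is.finite(fwhm)) 0.35 * fwhm else 0)
  sel <- which(t$temperature >= t$temperature[imax] - halfw &
                 t$temperature <= t$temperature[imax] + halfw &
                 inside)
  tw <- t$temperature[sel]; hw <- hf[sel]
  qfit <- lm(hw ~ tw + I(tw^2))
  a <- coef(qfit)[[3]]; b <- coef(qfit)[[2]]
  if (is.finite(a) && a < 0) {
    tm <- -b / (2 * a)
    # keep the vertex inside the refinement window
    if (tm < min(tw) || tm > max(tw)) tm <- t$temperature[imax]
    peak <- max(peak, predict(qfit, data.frame(tw = tm)))
  } else {
    tm <- t$temperature[imax]
  }
  # trapezoidal peak area inside the window (mW * degC)
  area <- sum(diff(t$temperature[idx_in]) *
                (head(hf[idx_in], -1) + tail(hf[idx_in], -1)) / 2)
  enthalpy <- NA_real_
  if (!is.null(moles) && is.finite(moles) && moles > 0 && t$scan_rate > 0)
    enthalpy <- area * 60 / t$scan_rate * 1e-6 / moles
  structure(list(tm_measured = unname(tm), enthalpy = enthalpy,
                 peak_height = unname(peak),
                 baseline_model = t$baseline_model,
                 fit_window = search_window, scan_rate = t$scan_rate,
                 sample_id = t$sample_id, replicate = t$replicate),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("<transition> %s: Tm = %.2f degC at beta = %g degC/min, dH = %s kJ/mol\n",
              x$sample_id, x$tm_measured, x$scan_rate,
              if (is.na(x$enthalpy)) "NA" else sprintf("%.1f", x$enthalpy)))
  invisible(x)
}

#' Fit the kinetic scan-rate model for the melting temperature
#'
#' Nonlinear least-squares fit of \eqn{T_{m,\beta} = T_m + B \beta^z} to
#' apparent melting temperatures measured at several heating rates. The
#' equilibrium (zero-rate) melting temperature is the extrapolated
#' intercept \eqn{T_m}. With \code{fix_z} supplied the model is linear in
#' \eqn{(T_m, B)} and solved directly; otherwise \eqn{z} is fitted freely
#' within (0, 3].
#'
#' Duplicate rates are first collapsed to their means (replicates), which
#' stabilises the nonlinear fit without changing the least-squares optimum
#' for balanced designs.
#'
#' @param points data.frame with columns \code{scan_rate} and \code{tm}
#'   (or a list of such pairs)
#' @param fix_z optional fixed exponent z
#' @return object of class \code{scan_rate_model}: \code{tm_equilibrium},
#'   \code{B}, \code{z}, \code{covariance} (3 x 3, rows/cols tm, B, z; the
#'   z row/col is NA when z was fixed), \code{n_rates}
#' @export
fit_scan_rate_model <- function(points, fix_z = NULL) {
  points <- as.data.frame(points)
  if (!all(c("scan_rate", "tm") %in% names(points)))
    stop("points must have columns scan_rate and tm")
  if (any(points$scan_rate < 0)) stop("scan rates must be non-negative")
  # collapse replicates at duplicate rates to their means
  agg <- stats::aggregate(tm ~ scan_rate, data = points, FUN = mean)
  w <- as.numeric(table(points$scan_rate)[as.character(agg$scan_rate)])
  n_rates <- nrow(agg)
  need <- if (is.null(fix_z)) 3L else 2L
  if (n_rates < need)
    stop(sprintf("need at least %d distinct scan rates (%d supplied)",
                 need, n_rates))
  cov3 <- matrix(NA_real_, 3, 3,
                 dimnames = list(c("tm", "B", "z"), c("tm", "B", "z")))
  if (is.null(fix_z) && diff(range(agg$tm)) < 1e-10) {
    # rate-independent limit: flat data pins B = 0, z unidentifiable
    return(structure(list(tm_equilibrium = sum(w * agg$tm) / sum(w),
                          B = 0, z = 1, z_fixed = FALSE,
                          covariance = cov3, n_rates = n_rates,
                          residuals = rep(0, n_rates)),
                     class = "scan_rate_model"))
  }
  if (!is.null(fix_z)) {
    if (fix_z <= 0) stop("fix_z must be positive")
    X <- cbind(1, agg$scan_rate^fix_z)
    fit <- stats::lm.wfit(X, agg$tm, w)
    est <- fit$coefficients
    dof <- n_rates - 2L
    if (dof > 0) {
      s2 <- sum(w * fit$residuals^2) / dof
      V <- s2 * solve(crossprod(X * sqrt(w)))
      cov3[1:2, 1:2] <- V
    }
    model <- list(tm_equilibrium = est[[1]], B = est[[2]], z = fix_z,
                  z_fixed = TRUE, covariance = cov3, n_rates = n_rates,
                  residuals = unname(fit$residuals))
  } else {
    # start from the fix_z = 1 linear solution
    X <- cbind(1, agg$scan_rate)
    st <- stats::lm.wfit(X, agg$tm, w)$coefficients
    dat <- data.frame(rate = agg$scan_rate, tm = agg$tm, w = w)
    fit <- tryCatch(
      minpack.lm::nlsLM(tm ~ tm0 + B * rate^z, data = dat,
                        start = list(tm0 = st[[1]],
                                     B = if (abs(st[[2]]) > 1e-12) st[[2]] else 1e-3,
                                     z = 1),
                        lower = c(tm0 = -Inf, B = -Inf, z = 1e-3),
                        upper = c(tm0 = Inf, B = Inf, z = 3),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e)
        stop("scan-rate model did not converge: ", conditionMessage(e),
             call. = FALSE))
    est <- coef(fit)
    V <- tryCatch(vcov(fit), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V))) cov3[, ] <- V
    model <- list(tm_equilibrium = est[["tm0"]], B = est[["B"]],
                  z = est[["z"]], z_fixed = FALSE, covariance = cov3,
                  n_rates = n_rates,
                  residuals = unname(stats::residuals(fit)))
  }
  if (!is.finite(model$B) || !is.finite(model$z))
    stop("scan-rate model fit produced non-finite parameters")
  structure(model, class = "scan_rate_model")
}

#' @export
print.scan_rate_model <- function(x, ...) {
  cat(sprintf("<scan_rate_model> Tm(eq) = %.3f degC, B = %.4g, z = %.3f%s (%d rates)\n",
              x$tm_equilibrium, x$B, x$z,
              if (x$z_fixed) " (fixed)" else "", x$n_rates))
  invisible(x)
}

#' Correct an apparent melting temperature for scan-rate kinetics
#'
#' Removes the kinetic shift predicted by a fitted [fit_scan_rate_model()]:
#' \code{tm_measured - B * scan_rate^z}. A zero scan rate leaves the value
#' unchanged; negative corrected values are permitted (sub-zero melting
#' points are physical for unsaturated lipids).
#'
#' @param tm_measured apparent Tm (deg C), vectorised
#' @param scan_rate heating rate(s) beta (deg C/min)
#' @param model a \code{scan_rate_model}
#' @return corrected Tm (deg C)
#' @export
correct_tm <- function(tm_measured, scan_rate, model) {
  stopifnot(inherits(model, "scan_rate_model"))
  tm_measured - model$B * scan_rate^model$z
}

#' Screen candidate mixtures against reference melting temperatures
#'
#' Selects mixtures whose corrected Tm (i) stays below a hard cap
#' \code{tm_max} (membranes must be fluid at growth temperature) and (ii)
#' lies within \code{tolerance} plus the reference uncertainty of at least
#' one reference extract. Matches are ranked by distance to the nearest
#' reference.
#'
#' @param measured named numeric vector of corrected Tm per mixture
#' @param references data.frame with columns \code{tm} and
#'   \code{uncertainty} (and optionally \code{name})
#' @param tolerance matching tolerance (deg C), > 0
#' @param tm_max hard upper cap on Tm (deg C), default 30
#' @return data.frame (mixture, tm, nearest_ref, distance) sorted by
#'   distance; zero rows when nothing matches
#' @export
select_candidates <- function(measured, references, tolerance = 1.5,
                              tm_max = 30) {
  if (tolerance <= 0) stop("tolerance must be positive")
  references <- as.data.frame(references)
  if (!all(c("tm", "uncertainty") %in% names(references)))
    stop("references must have columns tm and uncertainty")
  if (!length(measured))
    return(data.frame(mixture = character(), tm = numeric(),
                      nearest_ref = character(), distance = numeric()))
  if (is.null(names(measured)))
    names(measured) <- paste0("mix", seq_along(measured))
  ref_names <- if ("name" %in% names(references)) references$name
               else paste0("ref", seq_len(nrow(references)))
  rows <- lapply(seq_along(measured), function(i) {
    tm <- measured[[i]]
    dists <- abs(tm - references$tm)
    ok <- tm < tm_max & any(dists <= tolerance + references$uncertainty)
    if (!ok) return(NULL)
    j <- which.min(dists)
    data.frame(mixture = names(measured)[i], tm = tm,
               nearest_ref = ref_names[j], distance = dists[j])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(mixture = character(), tm = numeric(),
                      nearest_ref = character(), distance = numeric()))
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
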