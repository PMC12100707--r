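#' Ground truth for synthetic DSC thermograms
#'
#' Bundles the parameters that define a simulated endothermic main
#' transition: the equilibrium melting temperature, the kinetic scan-rate
#' shift Tm(beta) = tm_true + B * beta^z, the transition enthalpy, the peak
#' shape, a polynomial instrument baseline and additive Gaussian noise.
#'
#' @param tm_true equilibrium melting temperature (deg C)
#' @param B kinetic shift amplitude (deg C * (deg C/min)^-z)
#' @param z kinetic shift exponent (dimensionless)
#' @param enthalpy transition enthalpy (kJ/mol), > 0 for an endotherm
#' @param peak_width full width at half maximum of the peak (deg C)
#' @param baseline_coeffs polynomial drift coefficients, constant term
#'   first (mW per deg C^k)
#' @param noise_sd additive Gaussian noise standard deviation (mW)
#' @param skew optional skew-normal shape parameter for the peak (0 = the
#'   default symmetric Gaussian)
#' @return object of class \code{thermal_ground_truth}
#' @export
thermal_ground_truth <- function(tm_true, B = 0, z = 1, enthalpy = 25,
                                 peak_width = 4, baseline_coeffs = c(0, 0),
                                 noise_sd = 0, skew = 0) {
  stopifnot(length(tm_true) == 1L, length(B) == 1L, length(z) == 1L)
  if (peak_width <= 0) stop("peak_width must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (enthalpy <= 0) stop("enthalpy must be positive for an endotherm")
  structure(list(tm_true = tm_true, B = B, z = z, enthalpy = enthalpy,
                 peak_width = peak_width, baseline_coeffs = baseline_coeffs,
                 noise_sd = noise_sd, skew = skew),
            class = "thermal_ground_truth")
}

#' Ground truth for synthetic AFM force curves
#'
#' Parameters of a simulated nanoindentation experiment on a supported
#' bilayer: film elasticity and thickness, tip geometry, cantilever
#' calibration, the breakthrough (rupture) force, the contact point along
#' the piezo axis, and the force noise floor.
#'
#' @param young_modulus Young's modulus Y (MPa)
#' @param thickness membrane thickness h (nm); plausible defaults < 20 nm
#' @param tip_radius tip radius R (nm); plausible defaults < 100 nm
#' @param spring_constant cantilever spring constant k (N/m)
#' @param rupture_force breakthrough force F_r (nN); \code{Inf} disables
#'   rupture
#' @param force_noise_sd Gaussian force noise standard deviation (nN)
#' @param contact_point piezo position z0 at tip-membrane contact (nm)
#' @return object of class \code{mechanical_ground_truth}
#' @export
mechanical_ground_truth <- function(young_modulus = 17.5, thickness = 4.7,
                                    tip_radius = 12, spring_constant = 0.35,
                                    rupture_force = 3.0,
                                    force_noise_sd = 0.05,
                                    contact_point = 100) {
  vals <- c(young_modulus, thickness, tip_radius, spring_constant,
            rupture_force, contact_point)
  if (any(vals <= 0)) stop("all mechanical ground-truth parameters must be positive")
  if (force_noise_sd < 0) stop("force_noise_sd must be non-negative")
  structure(list(young_modulus = young_modulus, thickness = thickness,
                 tip_radius = tip_radius, spring_constant = spring_constant,
                 rupture_force = rupture_force,
                 force_noise_sd = force_noise_sd,
                 contact_point = contact_point),
            class = "mechanical_ground_truth")
}
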