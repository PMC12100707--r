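#' Thin-film corrected Hertz contact force
#'
#' Force exerted by a spherical indenter of radius \code{R} pressed a depth
#' \code{delta} into an incompressible elastic film of thickness \code{h}
#' bonded-free on a rigid substrate:
#' \deqn{F = \frac{16}{9} Y \sqrt{R}\, \delta^{3/2}
#'   \left[1 + 1.133\chi + 1.497\chi^2 + 1.469\chi^3 + 0.755\chi^4\right],
#'   \qquad \chi = \frac{\sqrt{R\delta}}{h}.}
#' The 16/9 prefactor is the Hertz prefactor \eqn{(4/3) Y/(1-\nu^2) } at
#' Poisson ratio \eqn{\nu = 0.5} (volume-conserving membrane); the bracket is
#' the finite-thickness (non-bonded) correction polynomial. The model is
#' valid for \eqn{\delta \le R}.
#'
#' @param delta indentation depth (nm); vectorised, all values in [0, R]
#' @param young_modulus Young's modulus Y (MPa)
#' @param tip_radius tip radius of curvature R (nm)
#' @param thickness film (membrane) thickness h (nm)
#' @return force in nN, same length as \code{delta}
#' @examples
#' thin_film_force(1, young_modulus = 17.5, tip_radius = 12, thickness = 4.7)
#' @export
thin_film_force <- function(delta, young_modulus, tip_radius, thickness) {
  stopifnot(is.numeric(delta), length(young_modulus) == 1L,
            length(tip_radius) == 1L, length(thickness) == 1L)
  if (thickness <= 0) stop("membrane thickness must be positive")
  if (tip_radius <= 0) stop("tip radius must be positive")
  if (any(delta < 0, na.rm = TRUE))
    stop("indentation depth must be non-negative")
  if (any(delta > tip_radius, na.rm = TRUE))
    stop("model validity violated: indentation depth exceeds tip radius ",
         "(requires delta <= R)")
  chi <- sqrt(tip_radius * delta) / thickness
  corr <- 1 + 1.133 * chi + 1.497 * chi^2 + 1.469 * chi^3 + 0.755 * chi^4
  (16 / 9) * (young_modulus * .MPA_PER_NN_NM2) *
    sqrt(tip_radius) * delta^1.5 * corr
}

#' Area stretching modulus from Young's modulus (thin plate theory)
#'
#' Relates the in-plane area expansion modulus of a membrane to its
#' out-of-plane Young's modulus via \eqn{K_a = Y h / (2 (1 - \nu))}. For an
#' incompressible membrane (\eqn{\nu = 0.5}) this reduces to
#' \eqn{K_a = Y h}. The reported uncertainty is two standard deviations of
#' the propagated Y spread.
#'
#' @param young_modulus mean Young's modulus Y (MPa)
#' @param sd_young standard deviation of Y (MPa)
#' @param thickness membrane thickness h (nm); defaults to the measured
#'   fluid-bilayer patch thickness
#' @param poisson Poisson ratio nu in [0, 1)
#' @return object of class \code{elastic_result}: \code{ka} (N/m),
#'   \code{ka_uncertainty} (two standard deviations, N/m), and the inputs
#' @export
stretching_modulus <- function(young_modulus, sd_young = 0, thickness = 4.7,
                               poisson = 0.5) {
  stopifnot(length(young_modulus) == 1L, length(thickness) == 1L)
  if (poisson < 0 || poisson >= 1)
    stop("Poisson ratio must lie in [0, 1)")
  if (thickness <= 0) stop("thickness must be positive")
  if (sd_young < 0) stop("sd_young must be non-negative")
  # MPa * nm = 1e-3 N/m
  scale <- thickness / (2 * (1 - poisson)) * 1e-3
  structure(list(
    ka = young_modulus * scale,
    ka_uncertainty = 2 * sd_young * scale,
    inputs = list(young_modulus = young_modulus, sd_young = sd_young,
                  thickness = thickness, poisson = poisson)
  ), class = "elastic_result")
}

#' @export
print.elastic_result <- function(x, ...) {
  cat(sprintf("Stretching modulus Ka = %.4f +/- %.4f N/m (2 sd)\n",
              x$ka, x$ka_uncertainty))
  cat(sprintf("  from Y = %.2f MPa (sd %.2f), h = %.2f nm, nu = %.2f\n",
              x$inputs$young_modulus, x$inputs$sd_young,
              x$inputs$thickness, x$inputs$poisson))
  invisible(x)
}
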