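#' Candidate lipid mixture compositions
#'
#' The 18 candidate binary and ternary mixtures of POPE, POPG, DPPG and
#' cardiolipin (CL) screened as minimal models of the E. coli inner
#' membrane, in molar percent. Numbers index a stoichiometry; the letter
#' selects the PG source ("A" = POPG, "B" = DPPG). Reference constants,
#' not measurements.
#'
#' @return data.frame with columns mixture, POPE, POPG, DPPG, CL (molar %)
#' @export
mixture_table <- function() {
  df <- data.frame(
    mixture = c("1-A", "1-B", "2-A", "2-B", "3-A", "3-B", "4-A", "4-B",
                "5-A", "5-B", "6-A", "6-B", "7-A", "7-B", "8-A", "8-B",
                "9-A", "9-B"),
    POPE = c(80, 80, 75, 75, 70, 70, 60, 60, 80, 80, 75, 75, 70, 70,
             70, 70, 65, 65),
    POPG = c(20, 0, 25, 0, 30, 0, 40, 0, 15, 0, 20, 0, 25, 0, 20, 0,
             25, 0),
    DPPG = c(0, 20, 0, 25, 0, 30, 0, 40, 0, 15, 0, 20, 0, 25, 0, 20,
             0, 25),
    CL = c(0, 0, 0, 0, 0, 0, 0, 0, 5, 5, 5, 5, 5, 5, 10, 10, 10, 10),
    stringsAsFactors = FALSE)
  stopifnot(all(abs(rowSums(df[, -1]) - 100) < 0.01))
  df
}

#' Reference melting temperatures of E. coli membrane extracts
#'
#' Scan-rate-corrected (equilibrium) main transition temperatures of the
#' two commercial E. coli lipid extracts used as references for candidate
#' screening, with their standard deviations. Reference constants, not
#' measurements made by this package.
#'
#' @return data.frame with columns name, tm (deg C), uncertainty (deg C)
#' @export
ecoli_reference_tm <- function() {
  data.frame(name = c("Native", "Polar"),
             tm = c(22.7, 20.7),
             uncertainty = c(0.3, 0.4),
             stringsAsFactors = FALSE)
}

#' Reference nanomechanical values of the membrane phases
#'
#' Membrane-averaged Young's modulus and rupture force reported for the
#' fluid pretransition and the more ordered post-transition phase of the
#' reference and candidate membranes, plus the measured fluid-bilayer
#' patch thickness. Reference constants used to parameterise synthetic
#' validation data.
#'
#' @return list with \code{phases} (data.frame: phase, young_modulus in
#'   MPa, rupture_force in nN) and \code{patch_thickness} (nm)
#' @export
reference_mechanics <- function() {
  list(phases = data.frame(phase = c("pre", "post"),
                           young_modulus = c(17.5, 25.8),
                           rupture_force = c(3.0, 3.4),
                           stringsAsFactors = FALSE),
       patch_thickness = 4.7)
}
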