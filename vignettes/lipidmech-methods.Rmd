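---
title: "Methods: thermomechanical characterisation of model lipid membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermomechanical characterisation of model lipid membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmech)
```

## Scope

`lipidmech` implements the analysis chain used to decide whether a
candidate lipid mixture — e.g. a POPE/POPG/cardiolipin ternary — is a
faithful minimal model of the *E. coli* inner membrane. Two instruments
feed it: a differential scanning calorimeter (DSC), which reports the
main gel-to-fluid transition of vesicle suspensions, and an atomic force
microscope (AFM), which reports the out-of-plane elasticity, breakthrough
strength and topography of supported lipid bilayers (SLBs). Because raw
instrument data of this kind is rarely redistributable at usable
granularity, the package ships seeded synthetic-data generators with
embedded ground truth; every analysis stage is validated as a closed loop
against data whose answer is known.

Units are fixed package-wide: °C, °C/min, nm, nN, MPa, N/m, mW.
Conversions happen only at I/O boundaries.

## DSC: melting temperature and enthalpy

A thermogram is heat flow versus temperature at a fixed heating rate
$\beta$. The analysis proceeds in three steps.

**Baseline.** `subtract_baseline()` fits a polynomial (linear by default;
the order is a configuration option) to the heat flow *outside* a
user-declared exclusion window bracketing the peak, and subtracts it
everywhere. At least 8 points outside the window are required. The
linear default reflects typical instrument drift over a 70 °C scan;
nothing in the pipeline depends on the proprietary baseline algorithms
of vendor software.

**Transition.** `find_transition()` reads the apparent melting
temperature $T_{m,\beta}$ at the highest point of the endothermic peak
(endo-positive is the internal sign convention; file readers must declare
the convention of their source). The discrete maximum is refined by a
quadratic vertex fit. The refinement window scales with the peak: it
spans ±0.35 of the full width at half maximum (never fewer than ±3
samples). A fixed ±3-sample vertex is exact on noise-free data but
transmits instrument noise almost unattenuated into $T_m$; at a 2 %
peak-height noise level it leaves ~0.1 °C of jitter per scan, which the
zero-rate extrapolation below amplifies several-fold. Averaging the
vertex over the cap of the peak removes most of that jitter, and for a
symmetric peak introduces no bias. For visibly skewed peaks the wide
vertex is biased toward the heavy tail by ~0.1 °C; the estimate remains
an estimate of the peak *mode*, not the centroid. The transition
enthalpy is the trapezoidal peak area converted through the scan rate,
$\Delta H = A \cdot 60/\beta \cdot 10^{-6} / n_{\mathrm{mol}}$ (mW·°C to
kJ/mol), so it is invariant to the baseline slope by construction. A
maximum below 5× the residual noise is reported as "no transition"
rather than a number.

**Scan-rate correction.** Faster scans shift the apparent melting point.
The kinetic model
$$T_{m,\beta} = T_m + B\,\beta^{z}$$
is fitted across rates with `fit_scan_rate_model()`; the equilibrium
melting temperature is the $\beta \to 0$ intercept. $z$ is fitted freely
by default, bounded in $(0, 3]$, with the $z$-fixed linear solution
available (`fix_z`) for designs with only two rates. Replicates at
duplicate rates are collapsed to their means before the nonlinear fit.
Exactly rate-independent input (a zero-residual flat series) pins
$B = 0$ and leaves $z$ unidentifiable; that case returns the mean with
$B = 0$ rather than failing. `correct_tm()` subtracts the fitted shift;
negative corrected values are physical (unsaturated PG lipids melt below
0 °C).

**Screening.** `select_candidates()` applies the qualification rule: a
candidate mixture passes when its corrected $T_m$ (i) stays below a hard
cap (30 °C by default — the membrane must be fluid at the 37 °C growth
temperature) and (ii) lies within a tolerance plus the reference
uncertainty of at least one reference extract. Matches are ranked by
distance to the nearest reference.

## AFM force spectroscopy

**Calibration.** `calibrate_invols()` estimates the inverse optical
lever sensitivity from a force-distance curve on bare mica: on a rigid
substrate every nanometre of piezo travel past contact becomes
deflection, so the InvOLS is the inverse slope of the contact branch
(robust line fit over the upper half of the branch, where the contact
onset no longer matters). `spring_constant_thermal()` fits a simple
harmonic oscillator plus white noise floor,
$S(f) = S_0 + A f_0^4 / [(f^2 - f_0^2)^2 + (f f_0/Q)^2]$, to the thermal
deflection spectrum; the mean-square thermal displacement is the analytic
resonance area $\langle x^2 \rangle = \pi A f_0 Q / 2$ and equipartition
gives $k = k_B T / \langle x^2 \rangle$.

**Contact point.** The contact point $z_0$ is not directly observable
and the literature offers no single standard; `detect_contact_point()`
uses a deliberately swappable two-stage scheme. Stage one: baseline
statistics from the first 25 % of the approach define a force threshold
(mean + 2 sd); scanning backwards from full indentation, the first
sample below threshold is the coarse contact. Stage two: a changepoint
fit of a flat baseline joined to a $(z - z_0)^{3/2}$ power law, over a
window extending 15 nm before and 2 nm past the coarse estimate,
minimises the residual sum of squares over candidate $z_0$. The short
contact-side window matters: further from contact the deflection is no
longer negligible against the indentation and the force-versus-$z$ shape
departs from the 3/2 power law, which would bias the changepoint. With
the 2 nm window the noise-free bias is below one sample spacing and the
median error at a 50 pN noise floor is ~0.15 nm. A curve whose detected
contact falls inside the baseline-statistics region is rejected as
"starting in contact".

**Force-indentation transform.** `to_force_indentation()` applies the
standard transform $F = k d$, $\delta = (z - z_0) - d$, clipping
$\delta \ge 0$ before contact.

**Contact model.** For a thin incompressible film on a rigid support
indented by a sphere, `thin_film_force()` evaluates
$$F = \tfrac{16}{9}\, Y \sqrt{R}\, \delta^{3/2}
  \left[1 + 1.133\chi + 1.497\chi^2 + 1.469\chi^3 + 0.755\chi^4\right],
  \qquad \chi = \sqrt{R\delta}/h,$$
valid for $\delta \le R$. The $16/9$ prefactor is the Hertz prefactor at
Poisson ratio $\nu = 0.5$ (volume conserved under compression); the
bracket is the finite-thickness correction for a film free to slip on
its substrate, which reduces to Hertz as $h \to \infty$. Note the
convergence rate: the leading correction is $1.133\sqrt{R\delta}/h$, so
at $R = 12$ nm agreement with Hertz to $10^{-6}$ at $h = 10^6$ nm is only
reached for sub-ångström depths; limit checks are evaluated there.

**Modulus fit.** `fit_young_modulus()` fits $Y$ over the window
$0 < \delta \le \min(R,\, 0.75\,h)$: the model demands $\delta \le R$,
and capping at three quarters of the film thickness keeps the response
in the linear elastic regime rather than the steep substrate-dominated
rise. One subtlety dominates the noise behaviour. Deflection noise
$\varepsilon$ enters force and indentation *anticorrelated*
($F = k(d+\varepsilon)$, $\delta = (z - z_0) - d - \varepsilon$), and
because a supported bilayer's contact stiffness (several N/m) exceeds
the cantilever's (~0.35 N/m), most of the ramp is deflection, not
indentation. A naive regression of $F$ on measured $\delta$ is then an
errors-in-variables problem and attenuates $Y$ by tens of percent.
When the spring constant is supplied, the fit therefore uses the
reconstructed piezo separation $\zeta = \delta + F/k = z - z_0$, which
is noise-free, and fits the implicit response $F(\zeta; Y)$ (tabulated
on a 512-point indentation grid and interpolated; interpolation error is
~$10^{-5}$ relative). A small contact offset ($\pm 2$ nm) can be floated
jointly (`float_contact`) to absorb residual contact-detection error;
the batch pipeline enables it by default. Without a spring constant the
model is linear in $Y$ and solved in closed form against $\delta$ —
exact on noise-free data and useful as an independent cross-check.

**Rupture.** `detect_rupture()` looks for the first force drop larger
than `min_drop` within fewer than 5 samples of advancing piezo, then
pins the event at the largest single-step drop inside that trigger
window; the rupture force is the force immediately before the drop. The
0.5 nN default threshold is ~10× a typical 50 pN noise floor, making a
false trigger a >7σ event per comparison. Absence of rupture is a valid
result, not an error.

## Force maps and phase statistics

`process_map()` runs the single-curve chain over every pixel of a grid,
flags failed pixels (never dropping them silently), records the failure
count, and aborts if more than half the map fails — a symptom of bad
calibration, not bad pixels. `classify_phases()` assigns pixels to the
fluid pretransition or the more ordered post-transition phase. The
default channel is the height image: ordered domains stand 0.5–0.7 nm
taller, a larger and cleaner contrast than per-pixel modulus estimates
at realistic noise. The default method is a two-means threshold; a
two-component Gaussian mixture (posterior > 0.5) is available for both
channels. A channel is declared unimodal — one phase plus a flag — when
the two-means centre separation is below 3.2 within-cluster standard
deviations, because splitting a *unimodal* Gaussian at its centre already
produces a separation of ~2.65 within-cluster sd; demanding clearly more
avoids hallucinating domains in single-phase maps. The taller/stiffer
class is always labelled post-transition.

`phase_statistics()` reports per-phase boxplot statistics (quartiles by
linear interpolation; whiskers to the furthest datum within 1.5×IQR of
the quartiles) plus mean and sd, over converged pixels only; phases with
fewer than 3 values carry an undefined-spread flag.

`stretching_modulus()` converts the phase-mean modulus to the in-plane
area expansion modulus via thin plate theory,
$$K_a = \frac{Y h}{2(1-\nu)},$$
with $\nu = 0.5$ (so $K_a = Y h$) and $h$ defaulting to the measured
fluid-patch thickness of 4.7 nm; a per-phase thickness can be supplied
since ordered domains are taller. Reported uncertainty is two standard
deviations of the propagated $Y$ spread. The thin-plate framing treats
the bilayer as a homogeneous isotropic solid; it is the weakest
assumption in the chain and the reason these $K_a$ values should be read
comparatively rather than absolutely.

## Topography

`flatten()` removes the scanner background by per-row polynomial fits
(order 0–2) over unmasked pixels, then zeroes the substrate median —
masking the membrane patch is essential, otherwise the patch drags the
background fit. The operation is idempotent. `step_height()` takes the
median height difference between two disjoint regions with a pooled
MAD-based spread estimate; medians beat means here because patch-edge
pixels are neither substrate nor membrane.

## What the synthetic generators emulate — and what they do not

`generate_thermogram()` produces a (optionally skewed) Gaussian
endotherm whose area encodes the enthalpy, centred at
$T_m + B\beta^{z}$, on a polynomial baseline with Gaussian noise. Only
the peak position and area are consumed downstream, so the exact peak
shape is not load-bearing. `generate_force_curve()` solves the force
balance $kd = F_{\text{film}}((z - z_0) - d)$ per sample, renders the
breakthrough as an instantaneous drop — the last membrane sample carries
exactly the set rupture force — onto a rigid substrate branch of
cantilever-limited compliance, and adds Gaussian force noise everywhere.
`generate_force_map()` draws pixels from two mechanical ground truths by
a domain mask and offsets the height channel; `generate_topo_image()` is
plane tilt + patch step + noise. All generators are bit-reproducible
under a fixed seed.

Deliberately not modelled: thermal drift of the AFM, tip wear,
viscoelastic or rate-dependent contact, retract adhesion (excluded from
analysis by design), multilamellar peak splitting, and cooling-scan
hysteresis beyond the kinetic shift law. Closed-loop tests therefore
demonstrate estimator correctness under the stated noise model — they do
not certify performance on drifting instruments or dirty tips.

Instrument noise floors are not something one can take from published
figures; the defaults (50 pN force noise, 0.05 nm height noise) are
chosen as plausible for a commercial liquid-cell AFM and are stated
wherever they matter.

## Validation problem sizes and defaults

The shipped validation uses: 3 heating rates × 3 replicates at 2 %
peak-height noise for the DSC loop (equilibrium $T_m$ recovered to
≲0.1 °C); 200 curves per phase at 50 pN noise for modulus and rupture
recovery (mean modulus within ~2 %, rupture force unbiased); a 512×512
topography image for thickness recovery (±0.01 nm typical); and a 32×32
force map at a 0.6 nm height offset with 0.1 nm height noise for phase
classification (>95 % agreement). Key defaults: tip radius 12 nm
(manufacturer's nominal, treated as exact — consistent with a
comparative, same-tip measurement design), spring constant 0.35 N/m,
membrane thickness 4.7 nm, transition enthalpy 25 kJ/mol (mid-range for
single-peak lipid melting), fit cap $0.75\,h$, rupture threshold 0.5 nN.

## Known limitations

- The contact model assumes a locally spherical tip; pyramidal-tip
  corrections are out of scope.
- $K_a$ inherits the isotropic thin-plate idealisation; bending rigidity
  is not estimated.
- The mixture classifier assumes at most two phases; coexistence of
  three (e.g. near a triple point) would need a different model.
- File formats are the package's own versioned text/JSON containers;
  proprietary vendor formats are intentionally not parsed.
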