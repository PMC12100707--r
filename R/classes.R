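#' DSC thermogram container
#'
#' A single heating (or cooling) scan: temperature and heat-flow arrays
#' plus the metadata the analysis needs (scan rate for the kinetic
#' correction, sign convention, sample identity).
#'
#' @param temperature temperatures (deg C), strictly monotonic
#' @param heat_flow heat flow (mW), same length
#' @param scan_rate heating rate beta (deg C/min)
#' @param sample_id sample label
#' @param replicate replicate index
#' @param endo_positive logical; TRUE if endothermic peaks point up.
#'   Internally endo-positive is the canonical convention.
#' @param units heat-flow units string (recorded, not converted)
#' @param baseline_corrected logical flag set by [subtract_baseline()]
#' @param ground_truth optional [thermal_ground_truth()] for synthetic data
#' @return object of class \code{thermogram}
#' @export
thermogram <- function(temperature, heat_flow, scan_rate,
                       sample_id = "sample", replicate = 1L,
                       endo_positive = TRUE, units = "mW",
                       baseline_corrected = FALSE, ground_truth = NULL) {
  temperature <- as.numeric(temperature)
  heat_flow <- as.numeric(heat_flow)
  if (length(temperature) != length(heat_flow))
    stop("temperature and heat_flow must have equal length")
  if (length(temperature) < 16L)
    stop("thermogram needs at least 16 points")
  dt <- diff(temperature)
  if (!(all(dt > 0) || all(dt < 0)))
    stop("temperature must be strictly monotonic")
  if (!is.finite(scan_rate) || scan_rate < 0)
    stop("scan_rate must be a non-negative number")
  structure(list(temperature = temperature, heat_flow = heat_flow,
                 scan_rate = scan_rate, sample_id = sample_id,
                 replicate = as.integer(replicate),
                 endo_positive = isTRUE(endo_positive), units = units,
                 baseline_corrected = isTRUE(baseline_corrected),
                 baseline_model = NULL, ground_truth = ground_truth),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %s (rep %d): %d points, %.1f-%.1f degC, beta = %g degC/min%s\n",
              x$sample_id, x$replicate, length(x$temperature),
              min(x$temperature), max(x$temperature), x$scan_rate,
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' AFM force-distance curve container
#'
#' Raw piezo extension and cantilever deflection for an approach/retract
#' cycle, plus calibration constants. Deflection is stored in nm once
#' calibrated; photodiode volts are accepted when \code{deflection_unit =
#' "V"} together with an InvOLS to convert.
#'
#' @param z_piezo piezo extension (nm); larger z = tip closer to sample
#' @param deflection cantilever deflection (nm, or V if
#'   \code{deflection_unit = "V"})
#' @param segment character or factor, "approach"/"retract" per sample
#' @param spring_constant cantilever spring constant k (N/m = nN/nm)
#' @param tip_radius tip radius R (nm)
#' @param invols inverse optical lever sensitivity (nm/V); may be NA for
#'   curves already in nm
#' @param position optional (x, y) position in a map (um)
#' @param deflection_unit "nm" or "V"
#' @param meta free-form metadata list (generators store ground truth here)
#' @return object of class \code{force_curve}
#' @export
force_curve <- function(z_piezo, deflection, segment, spring_constant,
                        tip_radius = 12, invols = NA_real_,
                        position = c(NA_real_, NA_real_),
                        deflection_unit = c("nm", "V"), meta = list()) {
  deflection_unit <- match.arg(deflection_unit)
  z_piezo <- as.numeric(z_piezo)
  deflection <- as.numeric(deflection)
  segment <- as.character(segment)
  if (length(z_piezo) != length(deflection) ||
      length(z_piezo) != length(segment))
    stop("z_piezo, deflection and segment must have equal length")
  if (!all(segment %in% c("approach", "retract")))
    stop("segment labels must be 'approach' or 'retract'")
  for (seg in unique(segment)) {
    dz <- diff(z_piezo[segment == seg])
    if (length(dz) && !(all(dz >= 0) || all(dz <= 0)))
      stop("each segment must be monotonic in z_piezo")
  }
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("spring_constant must be positive")
  if (!is.na(invols) && invols <= 0) stop("invols must be positive")
  if (tip_radius <= 0) stop("tip_radius must be positive")
  structure(list(z_piezo = z_piezo, deflection = deflection,
                 segment = segment, spring_constant = spring_constant,
                 tip_radius = tip_radius, invols = invols,
                 position = position, deflection_unit = deflection_unit,
                 meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples (%d approach), k = %g N/m, R = %g nm%s\n",
              length(x$z_piezo), sum(x$segment == "approach"),
              x$spring_constant, x$tip_radius,
              if (isTRUE(x$meta$ruptured)) ", rupture event" else ""))
  invisible(x)
}

# deflection in nm regardless of stored unit
deflection_nm <- function(curve) {
  if (curve$deflection_unit == "V") {
    if (is.na(curve$invols))
      stop("deflection in volts but no InvOLS recorded")
    curve$deflection * curve$invols
  } else curve$deflection
}

# vertical force in nN over the whole curve
curve_force <- function(curve) curve$spring_constant * deflection_nm(curve)

# subset a curve to one segment, approach ordered with increasing z
approach_segment <- function(curve) {
  i <- which(curve$segment == "approach")
  if (!length(i)) stop("curve has no approach segment")
  i <- i[order(curve$z_piezo[i])]
  list(z = curve$z_piezo[i], force = curve_force(curve)[i], idx = i)
}

#' AFM force-map container
#'
#' A grid of force curves with a co-registered height channel. Per-pixel
#' analysis results and phase labels are filled in by [process_map()] and
#' [classify_phases()].
#'
#' @param curves list of [force_curve()] objects, row-major
#' @param dims c(rows, cols)
#' @param heights rows x cols matrix of membrane heights (nm)
#' @param area scanned area (um^2)
#' @param labels_true optional ground-truth phase label matrix
#' @param truth optional generator ground-truth list
#' @return object of class \code{force_map}
#' @export
force_map <- function(curves, dims, heights = NULL, area = 25,
                      labels_true = NULL, truth = NULL) {
  dims <- as.integer(dims)
  if (length(curves) != prod(dims))
    stop("number of curves must equal rows * cols")
  if (!length(curves)) stop("force map is empty")
  if (!is.null(heights) && !all(dim(heights) == dims))
    stop("heights matrix must match grid dimensions")
  if (!is.null(labels_true) && !all(dim(labels_true) == dims))
    stop("label matrix must match grid dimensions")
  structure(list(curves = curves, dims = dims, heights = heights,
                 area = area, labels_true = labels_true, labels = NULL,
                 results = NULL, truth = truth),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map> %d x %d pixels over %g um^2%s%s\n",
              x$dims[1], x$dims[2], x$area,
              if (!is.null(x$results)) ", fitted" else "",
              if (!is.null(x$labels)) ", classified" else ""))
  invisible(x)
}

#' AFM topography image container
#'
#' @param heights rows x cols height matrix (nm), finite
#' @param pixel_size lateral pixel size (nm/pixel)
#' @param flattened logical flag set by [flatten()]
#' @param truth optional generator ground-truth list
#' @return object of class \code{topo_image}
#' @export
topo_image <- function(heights, pixel_size, flattened = FALSE,
                       truth = NULL) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  structure(list(heights = heights, pixel_size = pixel_size,
                 flattened = isTRUE(flattened), truth = truth),
            class = "topo_image")
}

#' @export
print.topo_image <- function(x, ...) {
  cat(sprintf("<topo_image> %d x %d pixels, %g nm/px%s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              if (x$flattened) ", flattened" else ""))
  invisible(x)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
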