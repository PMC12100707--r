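# text formats: thermograms and topography as commented-header TSV,
# force curves/maps as a versioned JSON container

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a thermogram as delimited text
#'
#' Tab-separated temperature / heat-flow columns preceded by a commented
#' header carrying the metadata the analysis needs. The scan rate is
#' mandatory: without it the kinetic Tm correction is undefined.
#'
#' @param t a [thermogram()]
#' @param path file path
#' @return \code{read_thermogram} returns a [thermogram()];
#'   \code{write_thermogram} returns \code{path} invisibly
#' @export
write_thermogram <- function(t, path) {
  stopifnot(inherits(t, "thermogram"))
  hdr <- c("# lipidmech thermogram v1",
           paste0("# sample_id: ", t$sample_id),
           paste0("# replicate: ", t$replicate),
           paste0("# scan_rate: ", .fmt_num(t$scan_rate)),
           paste0("# units: ", t$units),
           paste0("# endo_positive: ", t$endo_positive),
           paste0("# baseline_corrected: ", t$baseline_corrected))
  if (!is.null(t$lipid_amount))
    hdr <- c(hdr, paste0("# lipid_amount: ", .fmt_num(t$lipid_amount)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "temperature\theat_flow"), con)
  writeLines(paste(.fmt_num(t$temperature), .fmt_num(t$heat_flow),
                   sep = "\t"), con)
  invisible(path)
}

.parse_header <- function(lines) {
  kv <- lines[grepl("^# [^ ]+: ", lines)]
  keys <- sub("^# ([^:]+): .*$", "\\1", kv)
  vals <- sub("^# [^:]+: ", "", kv)
  setNames(as.list(vals), keys)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  hdr <- .parse_header(lines[startsWith(lines, "#")])
  if (is.null(hdr$scan_rate))
    stop("thermogram file lacks scan_rate metadata; ",
         "the kinetic correction is unusable without it")
  if (is.null(hdr$units))
    stop("thermogram file lacks a units declaration")
  body <- lines[!startsWith(lines, "#")]
  dat <- read.table(text = body, header = TRUE, sep = "\t")
  t <- thermogram(dat$temperature, dat$heat_flow,
                  scan_rate = as.numeric(hdr$scan_rate),
                  sample_id = if (is.null(hdr$sample_id)) "sample"
                              else hdr$sample_id,
                  replicate = if (is.null(hdr$replicate)) 1L
                              else as.integer(hdr$replicate),
                  endo_positive = identical(hdr$endo_positive, "TRUE"),
                  units = hdr$units,
                  baseline_corrected = identical(hdr$baseline_corrected,
                                                 "TRUE"))
  if (!is.null(hdr$lipid_amount))
    t$lipid_amount <- as.numeric(hdr$lipid_amount)
  t
}

.curve_to_list <- function(curve) {
  list(position = curve$position, z_piezo = curve$z_piezo,
       deflection = curve$deflection, segment = curve$segment)
}

.curve_from_list <- function(g, k, invols, tip_radius, unit, pixel = NULL) {
  where <- if (is.null(pixel)) "curve" else paste0("pixel ", pixel)
  need <- c("z_piezo", "deflection", "segment")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop(sprintf("parse error at %s: missing field(s) %s", where,
                 paste(miss, collapse = ", ")))
  n <- lengths(g[need])
  if (length(unique(n)) != 1L)
    stop(sprintf("parse error at %s: field lengths differ (%s)", where,
                 paste(n, collapse = "/")))
  force_curve(g$z_piezo, g$deflection, g$segment, spring_constant = k,
              tip_radius = tip_radius, invols = invols,
              position = if (is.null(g$position))
                c(NA_real_, NA_real_) else unlist(g$position),
              deflection_unit = unit)
}

#' Write / read force-spectroscopy data as a JSON container
#'
#' Versioned container holding either a single [force_curve()] or a whole
#' [force_map()]: map-level calibration attributes (spring constant,
#' InvOLS, tip radius) and one group per pixel with the piezo, deflection
#' and segment arrays. Calibration is mandatory on read — force conversion
#' is impossible without the spring constant.
#'
#' @param x a [force_curve()] or [force_map()]
#' @param path file path (.json)
#' @return \code{read_force_data} returns the stored object;
#'   \code{write_force_data} returns \code{path} invisibly
#' @export
write_force_data <- function(x, path) {
  if (inherits(x, "force_curve")) {
    doc <- list(format = "lipidmech-force", version = 1L, type = "curve",
                spring_constant = x$spring_constant, invols = x$invols,
                tip_radius = x$tip_radius,
                deflection_unit = x$deflection_unit,
                curve = .curve_to_list(x))
  } else if (inherits(x, "force_map")) {
    c1 <- x$curves[[1]]
    doc <- list(format = "lipidmech-force", version = 1L, type = "map",
                dims = x$dims, area = x$area,
                spring_constant = c1$spring_constant, invols = c1$invols,
                tip_radius = c1$tip_radius,
                deflection_unit = c1$deflection_unit,
                heights = x$heights, labels_true = x$labels_true,
                curves = lapply(x$curves, .curve_to_list))
  } else stop("x must be a force_curve or force_map")
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_force_data
#' @export
read_force_data <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = TRUE),
                  error = function(e)
                    stop("parse error reading force container '", path,
                         "': ", conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "lipidmech-force"))
    stop("not a lipidmech force container: ", path)
  if (is.null(doc$spring_constant) || !is.finite(doc$spring_constant))
    stop("force container lacks the spring constant; cannot convert ",
         "deflection to force")
  invols <- if (is.null(doc$invols)) NA_real_ else doc$invols
  if (identical(doc$deflection_unit, "V") && is.na(invols))
    stop("deflection stored in volts but the container lacks an InvOLS")
  if (identical(doc$type, "curve")) {
    return(.curve_from_list(doc$curve, doc$spring_constant, invols,
                            doc$tip_radius, doc$deflection_unit))
  }
  if (!identical(doc$type, "map")) stop("unknown container type")
  curves <- lapply(seq_along(doc$curves), function(i)
    .curve_from_list(doc$curves[[i]], doc$spring_constant, invols,
                     doc$tip_radius, doc$deflection_unit, pixel = i))
  heights <- if (is.null(doc$heights)) NULL else as.matrix(doc$heights)
  labels_true <- if (is.null(doc$labels_true)) NULL
                 else as.matrix(doc$labels_true)
  if (!is.null(labels_true)) dimnames(labels_true) <- NULL
  if (!is.null(heights)) dimnames(heights) <- NULL
  force_map(curves, dims = doc$dims, heights = heights, area = doc$area,
            labels_true = labels_true)
}

#' Write / read a topography image as a TSV height matrix
#'
#' @param img a [topo_image()]
#' @param path file path
#' @return \code{read_topo_image} returns a [topo_image()];
#'   \code{write_topo_image} returns \code{path} invisibly
#' @export
write_topo_image <- function(img, path) {
  stopifnot(inherits(img, "topo_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# lipidmech topo v1",
               paste0("# pixel_size: ", .fmt_num(img$pixel_size)),
               paste0("# flattened: ", img$flattened)), con)
  write.table(format(img$heights, digits = 17, trim = TRUE,
                     scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_topo_image
#' @export
read_topo_image <- function(path) {
  lines <- readLines(path)
  hdr <- .parse_header(lines[startsWith(lines, "#")])
  if (is.null(hdr$pixel_size))
    stop("topography file lacks pixel_size metadata")
  body <- lines[!startsWith(lines, "#")]
  m <- as.matrix(read.table(text = body, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  topo_image(m, pixel_size = as.numeric(hdr$pixel_size),
             flattened = identical(hdr$flattened, "TRUE"))
}

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis modules in one serialisable
#' object: units declaration, calibration constants, fit windows,
#' classification method, seeds and output paths. Written and read as
#' JSON; the round trip is lossless.
#'
#' @param ... overrides of the defaults
#' @return object of class \code{run_config}
#' @export
run_config <- function(...) {
  cfg <- list(
    units = list(temperature = "degC", scan_rate = "degC/min",
                 length = "nm", force = "nN", modulus = "MPa",
                 spring_constant = "N/m", heat_flow = "mW"),
    spring_constant = 0.35, tip_radius = 12, invols = NA,
    membrane_thickness = 4.7, poisson = 0.5,
    baseline_order = 1, fix_z = NULL,
    max_fraction_of_h = 0.75, min_drop = 0.5, float_contact = TRUE,
    classification_method = "height-threshold",
    classification_channel = "height",
    candidate_tolerance = 1.5, tm_max = 30,
    seed = 1L, output_dir = ".")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    val <- dots[[nm]]
    if (nm == "invols" && is.null(val)) val <- NA  # JSON null round trip
    cfg[nm] <- list(val)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a \code{run_config}
#' @param path file path (.json)
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[setdiff(names(raw), "units")])
}
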