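#' Batch-process all curves of a force map
#'
#' Runs the single-curve pipeline on every pixel: contact-point detection,
#' force-indentation transform, breakthrough detection, and the
#' thin-film Young's modulus fit restricted to pre-rupture samples.
#' Pixels whose pipeline fails are flagged, never dropped silently; the
#' failure count is recorded in the processing log attached to the result.
#'
#' @param map a [force_map()]
#' @param thickness membrane thickness h for the contact model (nm)
#' @param max_fraction_of_h upper fit bound as a fraction of h
#' @param min_drop rupture detection threshold (nN)
#' @param float_contact fit a residual contact offset per pixel (passed to
#'   [fit_young_modulus()])
#' @param max_failure_fraction abort when more than this fraction of
#'   pixels fails (bad calibration or fit parameters)
#' @return the map with \code{results}: a data.frame with one row per
#'   pixel (row, col, x, y, z0, Y, F_r, rupture_detected, converged, rss,
#'   n_points) and attribute \code{"log"} holding the failure count
#' @export
process_map <- function(map, thickness = 4.7, max_fraction_of_h = 0.75,
                        min_drop = 0.5, float_contact = TRUE,
                        max_failure_fraction = 0.5) {
  stopifnot(inherits(map, "force_map"))
  rows <- map$dims[1]; cols <- map$dims[2]
  npix <- rows * cols
  res <- data.frame(row = rep(seq_len(rows), each = cols),
                    col = rep(seq_len(cols), times = rows),
                    x = NA_real_, y = NA_real_, z0 = NA_real_,
                    Y = NA_real_, F_r = NA_real_,
                    rupture_detected = FALSE, converged = FALSE,
                    rss = NA_real_, n_points = NA_integer_,
                    failure = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(npix)) {
    curve <- map$curves[[i]]
    res$x[i] <- curve$position[1]; res$y[i] <- curve$position[2]
    status <- tryCatch({
      z0 <- detect_contact_point(curve)
      rup <- detect_rupture(curve, min_drop = min_drop)
      di <- to_force_indentation(curve, z0)
      keep <- if (rup$detected) seq_len(max(rup$index - 1L, 0L))
              else seq_along(di$delta)
      fit <- fit_young_modulus(di$delta[keep], di$force[keep],
                               tip_radius = curve$tip_radius,
                               thickness = thickness,
                               max_fraction_of_h = max_fraction_of_h,
                               float_contact = float_contact,
                               spring_constant = curve$spring_constant)
      res$z0[i] <- z0
      res$rupture_detected[i] <- rup$detected
      if (rup$detected) res$F_r[i] <- rup$rupture_force
      res$Y[i] <- fit$young_modulus
      res$converged[i] <- fit$converged
      res$rss[i] <- fit$rss
      res$n_points[i] <- fit$n_points
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(status)) res$failure[i] <- status
  }
  n_failed <- sum(!res$converged)
  if (n_failed > max_failure_fraction * npix)
    stop(sprintf(paste0("%d of %d pixel fits failed (> %.0f%%); check ",
                        "calibration and fit parameters"),
                 n_failed, npix, 100 * max_failure_fraction))
  map$results <- res
  attr(map$results, "log") <- list(n_pixels = npix, n_failed = n_failed,
                                   n_ruptures = sum(res$rupture_detected))
  map
}

# two-means split of a numeric vector; returns cluster means and labels
.two_means <- function(v) {
  q <- unname(quantile(v, c(0.25, 0.75)))
  if (diff(q) < .Machine$double.eps^0.5)
    return(list(degenerate = TRUE))
  km <- kmeans(v, centers = matrix(q, ncol = 1))
  within_sd <- sqrt(sum(km$withinss) / max(length(v) - 2, 1))
  # a two-means split of a *unimodal* Gaussian yields a center separation
  # of ~2.65 within-cluster sd; demand clearly more before calling the
  # channel bimodal
  list(degenerate = abs(diff(km$centers)) < 3.2 * within_sd,
       centers = as.numeric(km$centers), cluster = km$cluster)
}

#' Classify force-map pixels into pre- and post-transition phases
#'
#' Two-class assignment of map pixels from either the height channel
#' (ordered post-transition domains are 0.5-0.7 nm taller than the fluid
#' pretransition phase) or the fitted Young's modulus channel. The
#' \code{"height-threshold"} method splits the channel by a two-means
#' clustering; the \code{"two-component-mixture"} method fits a Gaussian
#' mixture and assigns by posterior probability > 0.5. In both cases the
#' taller/stiffer class is labelled \code{"post"}. Unimodal (degenerate)
#' channels yield a single class plus a flag.
#'
#' @param map a [force_map()]; the modulus channel requires
#'   [process_map()] to have been run
#' @param method "height-threshold" or "two-component-mixture"
#' @param channel "height" or "young"
#' @return object of class \code{phase_classification}: \code{labels}
#'   (rows x cols character matrix, "pre"/"post"/"unclassified"),
#'   \code{degenerate} flag, \code{method}, \code{channel},
#'   \code{class_means}
#' @export
classify_phases <- function(map,
                            method = c("height-threshold",
                                       "two-component-mixture"),
                            channel = c("height", "young")) {
  stopifnot(inherits(map, "force_map"))
  method <- match.arg(method)
  channel <- match.arg(channel)
  rows <- map$dims[1]; cols <- map$dims[2]
  if (channel == "height") {
    if (is.null(map$heights)) stop("map has no height channel")
    vmat <- map$heights
  } else {
    if (is.null(map$results)) stop("run process_map() before classifying on Y")
    vmat <- matrix(NA_real_, rows, cols)
    ok <- map$results$converged
    vmat[cbind(map$results$row[ok], map$results$col[ok])] <-
      map$results$Y[ok]
  }
  labels <- matrix("unclassified", rows, cols)
  usable <- which(is.finite(vmat))
  v <- vmat[usable]
  degenerate <- FALSE
  class_means <- c(pre = NA_real_, post = NA_real_)
  if (length(unique(v)) < 2L || sd(v) == 0) {
    degenerate <- TRUE
    labels[usable] <- "pre"
  } else if (method == "height-threshold") {
    tm <- .two_means(v)
    if (isTRUE(tm$degenerate)) {
      degenerate <- TRUE
      labels[usable] <- "pre"
    } else {
      post_cl <- which.max(tm$centers)
      labels[usable] <- ifelse(tm$cluster == post_cl, "post", "pre")
      class_means <- c(pre = min(tm$centers), post = max(tm$centers))
    }
  } else {
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    mc <- mclust::Mclust(v, G = 1:2, modelNames = c("E", "V"),
                         verbose = FALSE)
    if (is.null(mc) || mc$G == 1L) {
      degenerate <- TRUE
      labels[usable] <- "pre"
    } else {
      post_cl <- which.max(mc$parameters$mean)
      post <- mc$z[, post_cl] > 0.5
      labels[usable] <- ifelse(post, "post", "pre")
      class_means <- c(pre = min(mc$parameters$mean),
                       post = max(mc$parameters$mean))
    }
  }
  structure(list(labels = labels, degenerate = degenerate, method = method,
                 channel = channel, class_means = class_means),
            class = "phase_classification")
}

#' @export
print.phase_classification <- function(x, ...) {
  tab <- table(factor(x$labels, c("pre", "post", "unclassified")))
  cat(sprintf("<phase_classification> %s on %s: pre %d, post %d, unclassified %d%s\n",
              x$method, x$channel, tab[["pre"]], tab[["post"]],
              tab[["unclassified"]],
              if (x$degenerate) " [degenerate: single class]" else ""))
  invisible(x)
}

# boxplot-style summary of one numeric sample
.box_stats <- function(x) {
  n <- length(x)
  if (!n)
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, whisker_lo = NA_real_,
                whisker_hi = NA_real_, spread_defined = FALSE))
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  list(n = n, mean = mean(x), sd = if (n > 1) sd(x) else NA_real_,
       median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = lo, whisker_hi = hi, spread_defined = n >= 3L)
}

#' Phase-resolved statistics of a processed force map
#'
#' Descriptive statistics of the Young's modulus and rupture force per
#' phase, over converged pixels only (rupture statistics additionally
#' require a detected breakthrough). Quartiles use linear interpolation;
#' whiskers extend to the furthest data point within 1.5 times the
#' interquartile range of the quartiles, the convention used for boxplot
#' reporting. Phases with fewer than 3 values are flagged as having
#' undefined spread.
#'
#' @param map a processed [force_map()]
#' @param labels optional \code{phase_classification} (or label matrix);
#'   defaults to \code{map$labels}, falling back to ground-truth labels
#'   for synthetic maps
#' @return data.frame of class \code{phase_stats}: one row per
#'   (phase, metric) with n, mean, sd, median, q1, q3, whisker_lo,
#'   whisker_hi, spread_defined. Attribute \code{"n_excluded"} counts
#'   non-converged pixels.
#' @export
phase_statistics <- function(map, labels = NULL) {
  stopifnot(inherits(map, "force_map"))
  if (is.null(map$results)) stop("run process_map() first")
  if (is.null(labels)) labels <- map$labels
  if (is.null(labels)) labels <- map$labels_true
  if (is.null(labels)) stop("no phase labels available; run classify_phases()")
  if (inherits(labels, "phase_classification")) labels <- labels$labels
  res <- map$results
  lab <- labels[cbind(res$row, res$col)]
  rows <- list()
  for (phase in c("pre", "post")) {
    ok <- res$converged & lab == phase
    y <- res$Y[ok]
    fr <- res$F_r[ok & res$rupture_detected]
    fr <- fr[is.finite(fr)]
    rows[[paste0(phase, ".Y")]] <-
      c(list(phase = phase, metric = "Y"), .box_stats(y))
    rows[[paste0(phase, ".F_r")]] <-
      c(list(phase = phase, metric = "F_r"), .box_stats(fr))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!res$converged)
  class(out) <- c("phase_stats", "data.frame")
  out
}

#' @export
print.phase_stats <- function(x, ...) {
  cat("Phase-resolved statistics (converged pixels only):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("excluded (non-converged) pixels: %d\n",
              attr(x, "n_excluded")))
  invisible(x)
}
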