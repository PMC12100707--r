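#' Flatten an AFM topography image
#'
#' Removes the scanner background by fitting a polynomial of the given
#' order to each fast-scan row (order 0: offset; 1: line; 2: bow) over
#' the unmasked pixels and subtracting it, then shifting the unmasked
#' (substrate) median to zero. Feature pixels — membrane patches,
#' domains — should be excluded through \code{mask} so they do not bias
#' the background fit.
#'
#' @param img a [topo_image()]
#' @param order polynomial order per row, one of 0, 1, 2
#' @param mask optional logical matrix; TRUE pixels are excluded from the
#'   background fit (but still corrected)
#' @return the flattened [topo_image()]
#' @export
flatten <- function(img, order = 1, mask = NULL) {
  stopifnot(inherits(img, "topo_image"))
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  h <- img$heights
  rows <- nrow(h); cols <- ncol(h)
  if (is.null(mask)) mask <- matrix(FALSE, rows, cols)
  if (!all(dim(mask) == dim(h)))
    stop("mask dimensions must match the image")
  if (mean(mask) > 0.9)
    stop("mask excludes more than 90% of pixels; cannot fit a background")
  x <- seq_len(cols)
  X <- outer(x, 0:order, `^`)
  for (r in seq_len(rows)) {
    use <- !mask[r, ]
    if (sum(use) < order + 2L) use <- rep(TRUE, cols)  # fallback: whole row
    cf <- stats::lm.fit(X[use, , drop = FALSE], h[r, use])$coefficients
    cf[is.na(cf)] <- 0
    h[r, ] <- h[r, ] - as.numeric(X %*% cf)
  }
  h <- h - median(h[!mask])
  out <- img
  out$heights <- h
  out$flattened <- TRUE
  out
}

#' Step height between two image regions
#'
#' Median height difference between two disjoint pixel masks of a
#' flattened image (e.g. membrane patch vs. substrate), with a robust
#' spread estimate: the pooled median absolute deviation of the two
#' regions scaled to a Gaussian standard deviation.
#'
#' @param img a flattened [topo_image()]
#' @param region_a logical mask of the reference region (e.g. substrate)
#' @param region_b logical mask of the elevated region (e.g. patch)
#' @return list: \code{step} = median(b) - median(a) (nm), \code{sd} (nm),
#'   \code{n_a}, \code{n_b}
#' @export
step_height <- function(img, region_a, region_b) {
  stopifnot(inherits(img, "topo_image"))
  h <- img$heights
  if (!all(dim(region_a) == dim(h)) || !all(dim(region_b) == dim(h)))
    stop("region masks must match the image dimensions")
  if (!any(region_a) || !any(region_b))
    stop("both regions must contain at least one pixel")
  if (any(region_a & region_b))
    stop("regions must be disjoint")
  if (!img$flattened)
    warning("image is not flattened; step height may be biased by tilt")
  a <- h[region_a]; b <- h[region_b]
  mad_a <- mad(a); mad_b <- mad(b)
  na <- length(a); nb <- length(b)
  pooled <- sqrt((na * mad_a^2 + nb * mad_b^2) / (na + nb))
  list(step = median(b) - median(a), sd = pooled, n_a = na, n_b = nb)
}
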