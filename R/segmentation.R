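#' Partition a nodule ROI into central and peripheral regions
#'
#' Implements the offsetting principle used for regional vascularity
#' quantification: the whole-nodule ROI is contracted inward by a fraction of
#' its depth to delineate a central sub-region; the remaining outer rim is the
#' peripheral region. The study optimum for thyroid nodules is a 22% offset.
#'
#' With the default `distance_fraction` method a pixel `p` of the ROI belongs
#' to the central region iff `d(p) >= offset_fraction * max(d)`, where `d(p)`
#' is the Euclidean distance from `p` to the ROI boundary (ROI pixels
#' 4-adjacent to background, frame edges counting as background). Ties at the
#' threshold go to the central region, so `offset_fraction = 0` maps the whole
#' ROI to central and an empty peripheral rim, and `offset_fraction = 1`
#' leaves the innermost (deepest) pixels as central. The alternative
#' `contour_scale` method shrinks the ROI towards its centroid by the factor
#' `1 - offset_fraction` and is provided for sensitivity analysis.
#'
#' @param roi logical matrix; `TRUE` marks ROI pixels. Must be non-empty.
#'   A multi-component mask is processed as one region with a warning.
#' @param offset_fraction offset as a fraction of the maximum inscribed
#'   distance, in `[0, 1]`. Default 0.22.
#' @param method `"distance_fraction"` (default) or `"contour_scale"`.
#' @return An object of class `region_partition`: a list with logical masks
#'   `central` and `peripheral` (their union is exactly the ROI, their
#'   intersection empty), plus `offset_fraction` and `method`.
#' @examples
#' roi <- make_roi_mask(64, 64, "circle", radius = 25)
#' p <- partition_regions(roi, 0.22)
#' region_areas(p)
#' @export
partition_regions <- function(roi, offset_fraction = 0.22,
                              method = c("distance_fraction", "contour_scale")) {
  method <- match.arg(method)
  if (!is.logical(roi) || !is.matrix(roi))
    stop("'roi' must be a logical matrix")
  if (!any(roi)) stop("ROI mask is empty")
  check_fraction(offset_fraction, "offset_fraction")
  if (n_components(roi) > 1L)
    warning("ROI mask has multiple connected components; processed as one region")

  if (method == "distance_fraction") {
    d <- distance_to_boundary(roi)
    dmax <- max(d, na.rm = TRUE)
    central <- !is.na(d) & d >= offset_fraction * dmax
  } else {
    idx <- which(roi, arr.ind = TRUE)
    cen <- colMeans(idx)
    s <- 1 - offset_fraction
    # a pixel is central if its preimage under the scaling about the centroid
    # lies in the ROI (scale 0 collapses to the centroid pixel)
    central <- matrix(FALSE, nrow(roi), ncol(roi))
    if (s == 0) {
      central[round(cen[1]), round(cen[2])] <- TRUE
      central <- central & roi
      if (!any(central)) central[idx[1, 1], idx[1, 2]] <- TRUE
    } else {
      # a pixel is central if its preimage under scaling about the centroid
      # (by 1/s) is an ROI pixel inside the frame
      pre_r <- cen[1] + (idx[, 1] - cen[1]) / s
      pre_c <- cen[2] + (idx[, 2] - cen[2]) / s
      inside <- pre_r >= 0.5 & pre_r <= nrow(roi) + 0.5 &
                pre_c >= 0.5 & pre_c <= ncol(roi) + 0.5
      keep <- inside
      keep[inside] <- roi[cbind(pmin(pmax(round(pre_r[inside]), 1L), nrow(roi)),
                                pmin(pmax(round(pre_c[inside]), 1L), ncol(roi)))]
      central[idx[keep, , drop = FALSE]] <- TRUE
    }
  }
  peripheral <- roi & !central
  structure(
    list(central = central, peripheral = peripheral,
         offset_fraction = offset_fraction, method = method),
    class = "region_partition"
  )
}

#' Pixel areas of a region partition
#'
#' @param partition a [partition_regions()] result.
#' @return Named numeric vector `c(central = , peripheral = )` of pixel
#'   counts; their sum equals the ROI pixel count.
#' @export
region_areas <- function(partition) {
  stopifnot(inherits(partition, "region_partition"))
  c(central = sum(partition$central), peripheral = sum(partition$peripheral))
}

#' @export
print.region_partition <- function(x, ...) {
  a <- region_areas(x)
  cat(sprintf(
    "Region partition (%s, offset %.0f%%): %d central / %d peripheral px (%.1f%% central)\n",
    x$method, 100 * x$offset_fraction, a["central"], a["peripheral"],
    100 * a["central"] / sum(a)))
  invisible(x)
}

# number of 4-connected components of a logical mask (two-pass flood fill)
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  ord <- order(idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  parent <- integer(0)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    up <- if (i > 1L) lab[i - 1L, j] else 0L
    lf <- if (j > 1L) lab[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      lab[i, j] <- ru
      if (ru != rl) parent[rl] <- ru
    } else {
      lab[i, j] <- max(up, lf)
    }
  }
  length(unique(vapply(seq_len(nxt), find, integer(1))))
}

#' Construct a rasterised ROI mask
#'
#' Builds binary nodule masks used by the phantom generator and in tests:
#' a circle, an axis-aligned ellipse, or a smooth random blob (radial sine
#' perturbation of a circle).
#'
#' @param height,width frame dimensions in pixels.
#' @param shape `"circle"`, `"ellipse"` or `"blob"`.
#' @param radius circle radius (also the blob base radius), pixels.
#' @param semi_axes length-2 numeric, ellipse semi-axes (row, col), pixels.
#' @param centre length-2 numeric (row, col); defaults to the frame centre.
#' @param wobble blob relative radial perturbation amplitude (default 0.15).
#' @param seed integer seed for the blob perturbation phases.
#' @return Logical matrix of size `height x width`. Errors if the shape does
#'   not fit inside the frame, naming the offending parameter.
#' @export
make_roi_mask <- function(height, width, shape = c("circle", "ellipse", "blob"),
                          radius = min(height, width) / 4,
                          semi_axes = c(height / 4, width / 3),
                          centre = c((height + 1) / 2, (width + 1) / 2),
                          wobble = 0.15, seed = 1L) {
  shape <- match.arg(shape)
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  if (shape == "circle") {
    if (centre[1] - radius < 1 || centre[1] + radius > height ||
        centre[2] - radius < 1 || centre[2] + radius > width)
      stop("ROI does not fit inside the frame: 'radius' too large for the centre")
    (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
  } else if (shape == "ellipse") {
    if (centre[1] - semi_axes[1] < 1 || centre[1] + semi_axes[1] > height ||
        centre[2] - semi_axes[2] < 1 || centre[2] + semi_axes[2] > width)
      stop("ROI does not fit inside the frame: 'semi_axes' too large for the centre")
    ((rr - centre[1]) / semi_axes[1])^2 + ((cc - centre[2]) / semi_axes[2])^2 <= 1
  } else {
    rmax <- radius * (1 + wobble)
    if (centre[1] - rmax < 1 || centre[1] + rmax > height ||
        centre[2] - rmax < 1 || centre[2] + rmax > width)
      stop("ROI does not fit inside the frame: 'radius'*(1+'wobble') too large")
    ph <- with_seed(seed, stats::runif(3, 0, 2 * pi))
    th <- atan2(cc - centre[2], rr - centre[1])
    rad <- radius * (1 + wobble * (0.5 * sin(2 * th + ph[1]) +
                                   0.3 * sin(3 * th + ph[2]) +
                                   0.2 * sin(5 * th + ph[3])))
    (rr - centre[1])^2 + (cc - centre[2])^2 <= rad^2
  }
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks are stored as 8-bit greyscale PNG with 0 = background and 255 = ROI.
#'
#' @param path file path.
#' @param mask logical matrix.
#' @return `read_mask_png` returns a logical matrix; `write_mask_png` returns
#'   `path` invisibly.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a >= 0.5
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Export a partition as a 3-label PNG
#'
#' Writes 0 for background, 1/255 for peripheral and 2/255 for central, so the
#' file round-trips exactly through 8-bit greyscale PNG.
#'
#' @param partition a [partition_regions()] result.
#' @param path file path.
#' @export
write_partition_png <- function(partition, path) {
  stopifnot(inherits(partition, "region_partition"))
  lab <- matrix(0, nrow(partition$central), ncol(partition$central))
  lab[partition$peripheral] <- 1 / 255
  lab[partition$central] <- 2 / 255
  png::writePNG(lab, path)
  invisible(path)
}
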