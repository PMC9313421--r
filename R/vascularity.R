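#' Detect colour (Doppler-signal) pixels in an RGB frame
#'
#' Doppler machines overlay pure colour on a greyscale B-mode image, so a
#' pixel carries Doppler signal iff its channels disagree. A pixel is marked
#' colour when `max(R,G,B) - min(R,G,B) > chroma_threshold` (channels on the
#' 0-255 scale). The default threshold of 10 tolerates mild compression noise
#' around genuinely grey pixels.
#'
#' @param image a `doppler_image` (see [generate_doppler_image()]) or a
#'   numeric `h x w x 3` array with values in 0-255 (or 0-1, which is
#'   rescaled).
#' @param chroma_threshold non-negative channel-difference threshold,
#'   0-255 scale.
#' @return Logical matrix marking colour pixels.
#' @export
detect_colour_pixels <- function(image, chroma_threshold = 10) {
  px <- image_pixels(image)
  if (chroma_threshold < 0) stop("'chroma_threshold' must be >= 0")
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  (mx - mn) > chroma_threshold
}

image_pixels <- function(image) {
  if (inherits(image, "doppler_image")) image <- image$pixels
  if (!is.numeric(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an RGB array (h x w x 3)")
  if (max(image) <= 1) image <- image * 255
  image
}

#' Vascularity index of a region
#'
#' The vascularity index (VI) is the percentage of colour (Doppler-signal)
#' pixels among all pixels of a region: `VI = 100 * |colour & region| /
#' |region|`.
#'
#' @param colour_mask logical matrix from [detect_colour_pixels()].
#' @param region_mask logical matrix; must be non-empty and the same shape.
#' @return VI as a percentage in `[0, 100]`.
#' @export
compute_vi <- function(colour_mask, region_mask) {
  if (!identical(dim(colour_mask), dim(region_mask)))
    stop("colour and region masks have different dimensions")
  n <- sum(region_mask)
  if (n == 0L) stop("region mask is empty (degenerate partition)")
  100 * sum(colour_mask & region_mask) / n
}

#' Aggregate replicate regional VI readings into one measurement
#'
#' Regional VIs are determined as the arithmetic means of the replicate
#' readings (three per nodule per Doppler mode in the study protocol); the
#' ratio vascularity index (RVI) is then the ratio of the mean peripheral VI
#' to the mean central VI (ratio of means, not mean of ratios). A zero mean
#' central VI with peripheral signal gives `RVI = Inf` (exclusively peripheral
#' flow, suspicious for benignity); both means zero marks the nodule
#' `non_vascular`, mirroring the study's exclusion of non-vascular nodules.
#'
#' @param vi_peripheral,vi_central numeric vectors of per-replicate VIs
#'   (percent); equal length, at least one replicate.
#' @param areas optional named vector `c(central=, peripheral=)` of region
#'   pixel areas, used to report the area-weighted overall VI.
#' @param mode optional Doppler mode tag (`"CFI"`, `"ACFI"`, `"PDI"`,
#'   `"APDI"`).
#' @param rvi_threshold RVI decision threshold, default 1.
#' @return An object of class `vascularity_measurement`: list with
#'   `vi_peripheral`, `vi_central`, `vi_overall` (area-weighted if `areas`
#'   given, else `NA`), `rvi`, `n_replicates`, `mode`, `suspicion`.
#' @examples
#' aggregate_replicates(c(40, 50, 60), c(20, 25, 30))
#' @export
aggregate_replicates <- function(vi_peripheral, vi_central, areas = NULL,
                                 mode = NA_character_, rvi_threshold = 1) {
  if (length(vi_peripheral) == 0L || length(vi_central) == 0L)
    stop("at least one replicate is required")
  if (length(vi_peripheral) != length(vi_central))
    stop("peripheral and central replicate vectors differ in length")
  check_fraction(vi_peripheral, "vi_peripheral", 0, 100)
  check_fraction(vi_central, "vi_central", 0, 100)
  vp <- mean(vi_peripheral)
  vc <- mean(vi_central)
  rvi <- if (vc > 0) vp / vc else if (vp > 0) Inf else NaN
  suspicion <- if (vp == 0 && vc == 0) "non_vascular" else
    classify_rvi(rvi, rvi_threshold)
  vo <- if (!is.null(areas)) {
    (areas[["peripheral"]] * vp + areas[["central"]] * vc) /
      (areas[["peripheral"]] + areas[["central"]])
  } else NA_real_
  structure(
    list(vi_peripheral = vp, vi_central = vc, vi_overall = unname(vo),
         rvi = rvi, n_replicates = length(vi_peripheral), mode = mode,
         suspicion = suspicion),
    class = "vascularity_measurement"
  )
}

#' @export
print.vascularity_measurement <- function(x, ...) {
  cat(sprintf(
    "Vascularity measurement%s (%d replicate%s)\n  VI peripheral %.2f%%, central %.2f%%%s\n  RVI %.3g -> %s\n",
    if (is.na(x$mode)) "" else paste0(" [", x$mode, "]"),
    x$n_replicates, if (x$n_replicates == 1) "" else "s",
    x$vi_peripheral, x$vi_central,
    if (is.na(x$vi_overall)) "" else sprintf(", overall %.2f%%", x$vi_overall),
    x$rvi, x$suspicion))
  invisible(x)
}

#' Classify a nodule by its ratio vascularity index
#'
#' RVI above the threshold (default 1) denotes predominant peripheral
#' vascularity, suspicious for benignity; RVI at or below it denotes
#' predominant central vascularity, suspicious for malignancy.
#'
#' @param rvi ratio vascularity index, `>= 0` or `Inf`; vectorised.
#' @param threshold decision threshold, default 1.
#' @return `"benign_suspicious"` or `"malignant_suspicious"`.
#' @export
classify_rvi <- function(rvi, threshold = 1) {
  if (any(is.na(rvi) & !is.nan(rvi)) || any(rvi < 0, na.rm = TRUE))
    stop("'rvi' must be non-negative (or Inf)")
  ifelse(rvi > threshold, "benign_suspicious", "malignant_suspicious")
}

#' Map a qualitative vascularity grade to a suspicion label
#'
#' Grades follow the four-category scheme for Doppler flow distribution:
#' I exclusively peripheral, II predominantly peripheral, III predominantly
#' central, IV exclusively central. Grades I-II are suspicious for benignity,
#' III-IV for malignancy.
#'
#' @param grade character/factor vector over `c("I","II","III","IV")`.
#' @return `"benign_suspicious"` or `"malignant_suspicious"`, vectorised.
#' @export
classify_qualitative <- function(grade) {
  grade <- as.character(grade)
  bad <- !grade %in% c("I", "II", "III", "IV")
  if (any(bad))
    stop("invalid qualitative grade(s): ", paste(unique(grade[bad]), collapse = ", "))
  ifelse(grade %in% c("I", "II"), "benign_suspicious", "malignant_suspicious")
}
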