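#' Specify a synthetic Doppler phantom image
#'
#' Describes a Doppler-like still frame: a greyscale background (flat or
#' speckled), a nodule ROI of a given shape, and colour overlay painted
#' inside the central and peripheral regions of the ROI to hit requested
#' coverage fractions. Because the painter records exactly which pixels it
#' coloured, every phantom ships with exact per-region colour-pixel ground
#' truth for validating the quantification chain.
#'
#' @param width,height frame size in pixels.
#' @param roi_shape `"circle"`, `"ellipse"` or `"blob"`.
#' @param roi_params list of shape parameters passed to [make_roi_mask()]
#'   (`radius`, `semi_axes`, `centre`, `wobble`).
#' @param target_coverage_peripheral,target_coverage_central requested colour
#'   coverage fraction of each region, in `[0, 1]`.
#' @param colour_palette `"red_blue"` (directional flow map) or `"orange"`
#'   (power map).
#' @param background_noise `"speckle"` (multiplicative noise on a smooth
#'   base) or `"flat"`.
#' @param offset_fraction offset used to delimit the central region
#'   (default 0.22).
#' @param seed integer; identical spec and seed give bit-identical output.
#' @return Object of class `image_phantom_spec`.
#' @export
image_phantom_spec <- function(width = 256, height = 256,
                               roi_shape = c("circle", "ellipse", "blob"),
                               roi_params = list(),
                               target_coverage_peripheral = 0.25,
                               target_coverage_central = 0.25,
                               colour_palette = c("red_blue", "orange"),
                               background_noise = c("speckle", "flat"),
                               offset_fraction = 0.22,
                               seed = 1L) {
  check_fraction(target_coverage_peripheral, "target_coverage_peripheral")
  check_fraction(target_coverage_central, "target_coverage_central")
  check_fraction(offset_fraction, "offset_fraction")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         roi_shape = match.arg(roi_shape), roi_params = roi_params,
         target_coverage_peripheral = target_coverage_peripheral,
         target_coverage_central = target_coverage_central,
         colour_palette = match.arg(colour_palette),
         background_noise = match.arg(background_noise),
         offset_fraction = offset_fraction, seed = as.integer(seed)),
    class = "image_phantom_spec"
  )
}

# palette triples, 0-255
palette_colours <- function(palette) {
  switch(palette,
    red_blue = rbind(c(210, 45, 45), c(55, 70, 215)),
    orange = rbind(c(235, 150, 40)))
}

# paint colour disks uniformly inside `region` until `target` pixels are
# covered (exceeded by at most one primitive); returns the painted mask
paint_region <- function(region, target) {
  painted <- matrix(FALSE, nrow(region), ncol(region))
  if (target <= 0) return(painted)
  idx <- which(region)
  nr <- nrow(region)
  repeat {
    n_painted <- sum(painted)
    if (n_painted >= target) break
    ctr <- idx[sample.int(length(idx), 1L)]
    ci <- ((ctr - 1L) %% nr) + 1L
    cj <- ((ctr - 1L) %/% nr) + 1L
    # shrink the stroke near the target so the overshoot stays small even in
    # small regions (a single pixel is the smallest primitive)
    remaining <- target - n_painted
    r <- if (remaining <= 12) 0L else sample(1:3, 1L)
    if (r == 0L) { painted[ci, cj] <- TRUE; next }
    di <- rep(-r:r, times = 2L * r + 1L)
    dj <- rep(-r:r, each = 2L * r + 1L)
    keep <- di * di + dj * dj <= r * r
    pi <- ci + di[keep]; pj <- cj + dj[keep]
    ok <- pi >= 1L & pi <= nr & pj >= 1L & pj <= ncol(region)
    cells <- cbind(pi[ok], pj[ok])
    cells <- cells[region[cells], , drop = FALSE]
    painted[cells] <- TRUE
  }
  painted
}

#' Generate a synthetic Doppler image with exact colour ground truth
#'
#' Builds the greyscale background, rasterises the ROI, partitions it at the
#' spec's offset with [partition_regions()], and paints small colour disks
#' uniformly inside each region until its target coverage is met (exceeded by
#' at most one disk). All non-painted pixels are pure greyscale
#' (`R = G = B`); colour is painted only inside the ROI, and strictly inside
#' its target region, so the recorded per-region painted counts are exact.
#'
#' @param spec an [image_phantom_spec()].
#' @param mode Doppler-mode tag carried on the image (`"CFI"`, `"ACFI"`,
#'   `"PDI"`, `"APDI"`); a label only, the phantom physics does not change.
#' @return Object of class `doppler_phantom`: list with `image` (a
#'   `doppler_image`: `$pixels` is an `h x w x 3` array in 0-255, `$mode` the
#'   tag), `roi_mask`, `partition`, and `ground_truth` — a named vector of
#'   painted colour-pixel counts `c(central=, peripheral=)`.
#' @examples
#' ph <- generate_doppler_image(image_phantom_spec(width = 96, height = 96,
#'   roi_params = list(radius = 30), background_noise = "flat", seed = 7))
#' ph$ground_truth
#' @export
generate_doppler_image <- function(spec, mode = "APDI") {
  stopifnot(inherits(spec, "image_phantom_spec"))
  h <- spec$height; w <- spec$width
  roi <- do.call(make_roi_mask,
    c(list(height = h, width = w, shape = spec$roi_shape), spec$roi_params,
      if (!"seed" %in% names(spec$roi_params) && spec$roi_shape == "blob")
        list(seed = spec$seed)))
  part <- partition_regions(roi, spec$offset_fraction)
  with_seed(spec$seed, {
    # greyscale background, identical across channels
    if (spec$background_noise == "flat") {
      g <- matrix(100, h, w)
    } else {
      rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      base <- 90 + 35 * exp(-(((rr - h / 2)^2 + (cc - w / 2)^2) /
                                (2 * (min(h, w) / 2.5)^2)))
      g <- base * exp(matrix(stats::rnorm(h * w, 0, 0.18), h, w))
    }
    g[roi] <- g[roi] * 0.7   # nodules image darker than surrounding tissue
    g <- round(pmin(pmax(g, 0), 255))
    px <- array(0, c(h, w, 3))
    px[, , 1] <- g; px[, , 2] <- g; px[, , 3] <- g

    paint_c <- paint_region(part$central,
                            spec$target_coverage_central * sum(part$central))
    paint_p <- paint_region(part$peripheral,
                            spec$target_coverage_peripheral * sum(part$peripheral))
    pal <- palette_colours(spec$colour_palette)
    for (m in list(paint_c, paint_p)) {
      n <- sum(m)
      if (n == 0) next
      col <- pal[sample.int(nrow(pal), n, replace = TRUE), , drop = FALSE]
      bright <- stats::runif(n, 0.85, 1)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[m] <- round(col[, ch] * bright)
        px[, , ch] <- plane
      }
    }
  })
  structure(
    list(image = structure(list(pixels = px, mode = mode),
                           class = "doppler_image"),
         roi_mask = roi, partition = part,
         ground_truth = c(central = sum(paint_c), peripheral = sum(paint_p)),
         spec = spec),
    class = "doppler_phantom"
  )
}

#' @export
print.doppler_phantom <- function(x, ...) {
  a <- region_areas(x$partition)
  cat(sprintf(
    "Doppler phantom %dx%d [%s], ROI %d px\n  colour px: central %d/%d (%.1f%%), peripheral %d/%d (%.1f%%)\n",
    x$spec$height, x$spec$width, x$image$mode, sum(x$roi_mask),
    x$ground_truth["central"], a["central"],
    100 * x$ground_truth["central"] / a["central"],
    x$ground_truth["peripheral"], a["peripheral"],
    100 * x$ground_truth["peripheral"] / a["peripheral"]))
  invisible(x)
}

#' Write a reproducible bundle of phantom images and a simulated cohort
#'
#' Materialises fixtures on disk: each phantom as an 8-bit RGB PNG with its
#' ROI mask as a single-channel PNG (0/255), exact colour ground truth as
#' CSV, the simulated cohort as CSV, and a JSON manifest listing every file
#' with the seed that produced it. Re-running with the same specs yields
#' byte-identical files.
#'
#' @param output_dir directory (created if needed; an unwritable path is an
#'   error naming the path).
#' @param image_specs list of [image_phantom_spec()] objects (may be empty).
#' @param cohort_spec optional [cohort_spec()]; when given, the cohort table
#'   is written as `cohort.csv`.
#' @param modes Doppler-mode tag(s) recycled over the image specs.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_bundle <- function(output_dir, image_specs = list(),
                                 cohort_spec = NULL, modes = "APDI") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir) || file.access(output_dir, 2) != 0)
    stop("cannot write to directory: ", output_dir)
  img_dir <- file.path(output_dir, "images")
  msk_dir <- file.path(output_dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(msk_dir, showWarnings = FALSE)
  modes <- rep_len(modes, max(1L, length(image_specs)))
  entries <- list()
  gt <- NULL
  for (i in seq_along(image_specs)) {
    ph <- generate_doppler_image(image_specs[[i]], mode = modes[i])
    stem <- sprintf("phantom-%03d_%s_r1", i, modes[i])
    img_path <- file.path(img_dir, paste0(stem, ".png"))
    msk_path <- file.path(msk_dir, paste0(stem, ".png"))
    png::writePNG(ph$image$pixels / 255, img_path)
    write_mask_png(ph$roi_mask, msk_path)
    a <- region_areas(ph$partition)
    gt <- rbind(gt, data.frame(
      image = basename(img_path), mode = modes[i],
      colour_central = ph$ground_truth[["central"]],
      colour_peripheral = ph$ground_truth[["peripheral"]],
      area_central = a[["central"]], area_peripheral = a[["peripheral"]],
      offset_fraction = image_specs[[i]]$offset_fraction))
    entries[[length(entries) + 1L]] <- list(
      file = file.path("images", basename(img_path)), kind = "image",
      seed = image_specs[[i]]$seed)
    entries[[length(entries) + 1L]] <- list(
      file = file.path("masks", basename(msk_path)), kind = "mask",
      seed = image_specs[[i]]$seed)
  }
  if (!is.null(gt)) {
    utils::write.csv(gt, file.path(output_dir, "ground_truth.csv"),
                     row.names = FALSE)
    entries[[length(entries) + 1L]] <- list(file = "ground_truth.csv",
                                            kind = "ground_truth", seed = NA)
  }
  if (!is.null(cohort_spec)) {
    cohort <- generate_cohort(cohort_spec)
    utils::write.csv(cohort, file.path(output_dir, "cohort.csv"),
                     row.names = FALSE)
    entries[[length(entries) + 1L]] <- list(file = "cohort.csv",
                                            kind = "cohort",
                                            seed = cohort_spec$seed)
  }
  manifest <- list(n_images = length(image_specs), files = entries)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
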