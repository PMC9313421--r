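#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the regional offset
#' fraction (default 0.22, the study optimum for thyroid nodules), the
#' colour-detection chroma threshold (default 10 on the 0-255 scale), the
#' TIRADS cut-off used for the sole grey-scale assessment, the RVI decision
#' threshold (default 1), the confidence level, and the master seed.
#'
#' @param offset_fraction central-region offset fraction in `[0, 1]`.
#' @param chroma_threshold colour-pixel channel-difference threshold.
#' @param tirads_cutoff `"sole_ge5"` or `"combined_ge4"` (the combined
#'   assessments always use category >= 4 per protocol).
#' @param rvi_threshold RVI decision threshold.
#' @param ci_level confidence level for intervals.
#' @param seed master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(offset_fraction = 0.22, chroma_threshold = 10,
                       tirads_cutoff = c("sole_ge5", "combined_ge4"),
                       rvi_threshold = 1, ci_level = 0.95, seed = 1L) {
  check_fraction(offset_fraction, "offset_fraction")
  if (chroma_threshold < 0) stop("'chroma_threshold' must be >= 0")
  if (rvi_threshold < 0) stop("'rvi_threshold' must be >= 0")
  if (ci_level <= 0 || ci_level >= 1) stop("'ci_level' must be in (0, 1)")
  structure(
    list(offset_fraction = offset_fraction,
         chroma_threshold = chroma_threshold,
         tirads_cutoff = match.arg(tirads_cutoff),
         rvi_threshold = rvi_threshold, ci_level = ci_level,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Serialise and restore a run configuration
#'
#' Configurations round-trip unchanged through JSON.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- c("offset_fraction", "chroma_threshold", "rvi_threshold", "ci_level")
  x[num] <- lapply(x[num], as.numeric)
  do.call(run_config, x)
}

parse_image_name <- function(stem) {
  m <- regmatches(stem, regexec("^(.*)_(CFI|ACFI|PDI|APDI)_r([0-9]+)$", stem))[[1]]
  if (length(m) == 4L)
    list(nodule = m[2], mode = m[3], replicate = as.integer(m[4]))
  else
    list(nodule = stem, mode = NA_character_, replicate = 1L)
}

#' Quantify regional vascularity of a directory of Doppler images
#'
#' For every PNG in `image_dir` with a same-named ROI mask in `mask_dir`:
#' partitions the ROI at the configured offset, detects colour pixels, and
#' computes peripheral/central/overall VIs. Filenames of the form
#' `<nodule>_<mode>_r<k>.png` are grouped as replicates of one nodule and
#' mode; other names are treated as single-replicate nodules. Replicates are
#' then averaged with [aggregate_replicates()] to form RVIs and suspicion
#' labels; non-vascular records (both mean VIs zero) are excluded from the
#' aggregated table with a message.
#'
#' Per-file failures (missing mask, dimension mismatch, unreadable file) do
#' not abort the run; they are collected and reported in the result.
#'
#' @param image_dir directory of 8-bit RGB PNG images.
#' @param mask_dir directory of single-channel PNG masks (0/255).
#' @param config a [run_config()].
#' @return List with `replicates` (one row per image), `aggregated` (one row
#'   per nodule and mode, with `rvi` and `suspicion`), and `failures`.
#' @export
run_quantify <- function(image_dir, mask_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  files <- sort(list.files(image_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no images found in ", image_dir)
  rows <- list(); fails <- list()
  for (f in files) {
    stem <- sub("\\.png$", "", basename(f))
    info <- parse_image_name(stem)
    mask_path <- file.path(mask_dir, basename(f))
    res <- tryCatch({
      if (!file.exists(mask_path)) stop("missing mask for ", basename(f))
      img <- png::readPNG(f)
      if (length(dim(img)) != 3L) stop("not an RGB image: ", basename(f))
      img <- img[, , 1:3, drop = FALSE] * 255
      mask <- read_mask_png(mask_path)
      if (!identical(dim(mask), dim(img)[1:2]))
        stop("image/mask dimension mismatch for ", basename(f))
      part <- partition_regions(mask, config$offset_fraction)
      cm <- detect_colour_pixels(img, config$chroma_threshold)
      a <- region_areas(part)
      data.frame(nodule = info$nodule, mode = info$mode,
                 replicate = info$replicate, file = basename(f),
                 vi_p = compute_vi(cm, part$peripheral),
                 vi_c = compute_vi(cm, part$central),
                 vi_overall = compute_vi(cm, mask),
                 area_central = a[["central"]],
                 area_peripheral = a[["peripheral"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) fails[[basename(f)]] <- res else
      rows[[length(rows) + 1L]] <- res
  }
  if (length(fails))
    message(length(fails), " file(s) failed quantification; see $failures")
  reps <- do.call(rbind, rows)
  agg <- NULL
  dropped <- 0L
  if (!is.null(reps)) {
    for (key in unique(paste(reps$nodule, reps$mode, sep = "\r"))) {
      g <- reps[paste(reps$nodule, reps$mode, sep = "\r") == key, ]
      vm <- aggregate_replicates(g$vi_p, g$vi_c,
        areas = c(central = g$area_central[1], peripheral = g$area_peripheral[1]),
        mode = g$mode[1], rvi_threshold = config$rvi_threshold)
      if (vm$suspicion == "non_vascular") { dropped <- dropped + 1L; next }
      agg <- rbind(agg, data.frame(
        nodule = g$nodule[1], mode = g$mode[1], n_replicates = vm$n_replicates,
        vi_p = vm$vi_peripheral, vi_c = vm$vi_central,
        vi_overall = vm$vi_overall, rvi = vm$rvi, suspicion = vm$suspicion,
        stringsAsFactors = FALSE))
    }
  }
  if (dropped > 0L)
    message(dropped, " non-vascular record(s) excluded from the aggregated table")
  list(replicates = reps, aggregated = agg,
       failures = if (length(fails)) data.frame(file = names(fails),
         error = unlist(fails), row.names = NULL) else NULL)
}

eval_required_columns <- c("truth", "equivocal", "tirads_category",
                           paste0("grade_", doppler_modes),
                           paste0("rvi_", doppler_modes))

#' Evaluate all sole and combined assessments on a cohort table
#'
#' Computes diagnostic performance for the study's eleven assessments — sole
#' EU TIRADS, qualitative grading per Doppler mode, RVI classification per
#' mode, and EU TIRADS (cut-off >= 4) combined with APDI by the AND rule for
#' both vascularity approaches — each on all nodules and on the
#' cytologically-equivocal subset. Rows whose RVI is undefined because both
#' regional VIs are zero (non-vascular) are excluded from RVI-based
#' assessments with a message.
#'
#' @param cohort a cohort table, e.g. from [generate_cohort()]; must carry
#'   `truth`, `equivocal`, `tirads_category`, and per-mode `grade_<mode>` and
#'   `rvi_<mode>` columns (an informative error names any missing one).
#' @param config a [run_config()].
#' @return List with `reports` (nested list, assessment x cohort, of
#'   [performance()] reports) and `summary` (tidy data frame, one row per
#'   assessment and cohort).
#' @export
run_evaluate <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  miss <- setdiff(eval_required_columns, names(cohort))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  truth <- cohort$truth
  pred_of <- function(sus) ifelse(sus == "malignant_suspicious",
                                  "malignant", "benign")
  tirads_sole <- classify_tirads(cohort$tirads_category, config$tirads_cutoff)
  tirads_comb <- classify_tirads(cohort$tirads_category, "combined_ge4")

  assessments <- list()
  assessments[["EU"]] <- list(
    pred = ifelse(tirads_sole, "malignant", "benign"), keep = rep(TRUE, nrow(cohort)))
  for (m in doppler_modes) {
    sus <- classify_qualitative(cohort[[paste0("grade_", m)]])
    assessments[[paste0("Qual_", m)]] <- list(pred = pred_of(sus),
                                              keep = rep(TRUE, nrow(cohort)))
  }
  for (m in doppler_modes) {
    rvi <- cohort[[paste0("rvi_", m)]]
    keep <- !is.nan(rvi)
    sus <- rep(NA_character_, nrow(cohort))
    sus[keep] <- classify_rvi(rvi[keep], config$rvi_threshold)
    if (any(!keep))
      message(sum(!keep), " non-vascular record(s) excluded from RVI_", m)
    assessments[[paste0("RVI_", m)]] <- list(pred = pred_of(sus), keep = keep)
  }
  qual_apdi <- classify_qualitative(cohort$grade_APDI)
  assessments[["EU_APDI_Qual"]] <- list(
    pred = combine_assessments(tirads_comb, qual_apdi),
    keep = rep(TRUE, nrow(cohort)))
  rvi_apdi <- cohort$rvi_APDI
  keep <- !is.nan(rvi_apdi)
  pred <- rep(NA_character_, nrow(cohort))
  pred[keep] <- combine_assessments(tirads_comb[keep],
    classify_rvi(rvi_apdi[keep], config$rvi_threshold))
  assessments[["EU_APDI_RVI"]] <- list(pred = pred, keep = keep)

  reports <- list()
  rows <- list()
  for (a in names(assessments)) {
    for (coh in c("all", "equivocal")) {
      sel <- assessments[[a]]$keep &
        (if (coh == "equivocal") cohort$equivocal else TRUE)
      rep_ <- performance(confusion_matrix(assessments[[a]]$pred[sel],
                                           truth[sel]), config$ci_level)
      reports[[a]][[coh]] <- rep_
      rows[[length(rows) + 1L]] <-
        cbind(assessment = a, cohort = coh, summary(rep_))
    }
  }
  list(reports = reports, summary = do.call(rbind, rows))
}

#' Paired comparisons between Doppler modes and assessments
#'
#' For one vascularity family (qualitative grading or RVI classification)
#' compares the four Doppler modes on the same nodules: McNemar tests of
#' sensitivity (within malignant nodules) and specificity (within benign
#' nodules) for every mode pair, Cochran's Q across all modes within each
#' class, and unpaired z-tests between the modes' single-operating-point
#' AUROCs. Significance is marked `*` at p < 0.05 and `***` at p < 0.001.
#'
#' @param cohort a cohort table (see [run_evaluate()]).
#' @param config a [run_config()].
#' @param family `"qualitative"` or `"rvi"`.
#' @return List of data frames: `mcnemar` (mode pair x class), `cochran_q`
#'   (one row per class), `auroc_z` (mode pair).
#' @export
run_compare <- function(cohort, config = run_config(),
                        family = c("qualitative", "rvi")) {
  family <- match.arg(family)
  miss <- setdiff(eval_required_columns, names(cohort))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  ind <- sapply(doppler_modes, function(m) {
    if (family == "qualitative")
      classify_qualitative(cohort[[paste0("grade_", m)]]) == "malignant_suspicious"
    else
      classify_rvi(cohort[[paste0("rvi_", m)]], config$rvi_threshold) ==
        "malignant_suspicious"
  })
  mal <- cohort$truth == "malignant"
  sig <- function(p) ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
  pairs <- utils::combn(doppler_modes, 2)
  mc_rows <- list(); z_rows <- list()
  for (k in seq_len(ncol(pairs))) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    for (cls in c("malignant", "benign")) {
      sel <- if (cls == "malignant") mal else !mal
      d <- discordant_counts(ind[sel, m1], ind[sel, m2])
      tst <- mcnemar_test(d[["b"]], d[["c"]])
      mc_rows[[length(mc_rows) + 1L]] <- data.frame(
        pair = paste(m1, "vs", m2),
        measure = if (cls == "malignant") "sensitivity" else "specificity",
        b = d[["b"]], c = d[["c"]], p = tst$p_value, sig = sig(tst$p_value),
        stringsAsFactors = FALSE)
    }
    p1 <- performance(confusion_matrix(
      ifelse(ind[, m1], "malignant", "benign"), cohort$truth), config$ci_level)
    p2 <- performance(confusion_matrix(
      ifelse(ind[, m2], "malignant", "benign"), cohort$truth), config$ci_level)
    zt <- auroc_z_test(p1$auroc, p1$n_pos, p1$n_neg,
                       p2$auroc, p2$n_pos, p2$n_neg)
    z_rows[[length(z_rows) + 1L]] <- data.frame(
      pair = paste(m1, "vs", m2), auroc1 = p1$auroc, auroc2 = p2$auroc,
      z = zt$statistic, p = zt$p_value, sig = sig(zt$p_value),
      stringsAsFactors = FALSE)
  }
  cq <- lapply(c(malignant = "malignant", benign = "benign"), function(cls) {
    sel <- if (cls == "malignant") mal else !mal
    cochran_q(ind[sel, , drop = FALSE])
  })
  list(
    mcnemar = do.call(rbind, mc_rows),
    cochran_q = data.frame(
      class = names(cq),
      Q = vapply(cq, function(t) t$statistic, numeric(1)),
      df = vapply(cq, function(t) t$df, numeric(1)),
      p = vapply(cq, function(t) t$p_value, numeric(1)),
      sig = sig(vapply(cq, function(t) t$p_value, numeric(1))),
      row.names = NULL, stringsAsFactors = FALSE),
    auroc_z = do.call(rbind, z_rows)
  )
}

#' Reported operating points of the clinical evaluation cohort
#'
#' The sensitivities, specificities, predictive values and AUROCs reported
#' for the thyroid-nodule cohort the method was developed on: 94 nodules (30
#' malignant, 64 benign), of which 40 were cytologically equivocal (9
#' malignant, 31 benign). Because PPV, NPV and the single-operating-point
#' AUROC are deterministic functions of the confusion matrix, each column can
#' be reconstructed from its printed SEN/SPEC and the class sizes with
#' [confusion_from_rates()] and re-derived with [performance()]; see
#' [check_reported_consistency()].
#'
#' @return Data frame with one row per assessment and cohort: `assessment`,
#'   `cohort` (`"all"`/`"equivocal"`), printed `sen`, `spec`, `ppv`, `npv`,
#'   `auroc`, and class sizes `n_pos`, `n_neg`.
#' @export
study_operating_points <- function() {
  rows <- rbind(
    c("EU",           "all", 83.3, 50.0, 43.9, 86.5, 0.67),
    c("EU",           "equivocal", 88.9, 38.7, 29.6, 92.3, 0.62),
    c("Qual_CFI",     "all", 53.3, 92.2, 76.2, 80.8, 0.73),
    c("Qual_ACFI",    "all", 80.0, 82.8, 68.6, 89.8, 0.81),
    c("Qual_PDI",     "all", 46.7, 95.3, 82.4, 79.2, 0.71),
    c("Qual_APDI",    "all", 83.3, 81.3, 67.6, 91.2, 0.82),
    c("Qual_CFI",     "equivocal", 66.7, 90.3, 66.7, 90.3, 0.79),
    c("Qual_ACFI",    "equivocal", 88.9, 80.6, 57.1, 96.2, 0.85),
    c("Qual_PDI",     "equivocal", 66.7, 93.5, 75.0, 90.6, 0.80),
    c("Qual_APDI",    "equivocal", 100.0, 77.4, 56.3, 100.0, 0.89),
    c("RVI_CFI",      "all", 56.7, 81.3, 58.6, 80.0, 0.69),
    c("RVI_ACFI",     "all", 60.0, 73.4, 51.4, 79.7, 0.67),
    c("RVI_PDI",      "all", 46.7, 65.6, 38.9, 72.4, 0.56),
    c("RVI_APDI",     "all", 66.7, 73.4, 54.1, 82.5, 0.70),
    c("RVI_CFI",      "equivocal", 66.7, 83.9, 54.5, 89.7, 0.75),
    c("RVI_ACFI",     "equivocal", 55.6, 67.7, 33.3, 84.0, 0.62),
    c("RVI_PDI",      "equivocal", 33.3, 61.3, 20.0, 76.0, 0.47),
    c("RVI_APDI",     "equivocal", 77.8, 74.2, 46.7, 92.0, 0.76),
    c("EU_APDI_Qual", "all", 76.7, 84.4, 69.7, 88.5, 0.81),
    c("EU_APDI_Qual", "equivocal", 88.9, 77.4, 53.3, 96.0, 0.83),
    c("EU_APDI_RVI",  "all", 58.1, 81.0, 60.0, 79.7, 0.70),
    c("EU_APDI_RVI",  "equivocal", 66.7, 74.2, 42.9, 88.5, 0.70)
  )
  out <- data.frame(assessment = rows[, 1], cohort = rows[, 2],
                    sen = as.numeric(rows[, 3]), spec = as.numeric(rows[, 4]),
                    ppv = as.numeric(rows[, 5]), npv = as.numeric(rows[, 6]),
                    auroc = as.numeric(rows[, 7]), stringsAsFactors = FALSE)
  out$n_pos <- ifelse(out$cohort == "all", 30L, 9L)
  out$n_neg <- ifelse(out$cohort == "all", 64L, 31L)
  out
}

#' Check internal consistency of the reported performance tables
#'
#' Reconstructs every reported column's confusion matrix from its printed
#' SEN/SPEC and the class sizes, re-derives PPV, NPV and the
#' single-operating-point AUROC with [performance()], and compares them to
#' the printed values at the tables' rounding (percents to 1 decimal, AUROC
#' to 2, half away from zero). Columns whose printed SEN or SPEC is not
#' attainable by any integer count are flagged `rates_consistent = FALSE`.
#'
#' @param points operating-point table, by default
#'   [study_operating_points()].
#' @return `points` with recomputed `ppv_rec`, `npv_rec`, `auroc_rec`, the
#'   per-cell match flags `ppv_ok`, `npv_ok`, `auroc_ok`, and
#'   `rates_consistent`.
#' @export
check_reported_consistency <- function(points = study_operating_points()) {
  res <- points
  res$ppv_rec <- res$npv_rec <- res$auroc_rec <- NA_real_
  res$rates_consistent <- TRUE
  for (i in seq_len(nrow(points))) {
    cm <- withCallingHandlers(
      confusion_from_rates(points$sen[i], points$spec[i],
                           points$n_pos[i], points$n_neg[i]),
      warning = function(w) {
        res$rates_consistent[i] <<- FALSE
        invokeRestart("muffleWarning")
      })
    p <- performance(cm)
    res$ppv_rec[i] <- round_half_out(p$ppv, 1)
    res$npv_rec[i] <- round_half_out(p$npv, 1)
    res$auroc_rec[i] <- round_half_out(p$auroc, 2)
  }
  res$ppv_ok <- res$ppv_rec == res$ppv
  res$npv_ok <- res$npv_rec == res$npv
  res$auroc_ok <- res$auroc_rec == res$auroc
  res
}
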