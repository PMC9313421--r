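doppler_modes <- c("CFI", "ACFI", "PDI", "APDI")

# Default per-mode operating points for the simulated indicators: the
# reported qualitative-grading and RVI-based sensitivities/specificities of
# the clinical evaluation cohort (all-nodule analysis, fractions).
default_qual_sen  <- c(CFI = 0.533, ACFI = 0.800, PDI = 0.467, APDI = 0.833)
default_qual_spec <- c(CFI = 0.922, ACFI = 0.828, PDI = 0.953, APDI = 0.813)
default_rvi_sen   <- c(CFI = 0.567, ACFI = 0.600, PDI = 0.467, APDI = 0.667)
default_rvi_spec  <- c(CFI = 0.813, ACFI = 0.734, PDI = 0.656, APDI = 0.734)

#' Specify a simulated nodule cohort
#'
#' Describes the cohort structure of the clinical study the pipeline
#' emulates: 94 nodules (30 malignant, 64 benign), of which 40 had equivocal
#' cytology (9 malignant, 31 benign), each with a grey-scale EU TIRADS
#' category, a qualitative vascularity grade and three replicate regional VI
#' readings per Doppler mode (CFI, ACFI, PDI, APDI).
#'
#' Two per-mode operating-point maps drive the vascularity indicators: the
#' qualitative-grading map (behind grades I-IV) and the quantitative map
#' (behind the simulated RVIs). For a malignant nodule the
#' malignancy-suspicious indicator is Bernoulli(SEN of the mode); for a
#' benign nodule Bernoulli(1 - SPEC). Indicators are independent across
#' modes given truth unless `mode_correlation > 0`, which couples them
#' through a shared Gaussian latent. The equivocal flag is assigned
#' independently of the indicators given truth.
#'
#' @param n_total,n_malignant cohort size and number of malignant nodules.
#' @param n_equivocal_malignant,n_equivocal_benign cytologically-equivocal
#'   counts per class.
#' @param per_mode_sensitivity,per_mode_specificity named fractions (modes
#'   CFI/ACFI/PDI/APDI) for the qualitative-grading indicator.
#' @param quant_sensitivity,quant_specificity same, for the RVI-based
#'   indicator that the simulated replicate VIs realise.
#' @param tirads_probs_malignant,tirads_probs_benign probabilities over EU
#'   TIRADS categories 2-5 per truth class; each must sum to 1.
#' @param n_replicates replicate VI readings per nodule per mode (default 3).
#' @param replicate_sd Gaussian jitter of per-replicate regional VIs around
#'   the nodule mean, VI points (default 3).
#' @param mode_correlation shared-latent correlation of indicators across
#'   modes, in `[0, 1)` (default 0, independent).
#' @param seed master seed; all per-nodule randomness derives from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total = 94, n_malignant = 30,
                        n_equivocal_malignant = 9, n_equivocal_benign = 31,
                        per_mode_sensitivity = default_qual_sen,
                        per_mode_specificity = default_qual_spec,
                        quant_sensitivity = default_rvi_sen,
                        quant_specificity = default_rvi_spec,
                        tirads_probs_malignant =
                          c(`2` = 0.033, `3` = 0.067, `4` = 0.067, `5` = 0.833),
                        tirads_probs_benign =
                          c(`2` = 0.20, `3` = 0.20, `4` = 0.10, `5` = 0.50),
                        n_replicates = 3, replicate_sd = 3,
                        mode_correlation = 0, seed = 1L) {
  n_benign <- n_total - n_malignant
  if (n_malignant < 0 || n_benign < 0)
    stop("infeasible counts: n_malignant must be in [0, n_total]")
  if (n_malignant == 0 || n_benign == 0)
    stop("infeasible counts: both classes must be non-empty")
  if (n_equivocal_malignant < 0 || n_equivocal_malignant > n_malignant)
    stop("infeasible counts: n_equivocal_malignant exceeds n_malignant")
  if (n_equivocal_benign < 0 || n_equivocal_benign > n_benign)
    stop("infeasible counts: n_equivocal_benign exceeds n_benign")
  for (m in list(per_mode_sensitivity, per_mode_specificity,
                 quant_sensitivity, quant_specificity)) {
    if (!all(doppler_modes %in% names(m)))
      stop("operating-point maps must name all modes: ",
           paste(doppler_modes, collapse = ", "))
    check_fraction(m, "operating point")
  }
  for (p in list(tirads_probs_malignant, tirads_probs_benign)) {
    check_fraction(p, "tirads category probability")
    if (abs(sum(p) - 1) > 1e-6) stop("TIRADS category probabilities must sum to 1")
  }
  check_fraction(mode_correlation, "mode_correlation")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(
    list(n_total = as.integer(n_total), n_malignant = as.integer(n_malignant),
         n_benign = as.integer(n_benign),
         n_equivocal_malignant = as.integer(n_equivocal_malignant),
         n_equivocal_benign = as.integer(n_equivocal_benign),
         per_mode_sensitivity = per_mode_sensitivity[doppler_modes],
         per_mode_specificity = per_mode_specificity[doppler_modes],
         quant_sensitivity = quant_sensitivity[doppler_modes],
         quant_specificity = quant_specificity[doppler_modes],
         tirads_probs_malignant = tirads_probs_malignant,
         tirads_probs_benign = tirads_probs_benign,
         n_replicates = as.integer(n_replicates),
         replicate_sd = replicate_sd,
         mode_correlation = mode_correlation, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# canonical grey-scale feature set realising a given EU TIRADS category;
# for category 5 one high-risk feature is chosen at random
features_for_category <- function(category) {
  n <- length(category)
  comp <- ifelse(category == 2L, "spongiform", "solid")
  echo <- ifelse(category == 4L, "mildly_hypoechoic", "isoechoic")
  margins <- rep("smooth", n)
  taller <- rep(FALSE, n)
  calc <- rep(FALSE, n)
  i5 <- which(category == 5L)
  if (length(i5)) {
    pick <- sample(c("margins", "echo", "taller", "calc"), length(i5),
                   replace = TRUE)
    margins[i5][pick == "margins"] <- "irregular"
    echo[i5][pick == "echo"] <- "markedly_hypoechoic"
    taller[i5][pick == "taller"] <- TRUE
    calc[i5][pick == "calc"] <- TRUE
  }
  data.frame(composition = comp, echogenicity = echo, margins = margins,
             taller_than_wide = taller, microcalcifications = calc,
             shape_oval = !taller, stringsAsFactors = FALSE)
}

# Bernoulli indicator of malignancy-suspicion at a per-mode operating point,
# optionally coupled across modes through a shared Gaussian latent.
draw_indicator <- function(malignant, sen, spec, z_shared, rho) {
  n <- length(malignant)
  u <- stats::pnorm(rho * z_shared + sqrt(1 - rho^2) * stats::rnorm(n))
  p <- ifelse(malignant, sen, 1 - spec)
  u < p
}

#' Simulate a nodule cohort table
#'
#' Draws a cohort with exactly the class and equivocal counts of the spec:
#' truth labels, equivocal flags, EU TIRADS categories (from the per-truth
#' distributions) with a consistent grey-scale feature record, a qualitative
#' vascularity grade per mode (I/II when the qualitative indicator is
#' benign-suspicious, III/IV otherwise), and replicate regional VI readings
#' per mode whose replicate-mean RVI realises the quantitative indicator.
#' Replicate VIs are the nodule mean plus Gaussian jitter
#' (`replicate_sd`), truncated to `[0, 100]`.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with one row per nodule: `nodule_id`, `truth`,
#'   `equivocal`, `tirads_category`, the grey-scale feature columns, and per
#'   mode `grade_<mode>`, replicate columns `vi_p_<mode>_r<k>` /
#'   `vi_c_<mode>_r<k>`, replicate means `vi_p_<mode>` / `vi_c_<mode>`, and
#'   `rvi_<mode>`. Identical spec and seed give an identical table.
#' @examples
#' head(generate_cohort(cohort_spec(seed = 7)), 3)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_total
  with_seed(spec$seed, {
    truth <- sample(c(rep("malignant", spec$n_malignant),
                      rep("benign", spec$n_benign)))
    mal <- truth == "malignant"
    equivocal <- logical(n)
    im <- which(mal); ib <- which(!mal)
    equivocal[im[sample.int(length(im), spec$n_equivocal_malignant)]] <- TRUE
    equivocal[ib[sample.int(length(ib), spec$n_equivocal_benign)]] <- TRUE

    category <- integer(n)
    category[mal] <- sample(2:5, sum(mal), replace = TRUE,
                            prob = spec$tirads_probs_malignant)
    category[!mal] <- sample(2:5, sum(!mal), replace = TRUE,
                             prob = spec$tirads_probs_benign)
    feats <- features_for_category(category)

    out <- data.frame(nodule_id = sprintf("nod%05d", seq_len(n)),
                      truth = truth, equivocal = equivocal,
                      tirads_category = category, feats,
                      stringsAsFactors = FALSE)

    z_qual <- stats::rnorm(n)
    z_quant <- stats::rnorm(n)
    rho <- spec$mode_correlation
    for (m in doppler_modes) {
      qual_sus <- draw_indicator(mal, spec$per_mode_sensitivity[[m]],
                                 spec$per_mode_specificity[[m]], z_qual, rho)
      grade <- character(n)
      grade[qual_sus] <- sample(c("III", "IV"), sum(qual_sus), replace = TRUE)
      grade[!qual_sus] <- sample(c("I", "II"), sum(!qual_sus), replace = TRUE)

      quant_sus <- draw_indicator(mal, spec$quant_sensitivity[[m]],
                                  spec$quant_specificity[[m]], z_quant, rho)
      # nodule-mean regional VIs realising the intended RVI side:
      # suspicious (RVI <= 1) -> central dominant, else peripheral dominant
      dominant <- stats::runif(n, 25, 65)
      ratio <- stats::runif(n, 0.45, 0.90)
      vi_p_mean <- ifelse(quant_sus, dominant * ratio, dominant)
      vi_c_mean <- ifelse(quant_sus, dominant, dominant * ratio)
      reps_p <- matrix(NA_real_, n, spec$n_replicates)
      reps_c <- matrix(NA_real_, n, spec$n_replicates)
      for (k in seq_len(spec$n_replicates)) {
        reps_p[, k] <- pmin(pmax(vi_p_mean +
          stats::rnorm(n, 0, spec$replicate_sd), 0), 100)
        reps_c[, k] <- pmin(pmax(vi_c_mean +
          stats::rnorm(n, 0, spec$replicate_sd), 0), 100)
      }
      # jitter can flip the replicate-mean RVI across the threshold near 1;
      # swap regions where it disagrees with the intended indicator
      mp <- rowMeans(reps_p); mc <- rowMeans(reps_c)
      flip <- (mp > mc) == quant_sus
      if (any(flip)) {
        tmp <- reps_p[flip, , drop = FALSE]
        reps_p[flip, ] <- reps_c[flip, , drop = FALSE]
        reps_c[flip, ] <- tmp
        t2 <- mp[flip]; mp[flip] <- mc[flip]; mc[flip] <- t2
      }
      for (k in seq_len(spec$n_replicates)) {
        out[[sprintf("vi_p_%s_r%d", m, k)]] <- reps_p[, k]
        out[[sprintf("vi_c_%s_r%d", m, k)]] <- reps_c[, k]
      }
      out[[paste0("grade_", m)]] <- grade
      out[[paste0("vi_p_", m)]] <- mp
      out[[paste0("vi_c_", m)]] <- mc
      out[[paste0("rvi_", m)]] <- mp / mc
    }
    out
  })
}
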