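# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# Exhaustive boundary-distance partition: boundary = ROI pixels 4-adjacent to
# background (frame edge counts as background); d(p) = min over boundary
# pixels of the Euclidean distance; central iff d >= f * max(d).
oracle_partition <- function(roi, f) {
  nr <- nrow(roi); nc <- ncol(roi)
  is_bg <- function(i, j) i < 1 || i > nr || j < 1 || j > nc || !roi[i, j]
  bnd <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (roi[i, j] && (is_bg(i - 1, j) || is_bg(i + 1, j) ||
                      is_bg(i, j - 1) || is_bg(i, j + 1)))
      bnd <- rbind(bnd, c(i, j))
  }
  d <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (roi[i, j])
      d[i, j] <- sqrt(min((bnd[, 1] - i)^2 + (bnd[, 2] - j)^2))
  }
  dmax <- max(d, na.rm = TRUE)
  central <- !is.na(d) & d >= f * dmax
  list(central = central, peripheral = roi & !central)
}

# per-pixel colour count inside a region using the chroma rule
oracle_colour_count <- function(pixels, region, threshold = 10) {
  n <- 0L
  for (i in seq_len(nrow(region))) for (j in seq_len(ncol(region))) {
    if (region[i, j]) {
      v <- pixels[i, j, ]
      if (max(v) - min(v) > threshold) n <- n + 1L
    }
  }
  n
}

# two-sided exact McNemar p by direct binomial enumeration
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(choose(n, 0:k)) / 2^n)
}

# Cochran Q by direct evaluation of the defining formula
oracle_cochran_q <- function(m) {
  k <- ncol(m)
  (k - 1) * (k * sum(colSums(m)^2) - sum(m)^2) / (k * sum(m) - sum(rowSums(m)^2))
}

# Hanley-McNeil variance, written out independently
oracle_hm_var <- function(a, np, nn) {
  (a * (1 - a) + (np - 1) * (a / (2 - a) - a^2) +
     (nn - 1) * (2 * a^2 / (1 + a) - a^2)) / (np * nn)
}

# table-style rounding (half away from zero), as the reported tables use
round_1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
round_2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# build a confusion matrix from counts through the public tallying interface
make_cm <- function(tp, fn, fp, tn) {
  confusion_matrix(
    c(rep("malignant", tp), rep("benign", fn),
      rep("malignant", fp), rep("benign", tn)),
    c(rep("malignant", tp + fn), rep("benign", fp + tn)))
}
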