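# Exact Euclidean distance transform to an arbitrary site set, computed with
# the two-pass lower-envelope algorithm on squared distances (Felzenszwalb &
# Huttenlocher). Exact on integer pixel grids, O(n) per scanline.

# 1-D squared-distance transform: d[q] = min_p (q - p)^2 + f[p].
# Entries of f may be Inf (no site); the envelope is built over finite ones.
dt1d <- function(f) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (length(idx) == 0L) return(rep(Inf, n))
  v <- integer(length(idx))
  z <- numeric(length(idx) + 1L)
  k <- 1L
  v[1L] <- idx[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  if (length(idx) > 1L) {
    for (q in idx[-1L]) {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
      while (s <= z[k]) {
        k <- k - 1L
        s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Squared Euclidean distance from every pixel to the nearest TRUE pixel of
# `sites` (a logical matrix). Inf where no site exists.
squared_distance_to_sites <- function(sites) {
  nr <- nrow(sites); nc <- ncol(sites)
  f <- matrix(Inf, nr, nc)
  f[sites] <- 0
  for (j in seq_len(nc)) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt1d(f[i, ])
  # squared distances between integer grid points are integers; snap to
  # remove any floating-point residue from envelope arithmetic
  f[is.finite(f)] <- round(f[is.finite(f)])
  f
}

# Boundary of a binary ROI: ROI pixels 4-adjacent to background (frame edges
# count as background).
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !(up & down & left & right)
}

# Euclidean distance of every ROI pixel to the ROI boundary (boundary pixels
# themselves are at distance 0); NA outside the ROI.
distance_to_boundary <- function(mask) {
  b <- boundary_pixels(mask)
  d2 <- squared_distance_to_sites(b)
  d <- sqrt(d2)
  d[!mask] <- NA_real_
  d
}
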