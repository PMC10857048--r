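# Independent oracles, written as plain scalar loops so they share no
# code path with the package implementation.

# Direct evaluation of the four-neighbour weighted average at every
# output cell under the align-corners map.
oracle_bilinear <- function(src, ipf) {
  sr <- nrow(src); sc <- ncol(src)
  mr <- sr * ipf; mc <- sc * ipf
  out <- matrix(NA_real_, mr, mc)
  for (j in seq_len(mr)) {
    for (k in seq_len(mc)) {
      x <- (j - 1) * (sr - 1) / (mr - 1)
      y <- (k - 1) * (sc - 1) / (mc - 1)
      x0 <- min(floor(x), sr - 2)
      y0 <- min(floor(y), sc - 2)
      f <- x - x0
      g <- y - y0
      i00 <- src[x0 + 1, y0 + 1]; i10 <- src[x0 + 2, y0 + 1]
      i01 <- src[x0 + 1, y0 + 2]; i11 <- src[x0 + 2, y0 + 2]
      out[j, k] <- (1 - f) * (1 - g) * i00 + f * (1 - g) * i10 +
        (1 - f) * g * i01 + f * g * i11
    }
  }
  out
}

# Scalar re-summation of the silhouette coverage fraction: midpoint
# subsampling of each pixel against the scaled ellipse.
oracle_coverage <- function(axes_row, axes_col, center_row, center_col,
                            n_sub = 15L) {
  total <- 0
  for (r in 1:8) for (c in 1:8) {
    hits <- 0
    for (a in seq_len(n_sub)) for (b in seq_len(n_sub)) {
      u <- (r - 1) + (a - 0.5) / n_sub
      v <- (c - 1) + (b - 0.5) / n_sub
      if (((u - center_row) / axes_row)^2 +
          ((v - center_col) / axes_col)^2 <= 1) hits <- hits + 1
    }
    total <- total + hits / n_sub^2
  }
  total / 64
}

# Mean of the bilinearly upsampled grid, computed without building the
# grid: the align-corners resampling is separable, so the mean is a
# weighted average of source pixels with per-axis weights accumulated by
# a scalar loop over output positions.
oracle_interp_mean <- function(src, ipf) {
  sr <- nrow(src); sc <- ncol(src)
  axis_weights <- function(s, m) {
    w <- numeric(s)
    for (j in seq_len(m)) {
      x <- (j - 1) * (s - 1) / (m - 1)
      x0 <- min(floor(x), s - 2)
      f <- x - x0
      w[x0 + 1] <- w[x0 + 1] + (1 - f)
      w[x0 + 2] <- w[x0 + 2] + f
    }
    w / m
  }
  wr <- axis_weights(sr, sr * ipf)
  wc <- axis_weights(sc, sc * ipf)
  total <- 0
  for (r in seq_len(sr)) for (c in seq_len(sc)) {
    total <- total + wr[r] * wc[c] * src[r, c]
  }
  total
}

# Constant-temperature frame helper.
const_frame <- function(temp, thermistor = 18, timestamp = 0) {
  thermal_frame(matrix(temp, 8, 8), thermistor = thermistor,
                timestamp = timestamp)
}

random_frame <- function(lo = 10, hi = 30, thermistor = 18) {
  thermal_frame(matrix(runif(64, lo, hi), 8, 8), thermistor = thermistor)
}
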