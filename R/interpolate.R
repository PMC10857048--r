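#' Bilinear upsampling of a temperature grid
#'
#' Upsamples a low-resolution temperature grid by an integer magnification
#' factor using bilinear interpolation, producing the smooth silhouette
#' map the posture detector operates on. Each output cell is the weighted
#' average of its four bracketing source pixels,
#' \deqn{I(x, y) = (1-f)(1-g)\,I_{00} + f(1-g)\,I_{10} + (1-f)g\,I_{01} + f g\,I_{11},}
#' where \eqn{f} and \eqn{g} are the fractional distances of the target
#' coordinate from the lower bracketing pixel along rows and columns.
#'
#' @param src numeric matrix of temperatures with at least 2 rows and
#'   2 columns (an 8x8 sensor grid in the intended use).
#' @param ipf integer interpolation factor >= 1; the per-axis
#'   magnification. `ipf = 1` is the identity: the input is returned
#'   unchanged.
#'
#' @details The output has dimensions `nrow(src) * ipf` by
#'   `ncol(src) * ipf` (an 8x8 grid at `ipf = 50` becomes 400x400).
#'   Output sample positions follow the align-corners convention: output
#'   index \eqn{j} (0-based) on an axis of output length \eqn{m} maps to
#'   source coordinate \eqn{j (s - 1)/(m - 1)} for source length \eqn{s},
#'   so the first and last output samples coincide with the first and
#'   last source pixels and all interpolation weights stay in \[0, 1\].
#'   When a mapped coordinate lands exactly on the last source row or
#'   column the bracketing cell degenerates (upper index equals lower,
#'   fractional weight 0). Every output value is a convex combination of
#'   source values, hence bounded by `min(src)` and `max(src)`.
#'
#' @return A numeric matrix of dimension `nrow(src)*ipf` x `ncol(src)*ipf`
#'   with attribute `ipf` recording the factor used.
#' @examples
#' z <- bilinear_interpolate(matrix(1:4, 2, 2), ipf = 2)
#' dim(z)  # 4 4
#' @seealso [grid_mean()], [detect_step()]
#' @export
bilinear_interpolate <- function(src, ipf) {
  if (!is.matrix(src) || !is.numeric(src)) {
    stop("'src' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(src) < 2L || ncol(src) < 2L) {
    stop("'src' must have at least 2 rows and 2 columns", call. = FALSE)
  }
  ipf <- check_ipf(ipf)
  storage.mode(src) <- "double"
  if (ipf == 1L) {
    out <- src
    attr(out, "ipf") <- 1L
    return(out)
  }
  nr <- nrow(src) * ipf
  nc <- ncol(src) * ipf
  ax_r <- axis_map(nrow(src), nr)
  ax_c <- axis_map(ncol(src), nc)
  # gather the four neighbour planes as submatrices, then blend
  i00 <- src[ax_r$lo, ax_c$lo, drop = FALSE]
  i10 <- src[ax_r$hi, ax_c$lo, drop = FALSE]
  i01 <- src[ax_r$lo, ax_c$hi, drop = FALSE]
  i11 <- src[ax_r$hi, ax_c$hi, drop = FALSE]
  f <- matrix(ax_r$frac, nr, nc)
  g <- matrix(ax_c$frac, nr, nc, byrow = TRUE)
  # incremental form of the four-weight average: exact for constant
  # fields and at f = 0 / g = 0 (corners, identity at factor 1)
  out <- i00 + f * (i10 - i00) + g * (i01 - i00) +
    f * g * ((i11 - i01) - (i10 - i00))
  attr(out, "ipf") <- ipf
  out
}

# Align-corners coordinate map for one axis: 0-based output index j maps
# to source coordinate j*(s-1)/(m-1). Returns 1-based bracketing indices
# and the fractional weight; an exact hit on the last pixel degenerates
# (hi == lo, frac 0).
axis_map <- function(s, m) {
  x <- (seq_len(m) - 1) * (s - 1) / (m - 1)
  lo <- floor(x)
  frac <- x - lo
  hi <- lo + 1
  at_end <- lo >= s - 1
  lo[at_end] <- s - 1
  hi[at_end] <- s - 1
  frac[at_end] <- 0
  list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, frac = frac)
}

check_ipf <- function(ipf) {
  if (length(ipf) != 1L || is.na(ipf) || ipf < 1 || ipf != round(ipf)) {
    stop("'ipf' must be a single integer >= 1", call. = FALSE)
  }
  as.integer(ipf)
}

#' Mean temperature of a grid
#'
#' Arithmetic mean over all cells of a temperature grid, either a raw
#' sensor grid or an interpolated silhouette map.
#'
#' @param grid numeric matrix (or a `thermal_frame`, whose pixel matrix
#'   is used).
#' @return The mean temperature in degrees Celsius.
#' @export
grid_mean <- function(grid) {
  if (inherits(grid, "thermal_frame")) grid <- grid$pixels
  if (!is.numeric(grid) || length(grid) == 0L) {
    stop("'grid' must be a non-empty numeric grid", call. = FALSE)
  }
  mean(grid)
}
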