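#' Numerical image gradient
#'
#' Computes the per-pixel gradient field of a 2D intensity grid using
#' central differences (unit spacing) at interior pixels and one-sided
#' first-order differences at boundary pixels — the standard numerical
#' gradient. `x` runs along columns and `y` along rows, so `gx` is the
#' horizontal and `gy` the vertical partial derivative. Magnitude is
#' `sqrt(gx^2 + gy^2)` and direction is `atan2(gy, gx)` in `(-pi, pi]`,
#' with direction 0 wherever the gradient vanishes (the `atan2(0, 0)`
#' convention). This scheme is exact on affine images, and gradients
#' annihilate additive intensity shifts.
#'
#' @param slice numeric matrix with at least 2 rows and 2 columns, finite.
#' @return An object of class `gradient_field`: a list with matrices `gx`,
#'   `gy`, `gmag`, `gdir`, all the shape of `slice`.
#' @examples
#' g <- compute_gradient(outer(1:5, 1:5, function(y, x) 2 * x + 3 * y))
#' unique(as.vector(g$gx))  # 2
#' @export
compute_gradient <- function(slice) {
  if (!is.matrix(slice) || nrow(slice) < 2L || ncol(slice) < 2L) {
    stop("'slice' must be a matrix with at least 2 rows and 2 columns")
  }
  if (!all(is.finite(slice))) stop("'slice' must contain only finite values")
  nr <- nrow(slice); nc <- ncol(slice)
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (slice[, 3:nc, drop = FALSE] -
                       slice[, 1:(nc - 2), drop = FALSE]) / 2
  gx[, 1] <- slice[, 2] - slice[, 1]
  gx[, nc] <- slice[, nc] - slice[, nc - 1]
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (slice[3:nr, , drop = FALSE] -
                       slice[1:(nr - 2), , drop = FALSE]) / 2
  gy[1, ] <- slice[2, ] - slice[1, ]
  gy[nr, ] <- slice[nr, ] - slice[nr - 1, ]
  structure(list(gx = gx, gy = gy,
                 gmag = gradient_magnitude(gx, gy),
                 gdir = gradient_direction(gx, gy)),
            class = "gradient_field")
}

#' Gradient magnitude
#'
#' Element-wise `sqrt(gx^2 + gy^2)`: the strength of local intensity
#' variation, highlighting edges and boundaries.
#'
#' @param gx,gy gradient component matrices of equal shape.
#' @return Nonnegative matrix of the same shape.
#' @export
gradient_magnitude <- function(gx, gy) {
  if (!identical(dim(gx), dim(gy))) stop("'gx' and 'gy' must share a shape")
  sqrt(gx^2 + gy^2)
}

#' Gradient direction
#'
#' Element-wise four-quadrant inverse tangent `atan2(gy, gx)`, in radians in
#' `(-pi, pi]`; zero-gradient pixels map to 0.
#'
#' @param gx,gy gradient component matrices of equal shape.
#' @return Matrix of orientations, same shape.
#' @export
gradient_direction <- function(gx, gy) {
  if (!identical(dim(gx), dim(gy))) stop("'gx' and 'gy' must share a shape")
  atan2(gy, gx)
}

#' Per-block gradient statistics
#'
#' Tiles the slice into non-overlapping `block_size x block_size` blocks
#' (trailing rows/columns that do not fill a block are discarded) and emits,
#' per block, the gradient-magnitude mean, the gradient-magnitude population
#' variance (denominator N) and the circular mean of the gradient direction,
#' `atan2(mean(sin), mean(cos))`. Blocks are visited in row-major order and
#' the three statistics are concatenated grouped by block, so the raw
#' feature vector is `(m1, v1, d1, m2, v2, d2, ...)`.
#'
#' @param gmag,gdir gradient magnitude / direction matrices of equal shape,
#'   at least `block_size` in each dimension.
#' @param block_size side of the square block, default 3.
#' @return List of class `raw_features` with elements `b` (the concatenated
#'   statistics), `bmin`, `bmax`, `mu` (its minimum, maximum and mean) and
#'   `blocks` (tiling dimensions).
#' @export
block_statistics <- function(gmag, gdir, block_size = 3L) {
  if (!identical(dim(gmag), dim(gdir))) {
    stop("'gmag' and 'gdir' must share a shape")
  }
  block_size <- as.integer(block_size)
  nr <- nrow(gmag); nc <- ncol(gmag)
  nbr <- nr %/% block_size; nbc <- nc %/% block_size
  if (nbr < 1L || nbc < 1L) {
    stop("image smaller than one ", block_size, " x ", block_size, " block")
  }
  rows <- seq_len(nbr * block_size)
  cols <- seq_len(nbc * block_size)
  m <- gmag[rows, cols, drop = FALSE]
  d <- gdir[rows, cols, drop = FALSE]
  # Row-major block id for each retained pixel.
  br <- (rows - 1L) %/% block_size           # per-row block row
  bc <- (cols - 1L) %/% block_size           # per-col block col
  bid <- outer(br * nbc, bc, "+") + 1L       # nbr*bs x nbc*bs matrix
  n <- block_size^2
  grp <- as.vector(bid)
  sums <- rowsum(as.vector(m), grp)
  mean_m <- sums / n
  var_m <- rowsum(as.vector(m)^2, grp) / n - mean_m^2
  var_m[var_m < 0] <- 0   # guard tiny negative round-off
  dir_m <- atan2(rowsum(sin(as.vector(d)), grp) / n,
                 rowsum(cos(as.vector(d)), grp) / n)
  b <- as.vector(rbind(as.vector(mean_m), as.vector(var_m), as.vector(dir_m)))
  raw_features(b, blocks = c(nbr, nbc))
}

raw_features <- function(b, blocks = NULL) {
  structure(list(b = b, bmin = min(b), bmax = max(b), mu = mean(b),
                 blocks = blocks),
            class = "raw_features")
}

#' Min-max normalization of a feature vector
#'
#' Rescales the whole vector linearly to `[0, 1]` using its own minimum and
#' maximum. A constant vector maps to all zeros (the declared degenerate
#' case). Idempotent.
#'
#' @param b nonempty finite numeric vector (or a `raw_features` object,
#'   whose `$b` is used).
#' @return Numeric vector in `[0, 1]`, same length.
#' @export
normalize_vector <- function(b) {
  if (inherits(b, "raw_features")) b <- b$b
  if (length(b) == 0L) stop("cannot normalize an empty feature vector")
  if (!all(is.finite(b))) stop("feature vector must be finite")
  lo <- min(b); hi <- max(b)
  if (hi == lo) return(rep(0, length(b)))
  (b - lo) / (hi - lo)
}

#' Decimal descriptor quantizer: 11 discrete levels
#'
#' Maps every feature to a code in `{0, ..., 10}` using thresholds anchored
#' at the vector's minimum (`bmin`), maximum (`bmax`) and mean (`mu`).
#'
#' The three equality rules are anchors and take precedence: `bmin` maps to
#' 0, `bmax` to 1 and `mu` to 6 (when the anchors are distinct), regardless
#' of which interval rule would otherwise capture them — the interval cut
#' points can stray across `mu`, and without anchor precedence the mean
#' itself would be swallowed by an interval rule whenever `bmin > mu / 3`.
#'
#' In `"literal"` mode the remaining rules are the published intervals,
#' evaluated top-to-bottom with first match winning: codes 2-5 on the
#' sub-intervals cut at `(mu+bmin)/4`, `(mu+bmin)/2`, `3(mu+bmin)/4` below
#' the mean, and codes 7-10 on the sub-intervals cut at `(mu+bmax)/4`,
#' `(mu+bmax)/2`, `3(mu+bmax)/4` above it. Because those printed upper cut
#' points can fall below `mu`, the literal rules are not an ordered
#' partition; any feature matching no rule receives the fallback code 10,
#' which makes the mapping total.
#'
#' In `"monotone"` mode the cut points are replaced by
#' `bmin + k (mu - bmin) / 4` below the mean and `mu + k (bmax - mu) / 4`
#' above it (`k = 1, 2, 3`), giving a proper ordered partition of
#' `[bmin, bmax]` with the same 0/1/6 anchors.
#'
#' Equality against `bmin`, `bmax` and `mu` is tested within the relative
#' tolerance `1e-12 * (bmax - bmin)`, since exact floating-point equality
#' is measure-zero.
#'
#' @param b nonempty finite numeric vector (or `raw_features`).
#' @param mode `"literal"` (default) or `"monotone"`.
#' @return Integer vector of codes in `0:10`, with attribute
#'   `quantizer_mode`.
#' @examples
#' quantize_codes(c(0, 0.25, 0.5, 0.75, 1))
#' @export
quantize_codes <- function(b, mode = c("literal", "monotone")) {
  mode <- match.arg(mode)
  if (inherits(b, "raw_features")) b <- b$b
  if (length(b) == 0L) stop("cannot quantize an empty feature vector")
  if (!all(is.finite(b))) stop("feature vector must be finite")
  bmin <- min(b); bmax <- max(b); mu <- mean(b)
  eps <- 1e-12 * (bmax - bmin)
  codes <- rep.int(NA_integer_, length(b))
  hit <- function(cond, code) {
    sel <- is.na(codes) & cond
    codes[sel] <<- code
  }
  # equality anchors first: bmin -> 0, bmax -> 1, mu -> 6
  hit(abs(b - bmin) <= eps, 0L)
  hit(abs(b - bmax) <= eps, 1L)
  hit(abs(b - mu) <= eps, 6L)
  if (mode == "literal") {
    lo <- mu + bmin
    hi <- mu + bmax
    hit(b > bmin & b <= lo / 4, 2L)
    hit(b > lo / 4 & b <= lo / 2, 3L)
    hit(b > lo / 2 & b <= 3 * lo / 4, 4L)
    hit(b > 3 * lo / 4 & b < mu, 5L)
    hit(b > mu & b <= hi / 4, 7L)
    hit(b > hi / 4 & b <= hi / 2, 8L)
    hit(b > hi / 2 & b <= 3 * hi / 4, 9L)
    hit(b > 3 * hi / 4 & b < bmax, 10L)
  } else {
    cl <- bmin + (1:3) * (mu - bmin) / 4
    ch <- mu + (1:3) * (bmax - mu) / 4
    hit(b > bmin & b <= cl[1], 2L)
    hit(b > cl[1] & b <= cl[2], 3L)
    hit(b > cl[2] & b <= cl[3], 4L)
    hit(b > cl[3] & b < mu, 5L)
    hit(b > mu & b <= ch[1], 7L)
    hit(b > ch[1] & b <= ch[2], 8L)
    hit(b > ch[2] & b <= ch[3], 9L)
    hit(b > ch[3] & b < bmax, 10L)
  }
  codes[is.na(codes)] <- 10L   # fallback: totality guard
  attr(codes, "quantizer_mode") <- mode
  codes
}

#' Normalized histogram features
#'
#' Counts values into `n_bins` equal-width bins spanning `value_range`
#' (right edge inclusive in the last bin; values are clamped to the range)
#' and normalizes by the total count, yielding a probability vector that
#' sums to 1. The default range `[0, 10]` matches the quantizer's code
#' alphabet: code `c` lands in bin `floor(c * n_bins / 10)` capped at
#' `n_bins - 1`.
#'
#' @param values nonempty numeric vector (codes or normalized features).
#' @param n_bins number of histogram bins, default 16.
#' @param value_range length-2 numeric, the binning domain.
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
histogram_features <- function(values, n_bins = 16L, value_range = c(0, 10)) {
  if (length(values) == 0L) stop("cannot histogram an empty input")
  n_bins <- as.integer(n_bins)
  lo <- value_range[1]; hi <- value_range[2]
  idx <- floor((as.numeric(values) - lo) / (hi - lo) * n_bins) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  tabulate(idx, nbins = n_bins) / length(values)
}

#' Extract the per-slice descriptor histogram
#'
#' Full descriptor pipeline for one slice. For `method = "gradient-ddp"`:
#' numerical gradient, per-block gradient statistics, whole-vector min-max
#' normalization, 11-level quantization and a 16-bin normalized histogram.
#' For `method = "ddp"` the block-gradient stage is replaced by the
#' classical per-pixel 3x3 neighbourhood (mean, max, min) statistics of
#' [ddp_neighborhood_stats()]; normalization, quantization and histogram
#' stages are shared. Deterministic.
#'
#' @param slice numeric intensity matrix.
#' @param method `"gradient-ddp"` (default) or `"ddp"`.
#' @param block_size block side for the gradient statistics, default 3.
#' @param quantizer quantizer mode, `"literal"` or `"monotone"`.
#' @param n_bins histogram length, default 16.
#' @param bin_on `"codes"` (histogram of quantized codes on `[0, 10]`,
#'   default) or `"normalized"` (histogram of the pre-quantization
#'   normalized vector on `[0, 1]`).
#' @param normalization `"vector"` (whole-vector min-max, default) or
#'   `"channel"` (each of the three interleaved statistic channels is
#'   min-max scaled separately).
#' @return Numeric feature vector of length `n_bins` summing to 1, with
#'   attributes `method` and `quantizer` recording provenance.
#' @examples
#' set.seed(1)
#' f <- extract_slice_features(matrix(rnorm(81), 9, 9))
#' sum(f)
#' @export
extract_slice_features <- function(slice,
                                   method = c("gradient-ddp", "ddp"),
                                   block_size = 3L,
                                   quantizer = c("literal", "monotone"),
                                   n_bins = 16L,
                                   bin_on = c("codes", "normalized"),
                                   normalization = c("vector", "channel")) {
  method <- match.arg(method)
  quantizer <- match.arg(quantizer)
  bin_on <- match.arg(bin_on)
  normalization <- match.arg(normalization)
  raw <- if (method == "gradient-ddp") {
    g <- compute_gradient(slice)
    block_statistics(g$gmag, g$gdir, block_size)
  } else {
    ddp_neighborhood_stats(slice)
  }
  nb <- if (normalization == "vector") {
    normalize_vector(raw$b)
  } else {
    # three interleaved statistic channels, each min-max scaled on its own,
    # then restored to grouped-by-block order
    m <- matrix(raw$b, nrow = 3L)
    as.vector(t(apply(m, 1L, normalize_vector)))
  }
  hist <- if (bin_on == "codes") {
    histogram_features(quantize_codes(nb, quantizer), n_bins, c(0, 10))
  } else {
    histogram_features(nb, n_bins, c(0, 1))
  }
  attr(hist, "method") <- method
  attr(hist, "quantizer") <- if (bin_on == "codes") quantizer else NA_character_
  hist
}
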