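#' Classical DDP neighbourhood statistics
#'
#' The intensity-based decimal descriptor's first stage: for every interior
#' pixel, the mean, maximum and minimum of its 3x3 neighbourhood. Border
#' pixels are excluded rather than padded, so no intensities are fabricated.
#' Pixels are visited in row-major order and the three statistics are
#' concatenated grouped by pixel: `(mean1, max1, min1, mean2, ...)`.
#'
#' @param slice numeric matrix, at least 3x3.
#' @return A `raw_features` object (see [block_statistics()]); `$b` has
#'   length `3 * (nrow - 2) * (ncol - 2)`.
#' @examples
#' ddp_neighborhood_stats(matrix(1:9, 3, 3, byrow = TRUE))$b  # 5, 9, 1
#' @export
ddp_neighborhood_stats <- function(slice) {
  if (!is.matrix(slice) || nrow(slice) < 3L || ncol(slice) < 3L) {
    stop("'slice' must be at least 3 x 3")
  }
  nr <- nrow(slice); nc <- ncol(slice)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  acc_sum <- NULL; acc_max <- NULL; acc_min <- NULL
  for (di in -1:1) {
    for (dj in -1:1) {
      v <- as.vector(t(slice[ri + di, ci + dj, drop = FALSE]))  # row-major
      if (is.null(acc_sum)) {
        acc_sum <- v; acc_max <- v; acc_min <- v
      } else {
        acc_sum <- acc_sum + v
        acc_max <- pmax(acc_max, v)
        acc_min <- pmin(acc_min, v)
      }
    }
  }
  b <- as.vector(rbind(acc_sum / 9, acc_max, acc_min))
  raw_features(b)
}

#' Encode a raw DDP vector into histogram features
#'
#' Shared back half of both descriptors: whole-vector min-max normalization
#' ([normalize_vector()]), 11-level quantization ([quantize_codes()]) and
#' the normalized histogram ([histogram_features()]). Provenance records
#' `method = "ddp"`.
#'
#' @param v nonempty numeric vector (or `raw_features`), typically from
#'   [ddp_neighborhood_stats()].
#' @param mode quantizer mode, `"literal"` or `"monotone"`.
#' @param n_bins histogram length, default 16.
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
ddp_encode <- function(v, mode = c("literal", "monotone"), n_bins = 16L) {
  mode <- match.arg(mode)
  if (inherits(v, "raw_features")) v <- v$b
  hist <- histogram_features(quantize_codes(normalize_vector(v), mode),
                             n_bins, c(0, 10))
  attr(hist, "method") <- "ddp"
  attr(hist, "quantizer") <- mode
  hist
}
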