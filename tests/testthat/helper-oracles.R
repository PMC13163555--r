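# Independent oracles used across the suite.

# Scalar rule-by-rule reference for the 11-level quantizer: a direct
# transcription of the published rule table (literal) and of the ordered
# cut-point reading (monotone), evaluated one feature at a time with
# explicit if/else chains. Kept independent of the package's vectorized
# implementation.
quantize_ref <- function(b, mode = "literal") {
  bmin <- min(b); bmax <- max(b); mu <- mean(b)
  eps <- 1e-12 * (bmax - bmin)
  one <- function(bi) {
    # equality anchors take precedence over the interval rules
    if (abs(bi - bmin) <= eps) return(0L)
    if (abs(bi - bmax) <= eps) return(1L)
    if (abs(bi - mu) <= eps) return(6L)
    if (mode == "literal") {
      lo <- mu + bmin; hi <- mu + bmax
      if (bi > bmin && bi <= lo / 4) return(2L)
      if (bi > lo / 4 && bi <= lo / 2) return(3L)
      if (bi > lo / 2 && bi <= 3 * lo / 4) return(4L)
      if (bi > 3 * lo / 4 && bi < mu) return(5L)
      if (bi > mu && bi <= hi / 4) return(7L)
      if (bi > hi / 4 && bi <= hi / 2) return(8L)
      if (bi > hi / 2 && bi <= 3 * hi / 4) return(9L)
      if (bi > 3 * hi / 4 && bi < bmax) return(10L)
      return(10L)  # no rule matched
    }
    c1 <- bmin + (mu - bmin) / 4
    c2 <- bmin + (mu - bmin) / 2
    c3 <- bmin + 3 * (mu - bmin) / 4
    d1 <- mu + (bmax - mu) / 4
    d2 <- mu + (bmax - mu) / 2
    d3 <- mu + 3 * (bmax - mu) / 4
    if (bi > bmin && bi <= c1) return(2L)
    if (bi > c1 && bi <= c2) return(3L)
    if (bi > c2 && bi <= c3) return(4L)
    if (bi > c3 && bi < mu) return(5L)
    if (bi > mu && bi <= d1) return(7L)
    if (bi > d1 && bi <= d2) return(8L)
    if (bi > d2 && bi <= d3) return(9L)
    if (bi > d3 && bi < bmax) return(10L)
    10L
  }
  vapply(b, one, integer(1))
}

# 8-connected component count via breadth-first flood fill.
count_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

random_slice <- function(nr = 9, nc = 9) {
  matrix(stats::rnorm(nr * nc, mean = 100, sd = 20), nr, nc)
}
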