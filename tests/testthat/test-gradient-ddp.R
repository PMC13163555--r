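test_that("gradient of constant and affine images is exact", {
  expect_true(all(compute_gradient(matrix(3.7, 6, 8))$gmag == 0))

  # I(x, y) = 2x + 3y: central and one-sided differences are exact
  img <- outer(1:5, 1:5, function(y, x) 2 * x + 3 * y)
  g <- compute_gradient(img)
  expect_equal(as.vector(g$gx), rep(2, 25))
  expect_equal(as.vector(g$gy), rep(3, 25))
  expect_equal(g$gmag, matrix(sqrt(13), 5, 5))

  expect_error(compute_gradient(matrix(1:4, 4, 1)), "2 rows")
  expect_error(compute_gradient(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})

test_that("gradient field ignores additive shifts and scales with intensity", {
  set.seed(42)
  s <- random_slice(7, 9)
  g0 <- compute_gradient(s)
  g1 <- compute_gradient(s + 7.3)
  expect_equal(g0$gx, g1$gx, tolerance = 1e-12)
  expect_equal(g0$gmag, g1$gmag, tolerance = 1e-12)
  # direction is invariant under positive intensity scaling
  g2 <- compute_gradient(2.7 * s)
  expect_equal(g0$gdir, g2$gdir, tolerance = 1e-12)
})

test_that("gradient magnitude and direction obey their closed forms", {
  expect_equal(gradient_magnitude(matrix(3), matrix(4)), matrix(5))
  expect_equal(gradient_magnitude(matrix(0), matrix(0)), matrix(0))
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
    expect_equal(gradient_magnitude(matrix(sx * 3), matrix(sy * 4)),
                 matrix(5))
  }
  expect_error(gradient_magnitude(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")

  expect_equal(gradient_direction(matrix(1), matrix(0))[1], 0)
  expect_equal(gradient_direction(matrix(0), matrix(1))[1], pi / 2)
  expect_equal(gradient_direction(matrix(-1), matrix(0))[1], pi)
  expect_equal(gradient_direction(matrix(0), matrix(0))[1], 0)  # atan2(0,0)
})

test_that("block statistics match direct arithmetic on a single block", {
  gmag <- matrix(0:8, 3, 3)
  theta <- 0.8
  rf <- block_statistics(gmag, matrix(theta, 3, 3))
  expect_equal(rf$b, c(4, 60 / 9, theta))
  expect_equal(rf$bmin, min(rf$b))
  expect_equal(rf$mu, mean(rf$b))

  # constant magnitude: zero variance component
  rf2 <- block_statistics(matrix(5, 3, 3), matrix(0.1, 3, 3))
  expect_equal(rf2$b[2], 0)

  expect_error(block_statistics(matrix(0, 2, 2), matrix(0, 2, 2)), "block")
})

test_that("blocks tile row-major and trailing partial blocks are dropped", {
  # 6x6 grid: 2x2 blocks; give each block a distinct constant magnitude
  bm <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  gmag <- bm[rep(1:2, each = 3), rep(1:2, each = 3)]
  rf <- block_statistics(gmag, gmag * 0)
  expect_equal(rf$b[seq(1, 12, by = 3)], c(1, 2, 3, 4))  # row-major means
  expect_equal(rf$blocks, c(2L, 2L))

  # 7x8 input keeps only the leading 6x6 region
  rf2 <- block_statistics(matrix(1, 7, 8), matrix(0, 7, 8))
  expect_equal(rf2$blocks, c(2L, 2L))
  expect_length(rf2$b, 12L)
})

test_that("circular mean handles angle wrap-around", {
  for (delta in c(0.1, 0.7, 1.2)) {
    rf <- block_statistics(matrix(1, 3, 3),
                           matrix(c(rep(pi / 2 - delta, 4),
                                    pi / 2,
                                    rep(pi / 2 + delta, 4)), 3, 3))
    expect_equal(rf$b[3], pi / 2, tolerance = 1e-12)
  }
  # arithmetic-mean pathology at +/- pi: circular mean stays at pi
  rf <- block_statistics(matrix(1, 3, 3),
                         matrix(rep(c(pi - 0.05, -pi + 0.05), length.out = 9),
                                3, 3))
  expect_equal(abs(rf$b[3]), pi, tolerance = 0.1)
})

test_that("min-max normalization rescales, degenerates and is idempotent", {
  expect_equal(normalize_vector(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalize_vector(rep(4.2, 7)), rep(0, 7))
  expect_error(normalize_vector(numeric(0)), "empty")
  set.seed(8)
  for (i in 1:100) {
    b <- stats::rnorm(sample(3:40, 1), sd = sample(c(0.01, 1, 100), 1))
    n1 <- normalize_vector(b)
    expect_true(all(n1 >= 0 & n1 <= 1))
    expect_equal(normalize_vector(n1), n1, tolerance = 1e-15)
  }
})

test_that("quantizer anchors and oracle equivalence hold in both modes", {
  set.seed(123)
  bad_oracle <- 0L; bad_anchor <- 0L; bad_range <- 0L
  for (i in 1:2000) {
    b <- stats::runif(sample(4:12, 1))
    b2 <- c(b, mean(b))  # appending the mean leaves bmin/bmax/mu unchanged
    for (mode in c("literal", "monotone")) {
      codes <- quantize_codes(b2, mode)
      if (!identical(as.integer(codes), quantize_ref(b2, mode))) {
        bad_oracle <- bad_oracle + 1L
      }
      if (!all(codes %in% 0:10)) bad_range <- bad_range + 1L
      if (codes[[which.min(b2)]] != 0L || codes[[which.max(b2)]] != 1L ||
          codes[[length(b2)]] != 6L) {
        bad_anchor <- bad_anchor + 1L
      }
    }
  }
  expect_identical(bad_oracle, 0L)
  expect_identical(bad_range, 0L)
  expect_identical(bad_anchor, 0L)
})

test_that("monotone mode is order-preserving strictly inside each half", {
  set.seed(9)
  for (i in 1:200) {
    b <- sort(stats::runif(30))
    codes <- quantize_codes(b, "monotone")
    mu <- mean(b)
    lower <- codes[b > min(b) & b < mu & codes %in% 2:5]
    upper <- codes[b > mu & b < max(b) & codes %in% 7:10]
    expect_true(all(diff(lower) >= 0))
    expect_true(all(diff(upper) >= 0))
  }
})

test_that("histogram features bin codes correctly and conserve mass", {
  h <- histogram_features(rep(0L, 12))
  expect_equal(h[1], 1)
  expect_equal(sum(h), 1)

  h2 <- histogram_features(0:10)
  expect_equal(sum(h2 > 0), 11L)
  occupied <- pmin(floor((0:10) * 16 / 10), 15) + 1L
  expect_equal(which(h2 > 0), occupied)
  expect_true(all(h2[occupied] == 1 / 11))

  set.seed(2)
  h3 <- histogram_features(sample(0:10, 500, replace = TRUE))
  expect_equal(sum(h3), 1)
  expect_true(all(h3 >= 0))
  expect_error(histogram_features(integer(0)), "empty")
})

test_that("full descriptor is shift-invariant, normalized and deterministic", {
  set.seed(77)
  for (i in 1:20) {
    s <- random_slice(12, 12)
    f0 <- extract_slice_features(s)
    expect_length(f0, 16L)
    expect_equal(sum(f0), 1, tolerance = 1e-9)
    shift <- stats::runif(1, -50, 50)
    expect_equal(as.numeric(extract_slice_features(s + shift)),
                 as.numeric(f0), tolerance = 1e-9)
  }
  s <- random_slice(10, 10)
  expect_identical(extract_slice_features(s), extract_slice_features(s))
})

test_that("descriptor configuration flags are honoured", {
  set.seed(13)
  s <- random_slice(12, 12)
  f_norm <- extract_slice_features(s, bin_on = "normalized")
  expect_equal(sum(f_norm), 1, tolerance = 1e-9)
  f_chan <- extract_slice_features(s, normalization = "channel")
  expect_equal(sum(f_chan), 1, tolerance = 1e-9)
  f_mono <- extract_slice_features(s, quantizer = "monotone")
  expect_identical(attr(f_mono, "quantizer"), "monotone")
  f_ddp <- extract_slice_features(s, method = "ddp")
  expect_identical(attr(f_ddp, "method"), "ddp")
  expect_false(isTRUE(all.equal(as.numeric(f_ddp),
                                as.numeric(extract_slice_features(s)))))
})
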