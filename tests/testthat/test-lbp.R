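test_that("uniform mapping obeys the bin-count law and classifies known patterns", {
  m8 <- uniform_mapping(8)
  expect_equal(attr(m8, "n_bins"), 59)
  # 58 uniform codes in distinct bins, all others pooled
  expect_equal(sum(tabulate(m8, 59)[1:58]), 58)
  expect_equal(sum(m8 == 59), 256 - 58)
  # constant pattern 00000000 is uniform; alternating 01010101 is not
  expect_lt(m8[0 + 1], 59)
  expect_equal(m8[85 + 1], 59)
  expect_equal(m8[255 + 1], 58) # all-ones is the last uniform code
  # bin count P(P-1)+3 verified by enumeration for a range of P
  for (P in c(2, 4, 6, 8, 10)) {
    expect_equal(attr(uniform_mapping(P), "n_bins"), P * (P - 1) + 3)
  }
  expect_error(uniform_mapping(0), "1..16")
  expect_error(uniform_mapping(17), "1..16")
})

test_that("code computation follows the documented bit rule and tie rule", {
  # constant image: every neighbour ties the centre; >= rule gives all bits 1
  expect_equal(unique(as.vector(compute_lbp_codes(matrix(100, 5, 5)))), 255L)
  expect_equal(unique(as.vector(compute_lbp_codes(
    matrix(100, 5, 5), lbp_config(tie_rule = "gt_is_one")))), 0L)
  # hand-evaluated 3x3: centre 6, (E,NE,N,NW,W,SW,S,SE) = (7,6,2,1,9,8,9,3)
  img <- matrix(0, 3, 3)
  img[2, 2] <- 6
  img[2, 3] <- 7; img[1, 3] <- 6; img[1, 2] <- 2; img[1, 1] <- 1
  img[2, 1] <- 9; img[3, 1] <- 8; img[3, 2] <- 9; img[3, 3] <- 3
  expect_equal(compute_lbp_codes(img)[1, 1], 115L)
  # monotonic shift leaves all comparisons unchanged
  im <- random_image(20, 20, seed = 1)
  expect_identical(compute_lbp_codes(im), compute_lbp_codes(im + 10))
  expect_error(compute_lbp_codes(matrix(0, 2, 5)), "too small")
})

test_that("vectorized codes match the naive double-loop oracle", {
  for (seed in 1:5) {
    im <- random_image(16, 16, seed = seed)
    im[sample(256, 30)] <- im[sample(256, 30)] # inject duplicate values -> ties
    expect_identical(compute_lbp_codes(im, lbp_config(tie_rule = "geq_is_one")),
                     lbp_oracle_codes(im, tie_geq = TRUE))
    expect_identical(compute_lbp_codes(im, lbp_config(tie_rule = "gt_is_one")),
                     lbp_oracle_codes(im, tie_geq = FALSE))
  }
})

test_that("circular interpolated sampling agrees with 8-connected at the compass points", {
  im <- random_image(12, 12, seed = 3)
  c8 <- compute_lbp_codes(im, lbp_config())
  ci <- compute_lbp_codes(im, lbp_config(sampling = "circular_interpolated"))
  # bits 0, 2, 4, 6 (E, N, W, S) sample integer grid points in both schemes
  mask <- as.integer(2^0 + 2^2 + 2^4 + 2^6)
  expect_identical(bitwAnd(c8, mask), bitwAnd(ci, mask))
})

test_that("default descriptor has 2891 entries and conserves histogram mass", {
  im <- random_image(224, 224, seed = 0)
  v <- lbp_feature_vector(im)
  expect_length(v, 59 * 49)
  expect_equal(sum(v), 222 * 222) # every coded pixel lands in exactly one bin
  # non-square geometry: mass is still the coded-pixel count
  im2 <- random_image(100, 150, seed = 2)
  v2 <- lbp_feature_vector(im2)
  expect_length(v2, 2891)
  expect_equal(sum(v2), 98 * 148)
  # per-cell fractions: each of the 49 cells sums to 1
  vf <- lbp_feature_vector(im, lbp_config(normalize = "per_cell_fraction"))
  cells <- matrix(vf, nrow = 59)
  expect_equal(colSums(cells), rep(1, 49))
})

test_that("descriptor is invariant under strictly increasing intensity remaps", {
  im <- random_image(64, 64, seed = 4)
  lut <- cumsum(sample(1:3, 256, replace = TRUE)) # strictly increasing 0..255 map
  im2 <- matrix(lut[im + 1], nrow(im), ncol(im))
  expect_equal(lbp_feature_vector(im), lbp_feature_vector(im2))
})

test_that("images smaller than the cell grid are rejected with the required size", {
  expect_error(lbp_feature_vector(random_image(8, 8, seed = 1)), "at least 9x9")
})

test_that("LBP feature extraction stacks records into a tagged matrix", {
  recs <- list(list(image = random_image(30, 30, 1), label = "a", sample_id = "a/1.png"),
               list(image = random_image(30, 30, 2), label = "b", sample_id = "b/1.png"))
  fm <- extract_lbp_features(recs)
  expect_equal(dim(fm$values), c(2, 2891))
  expect_match(fm$feature_names[1], "^lbp:")
  expect_equal(fm$labels, c("a", "b"))
})
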