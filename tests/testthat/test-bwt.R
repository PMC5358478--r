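test_that("the nine basis patches are orthonormal and zero-mean", {
  b <- bwt_basis()
  gram <- b$matrix %*% t(b$matrix)
  expect_lt(max(abs(gram - diag(9))), 1e-12)
  for (w in b$wavelets) {
    expect_lt(abs(sum(w)), 1e-14)                 # zero mean
    expect_equal(sum(w^2), 1, tolerance = 1e-14)  # unit L2 norm
    expect_lt(abs(sum(w * b$dc)), 1e-14)          # orthogonal to DC
  }
  expect_equal(b$dc, matrix(1 / 3, 3, 3), tolerance = 1e-15)
  expect_equal(sum(b$dc^2), 1, tolerance = 1e-14)
})

test_that("basis golden values are locked", {
  b <- bwt_basis()
  expect_equal(b$wavelets$h_odd,
               outer(c(-1, 0, 1) / sqrt(2), rep(1, 3) / sqrt(3)))
  expect_equal(b$wavelets$v_even,
               outer(rep(1, 3) / sqrt(3), c(1, -2, 1) / sqrt(6)))
  expect_equal(b$wavelets$d45_even,
               outer(c(-1, 0, 1), c(-1, 0, 1)) / 2)
  expect_equal(unname(b$matrix[1, ]), rep(1 / 3, 9))
})

test_that("forward transform of canonical inputs", {
  # constant image: all wavelet coefficients vanish
  co <- bwt_forward(gray_image(matrix(77, 27, 27)), levels = 2)
  expect_lt(max(abs(unlist(co$levels))), 1e-10)
  expect_equal(unique(round(as.vector(co$dc_plane), 8)), 77 * 9)

  # a 3x3 image equal to one wavelet: single unit coefficient
  b <- bwt_basis()
  co1 <- bwt_forward(b$wavelets$d135_odd, levels = 1)
  expect_equal(co1$levels[[1]]$d135_odd[1, 1], 1, tolerance = 1e-12)
  others <- unlist(co1$levels[[1]][setdiff(names(co1$levels[[1]]),
                                           "d135_odd")])
  expect_lt(max(abs(others)), 1e-12)
  expect_lt(abs(co1$dc_plane[1, 1]), 1e-12)
})

test_that("the transform is critically sampled and energy preserving", {
  for (seed in 1:5) {
    img <- rand_img(27, 27, seed)
    co <- bwt_forward(img, levels = 3)
    n_coef <- length(unlist(co$levels)) + length(co$dc_plane)
    expect_equal(n_coef, 27 * 27)
    e_img <- sum(as.numeric(unclass(img))^2)
    e_coef <- sum(unlist(co$levels)^2) + sum(co$dc_plane^2)
    expect_equal(e_coef, e_img, tolerance = 1e-8)
  }
})

test_that("forward/inverse is a perfect round trip, including padding", {
  for (shape in list(c(27, 27), c(31, 40), c(81, 81))) {
    img <- rand_img(shape[1], shape[2], seed = sum(shape))
    co <- bwt_forward(img, levels = 2)
    rec <- bwt_inverse(co, quantize = FALSE)
    expect_equal(dim(rec), shape)
    expect_lt(max(abs(rec - unclass(img))), 1e-8)
    expect_identical(unclass(bwt_inverse(co)), unclass(img))
  }
})

test_that("the transform is linear on float rasters", {
  set.seed(42)
  x <- matrix(rnorm(27 * 27), 27, 27)
  y <- matrix(rnorm(27 * 27), 27, 27)
  ca <- bwt_forward(2.5 * x - 1.25 * y, levels = 2)
  cx <- bwt_forward(x, levels = 2)
  cy <- bwt_forward(y, levels = 2)
  expect_equal(unlist(ca$levels),
               2.5 * unlist(cx$levels) - 1.25 * unlist(cy$levels),
               tolerance = 1e-10)
  expect_equal(ca$dc_plane, 2.5 * cx$dc_plane - 1.25 * cy$dc_plane,
               tolerance = 1e-10)
})

test_that("3x3 blocks agree with the explicit projection oracle", {
  b <- bwt_basis()
  for (seed in 1:10) {
    set.seed(seed)
    block <- matrix(sample(0:255, 9), 3, 3)
    co <- bwt_forward(block, levels = 1)
    got <- c(dc = co$dc_plane[1, 1],
             vapply(co$levels[[1]], function(p) p[1, 1], numeric(1)))
    expect_equal(got, ora_bwt3(block, b), tolerance = 1e-10)
  }
})

test_that("zeroing every wavelet plane leaves the blockwise mean", {
  img <- rand_img(27, 27, seed = 8)
  for (k in 1:2) {
    co <- bwt_forward(img, levels = k)
    co$levels <- lapply(co$levels, function(bands) lapply(bands, function(p) p * 0))
    rec <- bwt_inverse(co, quantize = FALSE)
    expect_equal(rec, ora_block_mean(img, 3^k), tolerance = 1e-9)
  }
})

test_that("denoising contracts: identity at keep_fraction 1, constants fixed", {
  img <- rand_img(27, 27, seed = 2)
  expect_identical(unclass(bwt_denoise(img, 2, keep_fraction = 1)),
                   unclass(img))
  cimg <- gray_image(matrix(101, 27, 27))
  expect_true(all(bwt_denoise(cimg, 2, keep_fraction = 0.3) == 101))
})

test_that("shrinkage denoising reduces MSE against the clean phantom", {
  clean <- make_phantom(phantom_spec(noise_sigma = 0))$image
  for (seed in 1:3) {
    noisy <- make_phantom(phantom_spec(noise_sigma = 12, seed = seed))$image
    den <- bwt_denoise(noisy, levels = 2)
    expect_lt(mse(den, clean), mse(noisy, clean))
  }
})

test_that("too many levels for the raster is a parameter error", {
  expect_error(bwt_forward(rand_img(27, 27, 1), levels = 4), "too deep")
  expect_error(bwt_forward(rand_img(27, 27, 1), levels = 0), ">= 1")
})
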