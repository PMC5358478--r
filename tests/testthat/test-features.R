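test_that("first-order statistics on canonical inputs", {
  cimg <- gray_image(matrix(42, 8, 8))
  fo <- first_order(cimg)
  expect_equal(unname(fo[c("mean", "sd", "entropy", "skewness",
                           "kurtosis", "energy")]),
               c(42, 0, 0, 0, 0, 1))
  expect_true(attr(fo, "degenerate"))

  coin <- gray_image(matrix(c(0, 255), 8, 8))   # half 0, half 255
  fo2 <- first_order(coin)
  expect_equal(unname(fo2["entropy"]), 1)       # one fair bit
  expect_equal(unname(fo2["energy"]), 0.5)
})

test_that("first-order statistics match the loop oracle on random rasters", {
  for (seed in 1:25) {
    img <- rand_img(8, 8, seed)
    region <- if (seed %% 2) rand_mask(8, 8, seed + 100, p = 0.7) else NULL
    if (!is.null(region) && !any(region)) next
    vals <- if (is.null(region)) as.vector(unclass(img)) else
      unclass(img)[unclass(region)]
    expect_equal(first_order(img, region), ora_first_order(vals),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(first_order(rand_img(5, 5, 1),
                           binary_mask(matrix(FALSE, 5, 5))), "empty")
})

test_that("GLCM of canonical patterns", {
  g <- glcm(gray_image(matrix(200, 5, 5)), offset = c(0, 1), levels = 4)
  expect_equal(sum(diag(unclass(g))), 1)        # single diagonal entry

  # alternating 0/255 columns: all horizontal pairs are cross-level
  cb <- gray_image(matrix(c(0, 255), 3, 4, byrow = TRUE))
  g2 <- glcm(cb, offset = c(0, 1), levels = 2)
  expect_equal(unclass(g2)[1, 1] + unclass(g2)[2, 2], 0)
  expect_equal(sum(unclass(g2)), 1)
})

test_that("GLCM counts match a brute-force double loop", {
  offsets <- list(c(0, 1), c(-1, 1), c(1, 0), c(2, -1))
  for (seed in 1:12) {
    img <- rand_img(9, 7, seed)
    region <- if (seed %% 3 == 0) rand_mask(9, 7, seed + 7, p = 0.8) else NULL
    off <- offsets[[1 + seed %% 4]]
    for (symmetric in c(TRUE, FALSE)) {
      got <- glcm(img, region, offset = off, levels = 8,
                  symmetric = symmetric)
      want <- ora_glcm(img, if (is.null(region)) NULL else unclass(region),
                       off, 8, symmetric)
      expect_equal(unclass(got), want, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
  expect_error(glcm(rand_img(5, 5, 1), offset = c(0, 0)), "offset")
})

test_that("GLCM-derived features match the loop oracle", {
  # canonical: identity-diagonal GLCM
  gid <- diag(4) / 4
  f <- glcm_features(gid)
  expect_equal(unname(f[c("contrast", "homogeneity", "directional_moment")]),
               c(0, 1, 0))
  # uniform 2x2: ASM = 4 * (1/4)^2
  expect_equal(unname(glcm_features(matrix(0.25, 2, 2))["asm"]), 0.25)

  for (seed in 1:20) {
    set.seed(seed)
    g <- matrix(runif(16), 4, 4)
    g <- g / sum(g)
    expect_equal(glcm_features(g), ora_glcm_features(g),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("feature values respect their analytic ranges", {
  for (seed in 1:10) {
    img <- rand_img(12, 12, seed)
    g <- glcm(img, levels = 8)
    f <- glcm_features(g)
    expect_gt(f[["homogeneity"]], 0); expect_lte(f[["homogeneity"]], 1)
    expect_gt(f[["asm"]], 0);         expect_lte(f[["asm"]], 1)
    expect_gte(f[["correlation"]], -1); expect_lte(f[["correlation"]], 1)
    expect_gte(f[["contrast"]], 0)
    # symmetric GLCM: equal marginals
    expect_equal(rowSums(unclass(g)), colSums(unclass(g)), tolerance = 1e-12)
  }
})

test_that("features are invariant to pixels outside the region", {
  img <- rand_img(10, 10, 3)
  region <- rand_mask(10, 10, 4, p = 0.6)
  px2 <- unclass(img)
  px2[!region] <- 17L   # rewrite the background
  img2 <- gray_image(px2)
  expect_equal(first_order(img, region), first_order(img2, region))
  expect_equal(unclass(glcm(img, region)), unclass(glcm(img2, region)))
  expect_equal(extract_features(img, region), extract_features(img2, region))
})

test_that("coarseness is the scaled pixel sum", {
  expect_equal(coarseness(gray_image(matrix(0, 4, 4))), 0)
  expect_equal(coarseness(gray_image(matrix(1, 3, 3))), 9 / 2^6)
  img <- rand_img(5, 6, 9)
  expect_equal(coarseness(img), sum(unclass(img)) / 2^11)
})

test_that("the combined vector has 12 named features with expected contrasts", {
  ph <- make_phantom(phantom_spec(
    tumor = list(center = c(30, 48), radii = c(9, 7), intensity = 200),
    noise_sigma = 8, seed = 21))
  fv <- extract_features(ph$image, ph$brain_mask)
  expect_named(fv, c("mean", "sd", "entropy", "skewness", "kurtosis",
                     "energy", "contrast", "homogeneity", "asm",
                     "correlation", "directional_moment", "coarseness"))
  # tumor region is brighter and (with noise) less uniform than pure WM
  f_wm <- extract_features(ph$image, ph$wm_mask)
  f_tm <- extract_features(ph$image, ph$tumor_mask)
  expect_gt(f_tm[["mean"]], f_wm[["mean"]])

  cst <- extract_features(gray_image(matrix(9, 9, 9)))
  expect_equal(unname(cst[c("sd", "entropy", "energy", "contrast",
                            "homogeneity", "asm")]),
               c(0, 0, 1, 0, 1, 1))
})
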