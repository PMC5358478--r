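#' First-order statistical features
#'
#' Mean and standard deviation are population moments over the region's
#' pixels (`1/N` weighting); skewness and kurtosis are the third and
#' fourth standardized moments with the same weighting. Entropy and
#' (first-order) energy are computed on the normalized 256-bin intensity
#' histogram `p`: `E = -sum(p * log2(p))` with `0 * log 0 := 0`, and
#' `En = sum(p^2)`. A constant region has `SD = 0`; its skewness and
#' kurtosis are reported as 0 and flagged with a `degenerate` attribute.
#'
#' @param img a [gray_image()].
#' @param region optional [binary_mask()] restricting the computation;
#'   default is the whole image. Must be nonempty.
#' @return a named numeric vector `(mean, sd, entropy, skewness,
#'   kurtosis, energy)`.
#' @examples
#' img <- gray_image(matrix(c(0, 255), 4, 4))
#' first_order(img)[c("entropy", "energy")]  # 1 bit, 0.5
#' @export
first_order <- function(img, region = NULL) {
  vals <- region_values(img, region)
  n <- length(vals)
  m <- sum(vals) / n
  v <- sum((vals - m)^2) / n
  sdev <- sqrt(v)
  degenerate <- sdev == 0
  sk <- if (degenerate) 0 else sum((vals - m)^3) / n / sdev^3
  ku <- if (degenerate) 0 else sum((vals - m)^4) / n / sdev^4
  p <- tabulate(vals + 1L, nbins = 256L) / n
  p <- p[p > 0]
  out <- c(mean = m, sd = sdev,
           entropy = -sum(p * log2(p)),
           skewness = sk, kurtosis = ku,
           energy = sum(p^2))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

region_values <- function(img, region) {
  px <- as_matrix(img)
  if (is.null(region)) return(as.vector(px))
  check_same_shape(img, region, "image and region")
  if (!any(region)) stop("region is empty", call. = FALSE)
  px[as_matrix(region)]
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized gray levels at a fixed pixel offset.
#' Intensities are quantized into `levels` equal-width bins over
#' \[0, 255\]; a pair is counted only when both pixels lie inside
#' `region`. With `symmetric = TRUE` (the Haralick convention) each pair
#' is also counted with its endpoints swapped. The matrix is normalized
#' to probabilities.
#'
#' @inheritParams first_order
#' @param offset integer `(d_row, d_col)` displacement of the second
#'   pixel; must not be `(0, 0)`.
#' @param levels number of gray levels `L >= 2` after quantization.
#' @param symmetric count each pair in both directions.
#' @return an object of class `glcm`: the `L x L` probability matrix
#'   with attributes `offset`, `levels` and `symmetric`. Row/column `i`
#'   corresponds to quantized level `i - 1`.
#' @examples
#' img <- gray_image(matrix(c(0, 255), 2, 4))  # checkerboard columns
#' g <- glcm(img, offset = c(1, 0), levels = 2)
#' g[1, 2] + g[2, 1]  # all mass off-diagonal
#' @export
glcm <- function(img, region = NULL, offset = c(0, 1), levels = 8,
                 symmetric = TRUE) {
  stopifnot(length(offset) == 2L, levels >= 2L)
  offset <- as.integer(offset)
  if (all(offset == 0L)) stop("offset must not be (0, 0)", call. = FALSE)
  px <- as_matrix(img)
  q <- pmin(px %/% as.integer(ceiling(256 / levels)), levels - 1L)
  inr <- if (is.null(region)) matrix(TRUE, nrow(px), ncol(px)) else {
    check_same_shape(img, region, "image and region")
    as_matrix(region)
  }
  nr <- nrow(px); nc <- ncol(px)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  r1 <- r1[r1 + offset[1] >= 1L & r1 + offset[1] <= nr]
  c1 <- c1[c1 + offset[2] >= 1L & c1 + offset[2] <= nc]
  if (length(r1) == 0L || length(c1) == 0L) {
    stop("offset span exceeds the image/region extent", call. = FALSE)
  }
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + offset[1], c1 + offset[2], drop = FALSE]
  ok <- inr[r1, c1, drop = FALSE] &
    inr[r1 + offset[1], c1 + offset[2], drop = FALSE]
  if (!any(ok)) stop("region too small for this offset", call. = FALSE)
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a[ok], levels = 0:(levels - 1L)),
               factor(b[ok], levels = 0:(levels - 1L)))
  counts <- counts + unclass(tab)
  if (symmetric) counts <- counts + t(counts)
  g <- counts / sum(counts)
  dimnames(g) <- NULL
  structure(g, offset = offset, levels = as.integer(levels),
            symmetric = symmetric, class = c("glcm", "matrix", "array"))
}

#' Haralick features of a normalized GLCM
#'
#' With `p(x, y)` the co-occurrence probability of quantized levels `x`
#' and `y` (0-based):
#' contrast `sum((x - y)^2 p)`; homogeneity (inverse difference moment)
#' `sum(p / (1 + (x - y)^2))`; angular second moment `sum(p^2)`;
#' correlation `(sum(x y p) - mx my) / (sx sy)` with marginal means and
#' standard deviations `mx, my, sx, sy`; directional moment
#' `sum(p * |x - y|)`. A GLCM with a degenerate marginal (all mass at
#' one level) has undefined correlation, reported as 0 with a
#' `degenerate` attribute.
#'
#' @param g a [glcm()] (or any normalized nonnegative square matrix).
#' @return a named numeric vector `(contrast, homogeneity, asm,
#'   correlation, directional_moment)`.
#' @export
glcm_features <- function(g) {
  g <- unclass(g)
  stopifnot(is.matrix(g), nrow(g) == ncol(g), all(g >= 0))
  if (abs(sum(g) - 1) > 1e-8) stop("GLCM must be normalized", call. = FALSE)
  L <- nrow(g)
  x <- matrix(0:(L - 1L), L, L)
  y <- t(x)
  d <- x - y
  px_ <- rowSums(g); py_ <- colSums(g)
  mx <- sum((0:(L - 1L)) * px_); my <- sum((0:(L - 1L)) * py_)
  sx <- sqrt(sum(((0:(L - 1L)) - mx)^2 * px_))
  sy <- sqrt(sum(((0:(L - 1L)) - my)^2 * py_))
  degenerate <- sx * sy == 0
  corr <- if (degenerate) 0 else (sum(x * y * g) - mx * my) / (sx * sy)
  out <- c(contrast = sum(d^2 * g),
           homogeneity = sum(g / (1 + d^2)),
           asm = sum(g^2),
           correlation = corr,
           directional_moment = sum(g * abs(d)))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Coarseness
#'
#' A global roughness index: the sum of the region's pixel intensities
#' scaled by `2^-(m + n)`, where `m x n` is the image shape. Note the
#' scale factor shrinks extremely fast with image size, so the index is
#' only discriminative for small rasters / patches; it is included for
#' completeness of the texture vector.
#'
#' @inheritParams first_order
#' @return a single number.
#' @examples
#' coarseness(gray_image(matrix(1, 3, 3)))  # 9 / 2^6
#' @export
coarseness <- function(img, region = NULL) {
  px <- as_matrix(img)
  s <- if (is.null(region)) sum(px) else {
    check_same_shape(img, region, "image and region")
    sum(px[as_matrix(region)])
  }
  s / 2^(nrow(px) + ncol(px))
}

#' The full 12-feature texture vector
#'
#' Concatenates the six first-order statistics, the five GLCM features
#' averaged over the four standard distance-1 offsets (0, 45, 90 and
#' 135 degrees) and coarseness — the input representation of the
#' normal/abnormal classifier.
#'
#' @inheritParams first_order
#' @param levels GLCM quantization levels (default 8).
#' @param symmetric symmetric GLCM accumulation (default `TRUE`).
#' @return a named numeric vector of length 12: `mean, sd, entropy,
#'   skewness, kurtosis, energy, contrast, homogeneity, asm,
#'   correlation, directional_moment, coarseness`.
#' @examples
#' ph <- make_phantom(phantom_spec())
#' extract_features(ph$image, ph$brain_mask)
#' @export
extract_features <- function(img, region = NULL, levels = 8,
                             symmetric = TRUE) {
  fo <- first_order(img, region)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  gf <- rowMeans(vapply(offsets, function(off) {
    glcm_features(glcm(img, region, offset = off, levels = levels,
                       symmetric = symmetric))
  }, numeric(5)))
  c(fo[c("mean", "sd", "entropy", "skewness", "kurtosis", "energy")],
    gf, coarseness = coarseness(img, region))
}
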