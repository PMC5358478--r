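#' Mean squared error between two images
#'
#' @param a,b [gray_image()]s (or numeric matrices) of identical shape.
#' @return the mean squared per-pixel difference, in squared intensity
#'   units.
#' @examples
#' x <- gray_image(matrix(10, 4, 4)); y <- gray_image(matrix(11, 4, 4))
#' mse(x, y)  # 1
#' @export
mse <- function(a, b) {
  check_same_shape(a, b, "images")
  mean((as.numeric(as_matrix(a)) - as.numeric(as_matrix(b)))^2)
}

#' Peak signal-to-noise ratio
#'
#' Two conventions are provided. `mode = "standard"` (default) is the
#' usual `10 * log10((2^bit_depth - 1)^2 / MSE)`. `mode = "literal"`
#' evaluates `20 * log10((2^bit_depth - 1) / MSE)` — i.e. with the MSE
#' itself, not its square root, in the denominator — a form that
#' appears in parts of the tumor-segmentation literature; the two
#' differ by exactly `10 * log10(MSE)` dB. Identical images have
#' infinite PSNR, returned as `Inf`.
#'
#' @inheritParams mse
#' @param bit_depth bits per pixel (default 8).
#' @param mode `"standard"` or `"literal"` (see Details).
#' @return PSNR in dB.
#' @examples
#' a <- gray_image(matrix(c(0, 2), 4, 4))
#' b <- gray_image(matrix(c(1, 1), 4, 4))   # MSE 1
#' psnr(a, b)                   # 48.13 dB either way at MSE = 1
#' @export
psnr <- function(a, b, bit_depth = 8, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  err <- mse(a, b)
  if (err == 0) return(Inf)
  peak <- 2^bit_depth - 1
  switch(mode,
         standard = 10 * log10(peak^2 / err),
         literal  = 20 * log10(peak / err))
}

#' Structural similarity index
#'
#' Mean SSIM in the Wang et al. form: for each sliding `window`-sided
#' square fully inside the images, the product of luminance, contrast
#' and structure comparisons
#' `(2 mx my + c1)(2 sxy + c2) / ((mx^2 + my^2 + c1)(sx^2 + sy^2 + c2))`
#' is computed from the window means, variances and covariance, and the
#' window scores are averaged. Defaults follow the common convention
#' `c1 = (0.01 * 255)^2`, `c2 = (0.03 * 255)^2`, uniform 8 x 8 windows.
#'
#' @inheritParams mse
#' @param c1,c2 stabilizing constants (> 0).
#' @param window side of the square window; must not exceed either
#'   image dimension.
#' @return the mean SSIM, in \[-1, 1\].
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0))
#' ssim(ph$image, ph$image)  # 1
#' @export
ssim <- function(a, b, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                 window = 8) {
  check_same_shape(a, b, "images")
  stopifnot(c1 > 0, c2 > 0)
  x <- as_matrix(a) * 1.0
  y <- as_matrix(b) * 1.0
  if (window > min(dim(x))) {
    stop("window (", window, ") larger than the image", call. = FALSE)
  }
  n <- window^2
  sx  <- box_sums(x, window);     sy  <- box_sums(y, window)
  sxx <- box_sums(x * x, window); syy <- box_sums(y * y, window)
  sxy <- box_sums(x * y, window)
  mx <- sx / n; my <- sy / n
  vx <- sxx / n - mx^2
  vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
       ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

# sums over every w x w window fully inside the matrix (integral image)
box_sums <- function(x, w) {
  ii <- rbind(0, apply(x, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  nr <- nrow(x); nc <- ncol(x)
  r <- seq_len(nr - w + 1L); cc <- seq_len(nc - w + 1L)
  ii[r + w, cc + w, drop = FALSE] - ii[r, cc + w, drop = FALSE] -
    ii[r + w, cc, drop = FALSE] + ii[r, cc, drop = FALSE]
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A and B| / (|A| + |B|)`: 1 for identical nonempty masks, 0 for
#' disjoint ones. Undefined (an error) when both masks are empty.
#'
#' @param a,b [binary_mask()]s of identical shape.
#' @return the Dice coefficient in \[0, 1\].
#' @examples
#' a <- binary_mask(matrix(c(TRUE, FALSE), 4, 4))
#' dice(a, a)
#' @export
dice <- function(a, b) {
  check_same_shape(a, b, "masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    stop("Dice undefined: both masks are empty", call. = FALSE)
  }
  2 * sum(as_matrix(a) & as_matrix(b)) / (na + nb)
}

#' Confusion matrix of a binary (normal/abnormal) classifier
#'
#' Positives are abnormal (tumor) slices. `tp` counts abnormal slices
#' called abnormal, `tn` normal called normal, `fp` normal called
#' abnormal, `fn` abnormal called normal.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix cells must be non-negative counts", call. = FALSE)
  }
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(counts, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FN %d  |  FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' reported as percentages. Following the print convention of the
#' clinical tables this module mirrors, percentages are truncated (not
#' rounded) at the second decimal place; `digits = NULL` returns full
#' precision. A metric whose denominator is zero is returned as `NA`.
#'
#' @param cm a [confusion_matrix()].
#' @param digits decimal places to truncate to (default 2), or `NULL`
#'   for no truncation.
#' @return named numeric vector `(accuracy, sensitivity, specificity)`
#'   in percent.
#' @examples
#' classification_metrics(confusion_matrix(tp = 129, tn = 65, fp = 4, fn = 3))
#' @export
classification_metrics <- function(cm, digits = 2) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- c(accuracy    = ratio(cm$tp + cm$tn, total),
           sensitivity = ratio(cm$tp, cm$tp + cm$fn),
           specificity = ratio(cm$tn, cm$tn + cm$fp))
  if (!is.null(digits)) out <- trunc(out * 10^digits) / 10^digits
  out
}

#' Combined image-quality report
#'
#' Convenience wrapper collecting MSE, PSNR, SSIM (between a processed
#' image and its reference) and the Dice coefficient (between the
#' predicted and reference masks) into one list, ready for JSON
#' serialization.
#'
#' @param image,reference [gray_image()]s of identical shape.
#' @param mask,reference_mask optional [binary_mask()]s; when supplied,
#'   `dice` is included.
#' @param ... passed to [psnr()] (e.g. `mode`).
#' @return a list with `mse`, `psnr_db`, `ssim` and (optionally) `dice`.
#' @export
quality_report <- function(image, reference, mask = NULL,
                           reference_mask = NULL, ...) {
  out <- list(mse = mse(image, reference),
              psnr_db = psnr(image, reference, ...),
              ssim = ssim(image, reference))
  if (!is.null(mask) && !is.null(reference_mask)) {
    out$dice <- dice(mask, reference_mask)
  }
  out
}
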