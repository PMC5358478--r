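#' Sigmoid contrast enhancement
#'
#' Remaps intensities through a logistic curve, steepening contrast
#' around `cutoff`: with `u = intensity / 255`, each pixel becomes
#' `1 / (1 + exp(gain * (cutoff - u)))`, and the result is min--max
#' rescaled back to \[0, 255\] so the pipeline's fixed threshold of 128
#' keeps its meaning. The mapping is monotone nondecreasing in the input
#' intensity; in the large-`gain` limit it approaches a hard threshold
#' at `255 * cutoff`. A constant input has no range to stretch and is
#' mapped to mid-gray 128 by convention. The
#' transform is not idempotent: applying it twice steepens the curve
#' further.
#'
#' @param img a [gray_image()].
#' @param gain slope of the sigmoid (> 0); larger values give harder
#'   contrast. Default 10.
#' @param cutoff center of the sigmoid on the normalized \[0, 1\]
#'   intensity scale. Default 0.5.
#' @return a [gray_image()].
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0))
#' enh <- enhance_contrast(ph$image)
#' range(enh)
#' @export
enhance_contrast <- function(img, gain = 10, cutoff = 0.5) {
  if (!is.numeric(gain) || gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  if (cutoff < 0 || cutoff > 1) stop("`cutoff` must be in [0, 1]", call. = FALSE)
  u <- as_matrix(img) / 255
  t <- 1 / (1 + exp(gain * (cutoff - u)))
  rng <- range(t)
  out <- if (rng[1] == rng[2]) {
    matrix(128, nrow(img), ncol(img))
  } else {
    (t - rng[1]) / (rng[2] - rng[1]) * 255
  }
  as_gray_like(out, like = img)
}
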