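#' Grayscale image raster
#'
#' The unit of processing throughout the pipeline: a 2D matrix of integer
#' intensities in \[0, 255\], row-major, with rows indexing the vertical
#' image axis. An optional `pixel_spacing` attribute `(row_mm, col_mm)`
#' carries the physical size of a pixel in millimetres when it is known
#' (e.g. from a DICOM or NIfTI header); it is used only to convert tumor
#' areas from pixels to square centimetres.
#'
#' @param pixels numeric matrix; values are rounded and must fall in
#'   \[0, 255\] after rounding.
#' @param pixel_spacing optional numeric length-2 vector `(row_mm, col_mm)`.
#' @return an object of class `gray_image` (an integer matrix).
#' @examples
#' img <- gray_image(matrix(0:24 * 10, 5, 5))
#' dim(img)
#' @export
gray_image <- function(pixels, pixel_spacing = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3x3", call. = FALSE)
  }
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("intensities must be finite and in [0, 255]", call. = FALSE)
  }
  storage.mode(px) <- "integer"
  if (!is.null(pixel_spacing)) {
    stopifnot(is.numeric(pixel_spacing), length(pixel_spacing) == 2L,
              all(pixel_spacing > 0))
    attr(px, "pixel_spacing") <- as.numeric(pixel_spacing)
  }
  class(px) <- c("gray_image", class(px))
  px
}

#' @export
print.gray_image <- function(x, ...) {
  sp <- attr(x, "pixel_spacing")
  cat(sprintf("<gray_image> %d x %d, intensity range [%d, %d]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(sp)) "" else
                sprintf(", spacing %.3g x %.3g mm", sp[1], sp[2])))
  invisible(x)
}

#' Binary mask aligned to a grayscale image
#'
#' @param pixels logical (or 0/1 numeric) matrix, same shape as the image
#'   it annotates.
#' @return an object of class `binary_mask` (a logical matrix).
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE), 4, 4))
#' sum(m)
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 1))) {
      stop("numeric mask values must be 0/1", call. = FALSE)
    }
    pixels <- pixels > 0
  }
  if (!is.logical(pixels)) stop("mask must be logical or 0/1", call. = FALSE)
  if (anyNA(pixels)) stop("mask must not contain NA", call. = FALSE)
  class(pixels) <- c("binary_mask", class(pixels))
  pixels
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

# Strip classes for arithmetic with plain matrices.
as_matrix <- function(x) {
  attr(x, "pixel_spacing") <- NULL
  class(x) <- setdiff(class(x), c("gray_image", "binary_mask"))
  x
}

pixel_spacing <- function(img) attr(img, "pixel_spacing")

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Clamp, round and re-wrap a numeric matrix as a gray_image, preserving
# pixel spacing from `like`.
as_gray_like <- function(pixels, like = NULL) {
  px <- pmin(pmax(round(pixels), 0), 255)
  gray_image(px, pixel_spacing = if (!is.null(like)) pixel_spacing(like))
}
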