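#' Extract the tumor mask from a skull-stripped slice
#'
#' Thresholds the brain region at `threshold` (default 128, the global
#' pipeline cut-off), erodes once with a square structuring element of
#' radius `se_radius` to remove thin bright structures, selects the
#' 8-connected component maximizing `pixel count x mean intensity`
#' (preferring large, bright lesions; ties broken by the component
#' whose first pixel comes earliest in raster order), and dilates back
#' by the same radius. The result is always a subset of `brain_mask`.
#'
#' @param img a skull-stripped [gray_image()].
#' @param brain_mask the brain [binary_mask()] from [strip_skull()].
#' @param threshold intensity cut-off in \[0, 255\].
#' @param se_radius structuring-element radius for the erosion/dilation
#'   pair.
#' @return a [binary_mask()] of the tumor; empty (with a warning) when
#'   no candidate survives — a normal slice.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0,
#'   tumor = list(center = c(30, 48), radii = c(9, 7), intensity = 200)))
#' st <- strip_skull(ph$image)
#' tm <- extract_tumor(st$image, st$mask)
#' dice(tm, ph$tumor_mask)
#' @export
extract_tumor <- function(img, brain_mask, threshold = 128, se_radius = 1) {
  check_same_shape(img, brain_mask, "image and brain mask")
  bright <- as_matrix(binarize(img, threshold)) & as_matrix(brain_mask)
  if (!any(bright)) {
    warning("no pixels above threshold ", threshold,
            " inside the brain mask; returning an empty tumor mask")
    return(binary_mask(bright))
  }
  core <- erode(binary_mask(bright), se_radius)
  lab <- label_components(core)
  k <- max(lab)
  if (k == 0L) {
    warning("no tumor candidate survives erosion; returning an empty mask")
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img))))
  }
  px <- as_matrix(img)
  score <- vapply(seq_len(k), function(id) {
    sel <- lab == id
    sum(sel) * mean(px[sel])
  }, numeric(1))
  # which.max returns the first maximum; labels are numbered in raster
  # order of their first pixel, so ties resolve deterministically
  best <- binary_mask(lab == which.max(score))
  out <- as_matrix(dilate(best, se_radius)) & as_matrix(brain_mask)
  binary_mask(out)
}

#' Segment brain tissue into CSF, gray matter and white matter
#'
#' Within the brain mask (tumor excluded), pixel intensities are
#' clustered with k-means (k = 3) initialized deterministically at the
#' 10th / 50th / 90th intensity percentiles; clusters are ordered by
#' center so the darkest is CSF, the middle gray matter and the
#' brightest white matter. The tumor mask, obtained first via
#' [extract_tumor()], is disjoint from all three tissue masks. Tumor
#' area book-keeping (pixel count, optional cm^2, ratio of tumor pixels
#' to total raster pixels) is included in the result.
#'
#' @inheritParams extract_tumor
#' @param pixel_spacing optional `(row_mm, col_mm)`; defaults to the
#'   image's `pixel_spacing` attribute when present.
#' @return an object of class `segmentation_result`: a list with
#'   `tumor_mask`, `wm_mask`, `gm_mask`, `csf_mask`, `tumor_area_px`,
#'   `tumor_area_cm2` (`NULL` without spacing) and `area_ratio`.
#' @export
segment_tissues <- function(img, brain_mask, threshold = 128, se_radius = 1,
                            pixel_spacing = NULL) {
  check_same_shape(img, brain_mask, "image and brain mask")
  if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  tumor <- withCallingHandlers(
    extract_tumor(img, brain_mask, threshold, se_radius),
    warning = function(w) invokeRestart("muffleWarning"))
  tissue_sel <- as_matrix(brain_mask) & !as_matrix(tumor)
  px <- as_matrix(img)
  vals <- px[tissue_sel]
  masks <- list(csf = tissue_sel & FALSE, gm = tissue_sel & FALSE,
                wm = tissue_sel & FALSE)
  if (length(vals) > 0L) {
    centers <- unique(stats::quantile(vals, c(0.1, 0.5, 0.9), names = FALSE))
    if (length(centers) < 3L) {
      # nearly uniform brain: assign by nearest of the distinct levels
      cl <- findInterval(vals, c(-Inf, centers[-1] - diff(centers) / 2))
      cl <- pmin(cl + 3L - length(centers), 3L)
      ord_centers <- seq_len(3L)
    } else {
      km <- stats::kmeans(vals, centers = matrix(centers, ncol = 1))
      ord <- order(km$centers[, 1])
      cl <- match(km$cluster, ord)
    }
    for (j in 1:3) {
      m <- tissue_sel
      m[tissue_sel] <- cl == j
      masks[[j]] <- m
    }
  }
  spacing <- if (!is.null(pixel_spacing)) pixel_spacing else
    attr(img, "pixel_spacing")
  area <- tumor_area(tumor, spacing)
  structure(list(tumor_mask = tumor,
                 wm_mask  = binary_mask(masks$wm),
                 gm_mask  = binary_mask(masks$gm),
                 csf_mask = binary_mask(masks$csf),
                 tumor_area_px = area$area_px,
                 tumor_area_cm2 = area$area_cm2,
                 area_ratio = area$area_px / length(px)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result> tumor %d px (ratio %.4f)%s; ",
                     "wm/gm/csf %d/%d/%d px\n"),
              x$tumor_area_px, x$area_ratio,
              if (is.null(x$tumor_area_cm2)) "" else
                sprintf(", %.2f cm2", x$tumor_area_cm2),
              sum(x$wm_mask), sum(x$gm_mask), sum(x$csf_mask)))
  invisible(x)
}

#' Tumor area in pixels and square centimetres
#'
#' @param mask the tumor [binary_mask()].
#' @param pixel_spacing optional `(row_mm, col_mm)` in millimetres.
#' @return a list with `area_px` (foreground pixel count) and
#'   `area_cm2` (`area_px * row_mm * col_mm / 100`, or `NULL` when the
#'   spacing is unknown).
#' @examples
#' m <- binary_mask(matrix(rep(c(TRUE, FALSE), 50), 10, 10))
#' tumor_area(m, pixel_spacing = c(1, 1))
#' @export
tumor_area <- function(mask, pixel_spacing = NULL) {
  npx <- sum(mask)
  cm2 <- if (!is.null(pixel_spacing)) {
    stopifnot(length(pixel_spacing) == 2L, all(pixel_spacing > 0))
    npx * pixel_spacing[1] * pixel_spacing[2] / 100
  }
  list(area_px = npx, area_cm2 = cm2)
}
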