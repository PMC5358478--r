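#' Specification of a synthetic brain-slice phantom
#'
#' Describes a 2D head phantom with exact ground truth: an elliptical
#' head bounded by a bright skull annulus, an interior partitioned into
#' three concentric intensity zones mimicking cortical gray matter
#' (outer ring), white matter (middle) and ventricular CSF (core), an
#' optional hyperintense elliptical tumor, and additive Gaussian noise
#' clipped to \[0, 255\]. Geometry is deliberately schematic rather than
#' anatomical so that every ground-truth mask is exact by construction.
#'
#' Default tissue intensities (CSF 30 < GM 80 < WM 120 < skull 220) keep
#' all normal brain tissue below the pipeline's global threshold of 128
#' while the skull and the default tumor (200) sit above it, emulating
#' the contrast relations the segmentation stages rely on in
#' T2/FLAIR-like slices.
#'
#' @param shape `(rows, cols)` of the raster; at least 27 x 27 so three
#'   triadic wavelet scales fit.
#' @param skull_thickness thickness of the skull annulus in pixels.
#' @param tissue_levels named intensities `c(csf, gm, wm, skull)`,
#'   strictly increasing in that order.
#' @param tumor `NULL` for a normal slice, or a list with `center`
#'   `(row, col)`, `radii` `(r_row, r_col)` in pixels and `intensity`.
#' @param noise_sigma standard deviation of the additive Gaussian noise,
#'   in intensity units.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return an object of class `phantom_spec`.
#' @examples
#' sp <- phantom_spec(shape = c(81, 81), tumor = list(center = c(30, 45),
#'                    radii = c(8, 6), intensity = 200))
#' ph <- make_phantom(sp)
#' sum(ph$tumor_mask)
#' @export
phantom_spec <- function(shape = c(81, 81),
                         skull_thickness = 4,
                         tissue_levels = c(csf = 30, gm = 80, wm = 120,
                                           skull = 220),
                         tumor = NULL,
                         noise_sigma = 5,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 27L),
            skull_thickness >= 1,
            length(tissue_levels) == 4L, noise_sigma >= 0)
  tl <- tissue_levels[c("csf", "gm", "wm", "skull")]
  if (anyNA(tl)) stop("tissue_levels needs names csf, gm, wm, skull",
                      call. = FALSE)
  if (any(diff(tl) <= 0)) {
    stop("tissue intensities must be strictly ordered csf < gm < wm < skull",
         call. = FALSE)
  }
  if (any(tl < 0) || any(tl > 255)) {
    stop("tissue intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.null(tumor)) {
    stopifnot(is.list(tumor),
              all(c("center", "radii", "intensity") %in% names(tumor)),
              length(tumor$center) == 2L, length(tumor$radii) == 2L,
              all(tumor$radii >= 1),
              tumor$intensity >= 0, tumor$intensity <= 255)
  }
  structure(list(shape = as.integer(shape),
                 skull_thickness = skull_thickness,
                 tissue_levels = tl,
                 tumor = tumor,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared normalized elliptical radius of every pixel for an ellipse
# centered at `cen` with semi-axes `rad` (row, col).
ellipse_r2 <- function(shape, cen, rad) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - cen[1]) / rad[1])^2 + ((c_ - cen[2]) / rad[2])^2
}

#' Render a phantom with its ground truth
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: a list with the noisy
#'   `image` ([gray_image()]), the exact `brain_mask`, `skull_mask`,
#'   `tumor_mask`, `wm_mask`, `gm_mask`, `csf_mask`
#'   ([binary_mask()]s) and the slice `label` (`"normal"` or
#'   `"abnormal"`). The tissue masks are pairwise disjoint subsets of
#'   `brain_mask`; `label` is `"abnormal"` iff the tumor mask is
#'   nonempty.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  cen <- (shape + 1) / 2
  outer_rad <- 0.46 * shape          # head ellipse semi-axes
  inner_rad <- outer_rad - spec$skull_thickness
  if (any(inner_rad < 6)) stop("skull too thick for this raster", call. = FALSE)

  head  <- ellipse_r2(shape, cen, outer_rad) <= 1
  brain <- ellipse_r2(shape, cen, inner_rad) <= 1
  skull <- head & !brain
  # concentric tissue zones: GM cortex ring, WM interior, CSF ventricle core
  rb <- ellipse_r2(shape, cen, inner_rad)
  gm  <- brain & rb > 0.75^2
  csf <- brain & rb <= 0.35^2
  wm  <- brain & !gm & !csf

  tl <- spec$tissue_levels
  img <- matrix(0, shape[1], shape[2])
  img[skull] <- tl[["skull"]]
  img[gm]  <- tl[["gm"]]
  img[wm]  <- tl[["wm"]]
  img[csf] <- tl[["csf"]]

  tumor <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(spec$tumor)) {
    tm <- spec$tumor
    tumor <- ellipse_r2(shape, tm$center, tm$radii) <= 1
    if (!all(brain[tumor])) {
      stop("tumor must lie entirely inside the brain region", call. = FALSE)
    }
    img[tumor] <- tm$intensity
  }

  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed,
                     img + stats::rnorm(length(img), 0, spec$noise_sigma))
  }
  structure(list(
    image      = as_gray_like(img),
    brain_mask = binary_mask(brain),
    skull_mask = binary_mask(skull),
    tumor_mask = binary_mask(tumor),
    wm_mask    = binary_mask(wm & !tumor),
    gm_mask    = binary_mask(gm & !tumor),
    csf_mask   = binary_mask(csf & !tumor),
    label      = if (any(tumor)) "abnormal" else "normal",
    spec       = spec
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s slice %d x %d, tumor %d px\n",
              x$label, nrow(x$image), ncol(x$image), sum(x$tumor_mask)))
  invisible(x)
}

#' Generate a labeled cohort of phantoms
#'
#' Draws `n_normal + n_abnormal` phantoms from `base_spec` with
#' per-slice jitter of the tissue intensities and, for abnormal slices,
#' of the tumor's position, radii and intensity, all from one seeded
#' generator so the cohort is reproducible. Tumors are placed in the
#' white-matter band at a random angle; radii vary by +/-30% around 1/8
#' of the head size and tumor intensity by +/-15 around 200.
#'
#' @param n_normal,n_abnormal number of slices of each class.
#' @param base_spec a [phantom_spec()] giving the common geometry.
#' @param seed integer seed for the cohort.
#' @return a list of `phantom_truth` objects, the `n_normal` normal
#'   slices first.
#' @export
make_dataset <- function(n_normal, n_abnormal, base_spec = phantom_spec(),
                         seed = 1L) {
  stopifnot(n_normal >= 0, n_abnormal >= 0)
  n <- n_normal + n_abnormal
  if (n == 0L) return(list())
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  shape <- base_spec$shape
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      tl <- base_spec$tissue_levels +
        round(stats::rnorm(4, 0, 4) * c(1, 1, 1, 1))
      tl <- pmin(pmax(tl, 5), 250)
      # keep the strict ordering after jitter
      tl <- sort(tl) + c(0, cumsum(pmax(0, 1 - diff(sort(tl)))))
      names(tl) <- c("csf", "gm", "wm", "skull")
      tumor <- NULL
      if (labels[i] == "abnormal") {
        cen0 <- (shape + 1) / 2
        ang <- stats::runif(1, 0, 2 * pi)
        # middle of the WM band at ~55% of the inner radius
        inner <- 0.46 * shape - base_spec$skull_thickness
        off <- 0.55 * stats::runif(1, 0.8, 1.1)
        center <- round(cen0 + off * inner * c(sin(ang), cos(ang)) * 0.9)
        radii <- pmax(3, round(shape / 8 * stats::runif(2, 0.7, 1.3)))
        tumor <- list(center = center, radii = radii,
                      intensity = min(250, max(150, round(
                        200 + stats::rnorm(1, 0, 8)))))
      }
      sp <- phantom_spec(shape = shape,
                         skull_thickness = base_spec$skull_thickness,
                         tissue_levels = tl,
                         tumor = tumor,
                         noise_sigma = base_spec$noise_sigma,
                         seed = sample.int(.Machine$integer.max, 1))
      out[[i]] <- make_phantom(sp)
    }
    out
  })
}
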