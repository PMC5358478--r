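#' The triadic Berkeley wavelet basis
#'
#' An orthonormal basis of the 3 x 3 patch space: eight zero-mean
#' piecewise-constant mother wavelets — four orientations (horizontal,
#' vertical and the two diagonals), each in an even (symmetric) and an
#' odd (antisymmetric) phase — plus one constant patch of value 1/3 per
#' cell that carries the local mean. All nine patches have unit L2 norm
#' and are mutually orthogonal, so the blockwise transform is critically
#' sampled and energy preserving.
#'
#' The patches are built from the 1D triadic vectors
#' `c = (1,1,1)/sqrt(3)`, `o = (-1,0,1)/sqrt(2)` (odd) and
#' `e = (1,-2,1)/sqrt(6)` (even): axis-aligned wavelets are outer
#' products with the constant vector, the diagonal pairs are the
#' symmetric and antisymmetric combinations of the mixed products and
#' the pure `o`/`e` products. Orthonormality is inherited from the 1D
#' vectors; the fixed construction order makes the basis reproducible
#' and it is locked by a golden-value test.
#'
#' @return an object of class `bwt_basis`: a list with `wavelets` (a
#'   named list of eight 3 x 3 matrices: `h_even`, `h_odd`, `v_even`,
#'   `v_odd`, `d45_even`, `d45_odd`, `d135_even`, `d135_odd`), `dc` (the
#'   constant patch) and `matrix` (the 9 x 9 change-of-basis matrix
#'   whose rows are the flattened patches, DC first).
#' @examples
#' b <- bwt_basis()
#' round(b$matrix %*% t(b$matrix), 12)  # identity
#' @export
bwt_basis <- function() {
  cvec <- rep(1, 3) / sqrt(3)
  ovec <- c(-1, 0, 1) / sqrt(2)
  evec <- c(1, -2, 1) / sqrt(6)
  wav <- list(
    h_even   = outer(evec, cvec),                       # varies along rows
    h_odd    = outer(ovec, cvec),
    v_even   = outer(cvec, evec),                       # varies along cols
    v_odd    = outer(cvec, ovec),
    d45_even = outer(ovec, ovec),
    d45_odd  = (outer(ovec, evec) + outer(evec, ovec)) / sqrt(2),
    d135_even = outer(evec, evec),
    d135_odd  = (outer(ovec, evec) - outer(evec, ovec)) / sqrt(2)
  )
  dc <- outer(cvec, cvec)                               # 1/3 per cell
  W <- rbind(as.vector(dc),
             do.call(rbind, lapply(wav, as.vector)))
  rownames(W) <- c("dc", names(wav))
  structure(list(wavelets = wav, dc = dc, matrix = W), class = "bwt_basis")
}

subband_names <- c("h_even", "h_odd", "v_even", "v_odd",
                   "d45_even", "d45_odd", "d135_even", "d135_odd")

# reflect-pad on the bottom/right so both sides divide 3^k
pad_reflect <- function(x, target) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(seq_len(nr), rev(seq_len(nr)))[seq_len(target[1])]
  ci <- c(seq_len(nc), rev(seq_len(nc)))[seq_len(target[2])]
  x[ri, ci, drop = FALSE]
}

#' Forward / inverse Berkeley wavelet transform
#'
#' `bwt_forward` decomposes a 2D raster over `levels` triadic scales.
#' At each scale the image is tiled into non-overlapping 3 x 3 blocks;
#' each block is projected onto the eight wavelet patches (giving eight
#' subband planes of one third the size) and onto the constant patch
#' (giving the scaling plane, which is decomposed recursively). The
#' transform is orthonormal: the total number of coefficients equals the
#' number of (padded) pixels and their energy equals the image energy.
#' Images whose sides are not multiples of `3^levels` are reflect-padded
#' on the bottom/right; the original shape is recorded and the padding
#' removed on inversion.
#'
#' `bwt_inverse` reconstructs the raster exactly (to floating-point
#' round-off) from a coefficient pyramid.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param levels number of triadic scales `K >= 1`; `3^K` may not exceed
#'   the smaller image side.
#' @return `bwt_forward`: an object of class `bwt_coefficients` — a list
#'   with `levels` (per scale, a named list of the eight subband
#'   planes), `dc_plane` (coarsest scaling coefficients),
#'   `original_shape`, `padded_shape` and `n_levels`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(81, 81), noise_sigma = 0))
#' co <- bwt_forward(ph$image, levels = 2)
#' rec <- bwt_inverse(co)
#' identical(as.vector(rec), as.vector(ph$image))
#' @export
bwt_forward <- function(img, levels = 2) {
  x <- as_matrix(img)
  storage.mode(x) <- "double"
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  if (3^levels > min(dim(x))) {
    stop("levels = ", levels, " too deep for a ",
         paste(dim(x), collapse = " x "), " image", call. = FALSE)
  }
  orig <- dim(x)
  unit <- 3^levels
  padded <- as.integer(ceiling(orig / unit) * unit)
  if (!identical(padded, orig)) x <- pad_reflect(x, padded)
  W <- bwt_basis()$matrix
  lev <- vector("list", levels)
  for (s in seq_len(levels)) {
    step <- bwt_step_forward(x, W)
    lev[[s]] <- step$bands
    x <- step$dc
  }
  structure(list(levels = lev, dc_plane = x,
                 original_shape = orig, padded_shape = padded,
                 n_levels = levels),
            class = "bwt_coefficients")
}

# one analysis step: 3a x 3b raster -> dc plane + 8 subband planes (a x b)
bwt_step_forward <- function(x, W) {
  a <- nrow(x) %/% 3L; b <- ncol(x) %/% 3L
  blocks <- matrix(0, 9, a * b)
  for (j in 1:3) for (i in 1:3) {
    blocks[(j - 1L) * 3L + i, ] <-
      x[seq(i, by = 3L, length.out = a), seq(j, by = 3L, length.out = b)]
  }
  P <- W %*% blocks
  bands <- lapply(seq_len(8), function(k) matrix(P[k + 1L, ], a, b))
  names(bands) <- subband_names
  list(dc = matrix(P[1L, ], a, b), bands = bands)
}

bwt_step_inverse <- function(dc, bands, W) {
  a <- nrow(dc); b <- ncol(dc)
  P <- rbind(as.vector(dc),
             do.call(rbind, lapply(bands[subband_names], as.vector)))
  blocks <- crossprod(W, P)          # t(W) %*% P, W orthogonal
  x <- matrix(0, 3L * a, 3L * b)
  for (j in 1:3) for (i in 1:3) {
    x[seq(i, by = 3L, length.out = a), seq(j, by = 3L, length.out = b)] <-
      matrix(blocks[(j - 1L) * 3L + i, ], a, b)
  }
  x
}

#' @param coeffs a `bwt_coefficients` pyramid.
#' @param quantize if `TRUE` (default) round/clip the reconstruction to
#'   an 8-bit [gray_image()]; if `FALSE` return the raw numeric matrix.
#' @rdname bwt_forward
#' @export
bwt_inverse <- function(coeffs, quantize = TRUE) {
  stopifnot(inherits(coeffs, "bwt_coefficients"))
  W <- bwt_basis()$matrix
  x <- coeffs$dc_plane
  for (s in rev(seq_len(coeffs$n_levels))) {
    bands <- coeffs$levels[[s]]
    if (!all(subband_names %in% names(bands))) {
      stop("malformed coefficient pyramid at scale ", s, call. = FALSE)
    }
    if (!all(vapply(bands, function(p) identical(dim(p), dim(x)), logical(1)))) {
      stop("subband plane shapes inconsistent at scale ", s, call. = FALSE)
    }
    x <- bwt_step_inverse(x, bands, W)
  }
  x <- x[seq_len(coeffs$original_shape[1]),
         seq_len(coeffs$original_shape[2]), drop = FALSE]
  if (quantize) as_gray_like(x) else x
}

#' Wavelet-shrinkage denoising
#'
#' Forward BWT, retention of the largest-magnitude `keep_fraction` of
#' wavelet coefficients (the scaling/DC plane is always kept), inverse
#' transform, and clipping to \[0, 255\]. With `keep_fraction = 1` this
#' is the identity up to rounding; small fractions keep the
#' piecewise-smooth structure of a brain slice while discarding noise
#' energy spread thinly across the subbands. The default retains the
#' top 20% of coefficients: on a head-sized slice roughly that share of
#' the triadic subband coefficients carries tissue-boundary structure,
#' and cutting deeper starts erasing real edges faster than noise.
#'
#' @inheritParams bwt_forward
#' @param keep_fraction fraction of wavelet coefficients to keep, in
#'   (0, 1\].
#' @return a denoised [gray_image()].
#' @export
bwt_denoise <- function(img, levels = 2, keep_fraction = 0.2) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must be in (0, 1]", call. = FALSE)
  }
  co <- bwt_forward(img, levels)
  if (keep_fraction < 1) {
    mags <- abs(unlist(co$levels, use.names = FALSE))
    cutoff <- stats::quantile(mags, 1 - keep_fraction, names = FALSE, type = 1)
    co$levels <- lapply(co$levels, function(bands) {
      lapply(bands, function(p) { p[abs(p) < cutoff] <- 0; p })
    })
  }
  bwt_inverse(co, quantize = TRUE)
}
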