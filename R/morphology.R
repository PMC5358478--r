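#' Threshold an image into a binary mask
#'
#' Foreground is strictly *greater than* the threshold: a pixel exactly
#' at the cut-off (e.g. 128 at the default pipeline threshold of 128)
#' is background.
#'
#' @param img a [gray_image()].
#' @param threshold intensity cut-off in \[0, 255\].
#' @return a [binary_mask()].
#' @examples
#' img <- gray_image(matrix(c(0, 128, 129, 255), 4, 4))
#' sum(binarize(img, 128)) # only the 129s and 255s
#' @export
binarize <- function(img, threshold = 128) {
  stopifnot(threshold >= 0, threshold <= 255)
  binary_mask(as_matrix(img) > threshold)
}

#' Binary erosion / dilation with a square structuring element
#'
#' Standard flat morphology with a `(2 * se_radius + 1)`-sided square
#' structuring element, so `erode(m) \\subseteq m \\subseteq dilate(m)`.
#' Pixels outside the raster count as background.
#'
#' @param mask a [binary_mask()].
#' @param se_radius half-width of the square structuring element, >= 1.
#' @return a [binary_mask()] of the same shape.
#' @export
erode <- function(mask, se_radius = 1) {
  morpho_op(mask, se_radius, EBImage::erode)
}

#' @rdname erode
#' @export
dilate <- function(mask, se_radius = 1) {
  morpho_op(mask, se_radius, EBImage::dilate)
}

morpho_op <- function(mask, se_radius, op) {
  stopifnot(se_radius >= 1)
  m <- as_matrix(mask) * 1L
  # pad with background so out-of-raster pixels count as background
  # (EBImage replicates the border instead)
  r <- as.integer(se_radius)
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0L, nr + 2L * r, nc + 2L * r)
  padded[r + seq_len(nr), r + seq_len(nc)] <- m
  kern <- matrix(1L, 2 * r + 1, 2 * r + 1)
  out <- op(padded, kern)[r + seq_len(nr), r + seq_len(nc)]
  binary_mask(out > 0)
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected to the raster border become
#' foreground.
#'
#' @inheritParams erode
#' @return a [binary_mask()].
#' @export
fill_holes <- function(mask) {
  binary_mask(EBImage::fillHull(as_matrix(mask) * 1L) > 0)
}

#' Label 8-connected components
#'
#' @inheritParams erode
#' @return an integer matrix of component labels (0 = background),
#'   numbered in raster order of each component's first pixel (column
#'   after column, matching R's column-major order).
#' @export
label_components <- function(mask) {
  m <- as_matrix(mask) * 1L
  lab <- EBImage::bwlabel(m)          # 4-connected
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  k <- max(lab)
  if (k > 1L) {
    # merge labels that touch diagonally (union-find over label ids)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    union_ <- function(a, b) { ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
    nr <- nrow(lab); nc <- ncol(lab)
    for (shift in list(c(1L, 1L), c(1L, -1L))) {
      dr <- shift[1]; dc <- shift[2]
      rows <- seq_len(nr - 1L)
      cols <- if (dc == 1L) seq_len(nc - 1L) else 2L:nc
      a <- lab[rows, cols, drop = FALSE]
      b <- lab[rows + dr, cols + dc, drop = FALSE]
      sel <- a > 0L & b > 0L & a != b
      if (any(sel)) {
        pairs <- unique(cbind(a[sel], b[sel]))
        for (p in seq_len(nrow(pairs))) union_(pairs[p, 1], pairs[p, 2])
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    # renumber by first-pixel raster order for determinism
    first <- match(seq_len(max(lab)), lab[lab > 0L])
    ord <- order(first)
    remap <- integer(max(lab)); remap[ord] <- seq_along(ord)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# Largest 8-connected component; ties broken by the component whose
# first pixel comes earliest in (col, row) raster order, i.e. the lowest
# label id. Returns a logical matrix (all FALSE when the mask is empty).
largest_component <- function(mask, min_px = 1L) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(binary_mask(lab > 0L))
  sizes <- tabulate(lab[lab > 0L])
  sizes[sizes < min_px] <- 0L
  if (all(sizes == 0L)) return(binary_mask(matrix(FALSE, nrow(lab), ncol(lab))))
  binary_mask(lab == which.max(sizes))
}
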