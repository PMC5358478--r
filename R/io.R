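#' Read a 2D grayscale slice from PNG, TIFF, DICOM or NIfTI
#'
#' Normalizes any supported input to the pipeline's internal raster: a
#' single-channel 8-bit [gray_image()]. Color inputs are converted to
#' grayscale with the classic luminance weighting (0.299 R + 0.587 G +
#' 0.114 B) and every slice is min--max rescaled to the full \[0, 255\]
#' range, so that the pipeline's fixed intensity threshold of 128 has the
#' same meaning regardless of the source bit depth (8-bit PNG, 16-bit
#' DICOM, float NIfTI). A constant slice, whose range cannot be
#' stretched, is kept as-is when already in \[0, 255\] and mapped to
#' mid-gray 128 otherwise. Pixel spacing is populated from DICOM
#' (`PixelSpacing`) and NIfTI (`pixdim`) headers when present.
#'
#' @param path path to the image file.
#' @param format one of `"auto"`, `"png"`, `"tiff"`, `"dicom"`, `"nifti"`.
#'   `"auto"` sniffs the file's magic bytes.
#' @param slice 1-based slice index along the third axis, required when a
#'   NIfTI file holds a 3D volume.
#' @return a [gray_image()].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(seq(0, 1, length.out = 64), 8, 8), f)
#' img <- read_image(f)
#' range(img)
#' @export
read_image <- function(path, format = c("auto", "png", "tiff", "dicom", "nifti"),
                       slice = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
    png   = read_raster(png::readPNG(path)),
    tiff  = read_raster(tiff::readTIFF(path)),
    dicom = read_dicom_slice(path),
    nifti = read_nifti_slice(path, slice),
    stop("unrecognized image format for ", path, call. = FALSE))
}

sniff_format <- function(path) {
  head <- readBin(path, "raw", n = 348L)
  if (length(head) >= 132L &&
      identical(head[129:132], charToRaw("DICM"))) return("dicom")
  if (length(head) >= 8L &&
      identical(head[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                    0x0d, 0x0a, 0x1a, 0x0a)))) return("png")
  if (length(head) >= 4L &&
      (identical(head[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(head[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))) return("tiff")
  if (length(head) >= 348L &&
      (identical(head[345:347], charToRaw("n+1")) ||
       identical(head[345:347], charToRaw("ni1")))) return("nifti")
  # gzipped NIfTI
  if (length(head) >= 2L && identical(head[1:2], as.raw(c(0x1f, 0x8b)))) {
    return("nifti")
  }
  stop("cannot determine image format of ", path, call. = FALSE)
}

# png/tiff arrays arrive in [0, 1]; restore the 8-bit scale before the
# common min-max normalization so constant images keep a natural level.
read_raster <- function(arr) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  rescale_to_uint8(arr * 255)
}

read_nifti_slice <- function(path, slice) {
  vol <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(vol)
  dm <- dim(vol)
  if (length(dm) == 2L) {
    dat <- vol[, ]
  } else if (length(dm) == 3L) {
    if (dm[3] == 1L) slice <- 1L
    if (is.null(slice)) {
      stop("3D NIfTI volume: supply `slice` to pick one 2D slice",
           call. = FALSE)
    }
    if (slice < 1L || slice > dm[3]) {
      stop("slice index out of range 1..", dm[3], call. = FALSE)
    }
    dat <- vol[, , slice]
  } else {
    stop("only 2D images or 3D volumes are supported", call. = FALSE)
  }
  spacing <- if (length(pd) >= 2L && all(pd[1:2] > 0)) pd[1:2]
  rescale_to_uint8(dat, pixel_spacing = spacing)
}

# Min-max rescale to the full 8-bit range (constant input -> itself if
# already a legal intensity, else mid-gray).
rescale_to_uint8 <- function(x, pixel_spacing = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite pixel values", call. = FALSE)
  rng <- range(x)
  px <- if (rng[1] == rng[2]) {
    matrix(if (rng[1] >= 0 && rng[1] <= 255) rng[1] else 128,
           nrow(x), ncol(x))
  } else {
    (x - rng[1]) / (rng[2] - rng[1]) * 255
  }
  gray_image(px, pixel_spacing = pixel_spacing)
}

#' Write / read a binary mask as an 8-bit PNG
#'
#' Foreground is stored as 255, background as 0; the round trip
#' `read_mask(write_mask(m, f))` is bit-exact.
#'
#' @param mask a [binary_mask()].
#' @param path output (input) PNG path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  mask <- binary_mask(as_matrix(mask) | matrix(FALSE, nrow(mask), ncol(mask)))
  ok <- try(png::writePNG(as_matrix(mask) * 1.0, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write mask to ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  binary_mask(arr > 0.5)
}

#' Persist feature vectors as a CSV table
#'
#' One row per region with an `id` column, one column per feature (in the
#' order of the first vector's names) and, when labels are supplied, a
#' final `label` column. All rows must share one feature schema.
#'
#' @param features a list of named numeric vectors (e.g. from
#'   [extract_features()]), all with identical names.
#' @param path output CSV path.
#' @param ids character vector of region/image identifiers; defaults to
#'   `"img_1"`, `"img_2"`, ...
#' @param labels optional factor/character vector of class labels.
#' @return `write_feature_table` returns the written data frame
#'   invisibly; `read_feature_table` returns a data frame.
#' @export
write_feature_table <- function(features, path, ids = NULL, labels = NULL) {
  stopifnot(is.list(features))
  n <- length(features)
  if (is.null(ids)) ids <- if (n) paste0("img_", seq_len(n)) else character()
  stopifnot(length(ids) == n, is.null(labels) || length(labels) == n)
  schema <- if (n) names(features[[1]]) else character()
  for (fv in features) {
    if (!identical(names(fv), schema)) {
      stop("all feature vectors must share the same names, in the same order",
           call. = FALSE)
    }
  }
  mat <- if (n) do.call(rbind, lapply(features, as.numeric)) else
    matrix(numeric(), 0, length(schema))
  colnames(mat) <- schema
  df <- data.frame(id = as.character(ids), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# ---- minimal single-frame DICOM reader --------------------------------
#
# Supports uncompressed little-endian transfer syntaxes (implicit
# 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1), MONOCHROME
# photometric interpretations, 8- or 16-bit pixels. Enough for
# single-slice exports from clinical workstations; compressed or
# multi-frame objects are rejected with a clear error.

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || !identical(raw[129:132], charToRaw("DICM"))) {
    stop("not a DICOM part-10 file (missing DICM marker): ", path,
         call. = FALSE)
  }
  elems <- parse_dicom_elements(raw)
  need <- function(tag, what) {
    if (is.null(elems[[tag]])) {
      stop("DICOM file lacks required element ", what, call. = FALSE)
    }
    elems[[tag]]
  }
  rows <- dicom_uint(need("0028,0010", "Rows"))
  cols <- dicom_uint(need("0028,0011", "Columns"))
  bits <- dicom_uint(need("0028,0100", "BitsAllocated"))
  signed <- if (!is.null(elems[["0028,0103"]])) {
    dicom_uint(elems[["0028,0103"]]) == 1L
  } else FALSE
  frames <- if (!is.null(elems[["0028,0008"]])) {
    as.integer(trimws(rawToChar(elems[["0028,0008"]])))
  } else 1L
  if (!is.na(frames) && frames > 1L) {
    stop("multi-frame DICOM objects are not supported", call. = FALSE)
  }
  pix <- need("7fe0,0010", "PixelData")
  vals <- switch(as.character(bits),
    "8"  = as.integer(pix),
    "16" = readBin(pix, "integer", n = length(pix) %/% 2L, size = 2L,
                   signed = signed, endian = "little"),
    stop("unsupported BitsAllocated: ", bits, call. = FALSE))
  if (length(vals) < rows * cols) {
    stop("truncated DICOM pixel data", call. = FALSE)
  }
  vals <- vals[seq_len(rows * cols)]
  slope <- if (!is.null(elems[["0028,1053"]]))
    as.numeric(trimws(rawToChar(elems[["0028,1053"]]))) else 1
  inter <- if (!is.null(elems[["0028,1052"]]))
    as.numeric(trimws(rawToChar(elems[["0028,1052"]]))) else 0
  spacing <- NULL
  if (!is.null(elems[["0028,0030"]])) {
    sp <- suppressWarnings(as.numeric(
      strsplit(trimws(rawToChar(elems[["0028,0030"]])), "\\\\")[[1]]))
    if (length(sp) == 2L && all(is.finite(sp)) && all(sp > 0)) spacing <- sp
  }
  # DICOM pixel data is stored row by row
  m <- matrix(vals * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  rescale_to_uint8(m, pixel_spacing = spacing)
}

parse_dicom_elements <- function(raw) {
  n <- length(raw)
  pos <- 133L                      # first byte after "DICM"
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) {
    as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
      65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  }
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  elems <- list()
  explicit <- TRUE                 # file meta group is always explicit LE
  syntax_checked <- FALSE
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (!syntax_checked && group != 0x0002) {
      ts <- elems[["0002,0010"]]
      if (!is.null(ts)) {
        uid <- gsub("\\x00|\\s", "", rawToChar(ts))
        if (uid == "1.2.840.10008.1.2") {
          explicit <- FALSE
        } else if (uid != "1.2.840.10008.1.2.1") {
          stop("unsupported DICOM transfer syntax ", uid,
               " (only uncompressed little endian)", call. = FALSE)
        }
      }
      syntax_checked <- TRUE
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(pos + 4L); hdr <- 8L
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (vr == "SQ" || len == 4294967295) {
      stop("DICOM sequences / undefined lengths are not supported",
           call. = FALSE)
    }
    start <- pos + hdr
    if (len > 0 && start + len - 1L <= n) {
      elems[[tag]] <- raw[start:(start + len - 1L)]
    }
    pos <- start + len
  }
  elems
}

dicom_uint <- function(bytes) {
  sum(as.integer(bytes) * 256^(seq_along(bytes) - 1L))
}
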