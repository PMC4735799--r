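#' Nuclei image container
#'
#' A 2-D grayscale intensity grid, e.g. a Hoechst-stained nuclei channel.
#' Intensities are stored on the native integer scale of the bit depth
#' (0..255 for 8-bit, 0..65535 for 16-bit).
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param bit_depth 8 or 16.
#' @return A matrix of class `nuclei_image` with a `bit_depth` attribute.
#' @export
nuclei_image <- function(pixels, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L,
            bit_depth %in% c(8L, 16L))
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxv)) {
    stop("intensities outside the ", bit_depth, "-bit range", call. = FALSE)
  }
  structure(pixels, class = "nuclei_image", bit_depth = as.integer(bit_depth))
}

#' @export
print.nuclei_image <- function(x, ...) {
  cat(sprintf("<nuclei_image> %d x %d, %d-bit\n",
              nrow(x), ncol(x), attr(x, "bit_depth")))
  invisible(x)
}

#' Read a grayscale nuclei image from PNG or TIFF
#'
#' RGB images are converted to grayscale by channel averaging; native
#' grayscale is used as-is. Values are rescaled to the 8-bit integer
#' range.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [nuclei_image()].
#' @export
read_nuclei_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L]))],
                                       c(1L, 2L), mean)
  nuclei_image(round(a * 255), bit_depth = 8L)
}

.as_binary <- function(mask) {
  stopifnot(is.matrix(mask))
  structure(mask != 0, class = "binary_mask")
}

#' Segment nuclei by Otsu thresholding and morphological cleanup
#'
#' Binarizes the image with the intensity-based automatic Otsu threshold
#' (foreground = pixels above the threshold), fills holes (background
#' regions not connected to the image border become foreground), then
#' applies one morphological opening with the 3x3 square structuring
#' element, which removes isolated specks smaller than the element.
#'
#' @param img A [nuclei_image()].
#' @return A logical matrix of class `binary_mask`.
#' @export
segment_nuclei <- function(img) {
  stopifnot(inherits(img, "nuclei_image"))
  maxv <- 2^attr(img, "bit_depth") - 1
  m <- unclass(img)
  if (diff(range(m)) == 0) {
    stop(errorCondition("constant image: Otsu threshold undefined",
                        class = c("degenerate_histogram", "error")))
  }
  x <- EBImage::Image(m / maxv)
  thr <- EBImage::otsu(x, range = c(0, 1), levels = maxv + 1)
  fg <- EBImage::fillHull(x > thr)
  fg <- EBImage::opening(fg, EBImage::makeBrush(3L, shape = "box"))
  .as_binary(matrix(as.numeric(fg) != 0, nrow(m), ncol(m)))
}

# merge 4-connected labels that touch diagonally, returning the number of
# 8-connected components
.count_8connected <- function(lab) {
  nmax <- max(lab)
  if (nmax == 0L) return(0L)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dj in c(-1L, 1L)) {
    a <- lab[-nr, , drop = FALSE]
    b <- if (dj == 1L) {
      cbind(lab[-1L, -1L, drop = FALSE], 0L)
    } else {
      cbind(0L, lab[-1L, -nc, drop = FALSE])
    }
    hit <- a > 0L & b > 0L & a != b
    if (any(hit)) {
      pairs <- unique(cbind(a[hit], b[hit]))
      for (k in seq_len(nrow(pairs))) union_(pairs[k, 1L], pairs[k, 2L])
    }
  }
  length(unique(vapply(seq_len(nmax), find, integer(1L))))
}

#' Count 8-connected foreground components
#'
#' @param mask A `binary_mask` (or logical/0-1 matrix).
#' @return Integer count of 8-connected foreground objects.
#' @export
count_components <- function(mask) {
  m <- unclass(.as_binary(mask))
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  .count_8connected(matrix(as.integer(lab), nrow(m), ncol(m)))
}

#' Dilate a binary mask by a Chebyshev radius
#'
#' Applies `distance_px` iterations of binary dilation with the 3x3
#' square structuring element, i.e. the foreground grows to every pixel
#' within Chebyshev distance `distance_px` of the original foreground
#' (the ImageJ binary-dilate convention).
#'
#' @param mask A `binary_mask`.
#' @param distance_px Non-negative integer dilation distance (default 5,
#'   chosen as roughly half a cell diameter).
#' @return The dilated `binary_mask`.
#' @export
dilate_mask <- function(mask, distance_px = 5L) {
  stopifnot(length(distance_px) == 1L, distance_px >= 0,
            distance_px == round(distance_px))
  m <- unclass(.as_binary(mask))
  if (distance_px == 0L) return(.as_binary(m))
  d <- EBImage::dilate(EBImage::Image(m * 1),
                       EBImage::makeBrush(2L * as.integer(distance_px) + 1L,
                                          shape = "box"))
  .as_binary(matrix(as.numeric(d) != 0, nrow(m), ncol(m)))
}

#' Nucleus-nucleus distance index
#'
#' Quantifies cell clustering from a nuclei-stained image: segment nuclei
#' ([segment_nuclei()]), count objects (`N0`), dilate the mask by
#' `distance_px` pixels ([dilate_mask()]) so that nuclei closer than
#' twice the dilation distance merge, count objects again (`N5`), and
#' return the index `N5 / N0`. The index is close to 1 when cells are
#' sparsely distributed and approaches 0 as cells cluster.
#'
#' @param img A [nuclei_image()], or an already segmented `binary_mask`.
#' @param distance_px Dilation distance in pixels (default 5).
#' @return An object of class `cluster_index_result`: list with `n0`,
#'   `n5`, `index` (NA and flagged `undefined` when `n0 = 0`) and
#'   `distance_px`.
#' @export
nn_distance_index <- function(img, distance_px = 5L) {
  mask <- if (inherits(img, "binary_mask")) img else segment_nuclei(img)
  n0 <- count_components(mask)
  n5 <- count_components(dilate_mask(mask, distance_px))
  structure(list(n0 = n0, n5 = n5,
                 index = if (n0 > 0) n5 / n0 else NA_real_,
                 undefined = n0 == 0L,
                 distance_px = as.integer(distance_px)),
            class = "cluster_index_result")
}

#' @export
print.cluster_index_result <- function(x, ...) {
  cat(sprintf("<cluster_index_result> N0 = %d, N%d = %d, index = %s\n",
              x$n0, x$distance_px, x$n5,
              if (x$undefined) "undefined" else format(x$index)))
  invisible(x)
}
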