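#' Binary mask
#'
#' A `H x W` matrix of 0/1 values marking foreground pixels, with the same
#' shape as the image it was derived from.
#'
#' @param values integer/logical matrix of 0/1.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(values) {
  if (is.logical(values)) values <- values * 1L
  if (!is.matrix(values) || !all(values %in% c(0L, 1L)))
    stop("a mask must be a matrix of 0/1 values", call. = FALSE)
  storage.mode(values) <- "integer"
  structure(values, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground pixel%s\n",
              nrow(x), ncol(x), sum(x), if (sum(x) == 1L) "" else "s"))
  invisible(x)
}

mask_values <- function(mask) {
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Segmentation parameters
#'
#' Tunable parameters of the lung region-of-interest pipeline. The lungs are
#' the dark (below-threshold) phase of a CT slice; the dark air surrounding
#' the body is discarded because it touches the image border.
#'
#' @param threshold_method `"otsu"` (threshold from the image histogram) or
#'   `"fixed"`.
#' @param fixed_threshold intensity cut used when `threshold_method = "fixed"`.
#' @param dilation_iterations number of dilation passes applied to the mask.
#' @param structuring_element `"square3"` (3x3 box, 8-neighbourhood) or
#'   `"cross3"` (3x3 cross, 4-neighbourhood).
#' @param crop_margin pixels of margin added around the mask bounding box.
#' @param min_component_area connected components smaller than this many
#'   pixels are discarded as noise.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                dilation_iterations = 2L,
                                structuring_element = c("square3", "cross3"),
                                crop_margin = 0L,
                                min_component_area = 64L) {
  threshold_method <- match.arg(threshold_method)
  structuring_element <- match.arg(structuring_element)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0))
    stop("`fixed_threshold` required for threshold_method = \"fixed\"",
         call. = FALSE)
  if (dilation_iterations < 0L || crop_margin < 0L || min_component_area < 0L)
    stop("counts must be nonnegative", call. = FALSE)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 dilation_iterations = as.integer(dilation_iterations),
                 structuring_element = structuring_element,
                 crop_margin = as.integer(crop_margin),
                 min_component_area = as.integer(min_component_area)),
            class = "segmentation_params")
}

seg_kernel <- function(element) {
  EBImage::makeBrush(3L, shape = if (element == "square3") "box" else "diamond")
}

#' Threshold a CT slice into a lung mask
#'
#' Foreground pixels are those strictly darker than the threshold (lungs are
#' low intensity on CT) that are *not* connected to the image border — the
#' border-connected dark phase is the air around the body and is removed by
#' flood fill from the border. Components smaller than
#' `params$min_component_area` are discarded.
#'
#' @param img a grayscale [image_grid()].
#' @param params a [segmentation_params()] object.
#' @return A [binary_mask()].
#' @export
threshold_mask <- function(img, params = segmentation_params()) {
  assert_image(img)
  if (n_channels(img) != 1L)
    stop("segmentation expects a grayscale image", call. = FALSE)
  px <- as.matrix(img)
  L <- n_levels(img)
  if (min(px) == max(px))
    stop("image has zero dynamic range; no threshold separates lung from body",
         call. = FALSE)
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(px / (L - 1)), range = c(0, 1),
                  levels = L) * (L - 1)
  } else {
    params$fixed_threshold
  }
  dark <- px < thr
  lab <- EBImage::bwlabel(EBImage::Image(dark * 1))
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  keep <- lab > 0L & !(lab %in% border)
  if (params$min_component_area > 0L && any(keep)) {
    sizes <- tabulate(lab[keep])
    small <- which(sizes > 0L & sizes < params$min_component_area)
    if (length(small)) keep <- keep & !(lab %in% small)
  }
  binary_mask(keep)
}

#' Dilate a binary mask
#'
#' Morphological dilation applied `iterations` times with a 3x3 structuring
#' element. Dilation is monotone: the output always contains the input.
#'
#' @param mask a [binary_mask()].
#' @param iterations number of passes (0 returns the mask unchanged).
#' @param element `"square3"` or `"cross3"`.
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask, iterations = 1L,
                        element = c("square3", "cross3")) {
  element <- match.arg(element)
  m <- mask_values(mask)
  if (iterations > 0L) {
    kern <- seg_kernel(element)
    im <- EBImage::Image(m)
    for (i in seq_len(iterations)) im <- EBImage::dilate(im, kern)
    m <- matrix(as.integer(im > 0), nrow(m), ncol(m))
  }
  binary_mask(m)
}

#' Fill enclosed holes in a mask
#'
#' Every background component not connected to the image border becomes
#' foreground (flood fill from the border identifies the true background).
#' Monotone: the output contains the input.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()].
#' @export
fill_mask_holes <- function(mask) {
  m <- mask_values(mask)
  filled <- EBImage::fillHull(EBImage::Image(m))
  binary_mask(matrix(as.integer(filled > 0), nrow(m), ncol(m)))
}

mask_bbox <- function(mask) {
  m <- mask_values(mask)
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("mask is empty; segmentation found no lung region", call. = FALSE)
  c(r0 = min(idx[, 1]), c0 = min(idx[, 2]),
    r1 = max(idx[, 1]), c1 = max(idx[, 2]))
}

#' Crop an image to the mask's region of interest
#'
#' Returns the subimage covering the foreground bounding box of `mask`,
#' expanded by `margin` pixels on each side and clipped to the image bounds.
#'
#' @param img an [image_grid()].
#' @param mask a nonempty [binary_mask()] of the same shape.
#' @param margin margin in pixels (>= 0).
#' @return An `image_grid` no larger than the input, with attribute `"bbox"`
#'   giving the crop bounds `(r0, c0, r1, c1)` in the source image.
#' @export
crop_to_roi <- function(img, mask, margin = 0L) {
  assert_image(img)
  d <- dim(img)
  if (!identical(dim(mask_values(mask)), d[1:2]))
    stop("mask shape does not match the image", call. = FALSE)
  bb <- mask_bbox(mask)
  r0 <- max(1L, bb["r0"] - margin); r1 <- min(d[1], bb["r1"] + margin)
  c0 <- max(1L, bb["c0"] - margin); c1 <- min(d[2], bb["c1"] + margin)
  out <- image_grid(ig_data(img)[r0:r1, c0:c1, , drop = FALSE],
                    levels = n_levels(img))
  attr(out, "bbox") <- as.integer(c(r0, c0, r1, c1))
  out
}

#' Segment the lung region of interest
#'
#' The full deterministic preprocessing pipeline for a chest CT slice:
#' threshold to a lung mask, dilate, fill holes, then crop the image to the
#' mask's bounding box. Both lungs are cropped together as one box.
#'
#' @param img a grayscale [image_grid()].
#' @param params a [segmentation_params()] object.
#' @return The cropped `image_grid`, with attributes `"bbox"` (crop bounds in
#'   the source image) and `"mask"` (the post-morphology [binary_mask()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 128, width = 128, seed = 1))
#' roi <- segment_lungs(ph$image)
#' dim(roi)
#' @export
segment_lungs <- function(img, params = segmentation_params()) {
  mask <- threshold_mask(img, params)
  mask <- dilate_mask(mask, params$dilation_iterations,
                      params$structuring_element)
  mask <- fill_mask_holes(mask)
  out <- crop_to_roi(img, mask, params$crop_margin)
  attr(out, "mask") <- mask
  out
}
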