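#' Construct an image grid
#'
#' The basic raster container of the package: an `H x W x C` array of integer
#' intensities in `[0, levels - 1]`. Grayscale matrices are promoted to a
#' single-channel array. All augmentation, segmentation and phantom operations
#' consume and return `image_grid` objects.
#'
#' Conventions used throughout the package: pixel coordinates are 1-based
#' `(row, col)` with the origin at the top-left; rectangles are given as an
#' origin plus an extent (see [patch_rect()]), both inclusive.
#'
#' @param pixels integer matrix (`H x W`) or array (`H x W x C`) of
#'   intensities in `[0, levels - 1]`.
#' @param levels number of representable intensity levels `L` (256 for 8-bit
#'   images, the default).
#' @return An `image_grid` object.
#' @examples
#' img <- image_grid(matrix(0:15, 4, 4, byrow = TRUE))
#' dim(img)
#' global_intensity(img)
#' @export
image_grid <- function(pixels, levels = 256L) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W matrix or H x W x C array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L || d[3] < 1L)
    stop("image must have at least one pixel per channel", call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("`levels` must be an integer >= 2", call. = FALSE)
  if (anyNA(pixels)) stop("pixel intensities must not be NA", call. = FALSE)
  if (is.double(pixels) && any(pixels != round(pixels)))
    stop("pixel intensities must be integers (integer mode)", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > levels - 1L)
    stop("pixel intensities must lie in [0, levels - 1]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(pixels, levels = levels, class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_grid> %d x %d, %d channel%s, L = %d\n",
              d[1], d[2], d[3], if (d[3] > 1L) "s" else "", n_levels(x)))
  invisible(x)
}

#' Number of intensity levels of an image
#' @param img an `image_grid`.
#' @return Integer `L` (256 for 8-bit images).
#' @export
n_levels <- function(img) attr(img, "levels")

#' @rdname n_levels
#' @export
n_channels <- function(img) dim(img)[3]

is_image_grid <- function(x) inherits(x, "image_grid")

assert_image <- function(img) {
  if (!is_image_grid(img)) stop("expected an `image_grid`", call. = FALSE)
  invisible(img)
}

#' @export
as.matrix.image_grid <- function(x, ...) {
  if (dim(x)[3] != 1L)
    stop("multi-channel image; subset a channel first", call. = FALSE)
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m)[1:2])
  m
}

# raw integer array without class/attrs beyond dim
ig_data <- function(img) {
  a <- unclass(img)
  attr(a, "levels") <- NULL
  a
}

same_geometry <- function(a, b) identical(dim(a), dim(b))

# PNG bit depth lives at a fixed offset in the IHDR chunk
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  if (length(hdr) < 26L) stop("not a PNG file: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

#' Read a raster image from disk
#'
#' Reads a PNG or JPEG file into an [image_grid()]. 8-bit files map to
#' `L = 256`; 16-bit PNGs map to `L = 65536`. Grayscale and 3-channel images
#' are supported; a PNG alpha channel is dropped.
#'
#' @param path path to an existing `.png`, `.jpg` or `.jpeg` file.
#' @return An `image_grid` with the file's height, width and channels.
#' @seealso [save_image()]
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    depth <- png_bit_depth(path)
    L <- if (depth == 16L) 65536L else 256L
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    L <- 256L
    a <- tryCatch(as.array(EBImage::readImage(path)),
                  error = function(e) stop("cannot read image: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
    # EBImage stores x (width) first; put rows first
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: .", ext, " (PNG or JPEG expected)",
         call. = FALSE)
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3L && dim(a)[3] == 2L) a <- a[, , 1L, drop = FALSE]
  image_grid(round(a * (L - 1)), levels = L)
}

#' Write an image grid to disk
#'
#' PNG output is lossless: a save/load round trip reproduces the pixels
#' exactly. JPEG output is supported for export but is lossy and must never be
#' used where pixel equality matters.
#'
#' @param img an `image_grid` with `L = 256` (8-bit).
#' @param path destination path; format chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`).
#' @param quality JPEG quality in `[1, 100]`; ignored for PNG.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, quality = 95) {
  assert_image(img)
  if (n_levels(img) > 256L)
    stop("save_image writes 8-bit files only (L = 256)", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  a <- ig_data(img) / (n_levels(img) - 1L)
  if (dim(a)[3] == 1L) dim(a) <- dim(a)[1:2]
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext == "png") {
      png::writePNG(a, path)
    } else if (ext %in% c("jpg", "jpeg")) {
      x <- if (is.matrix(a)) t(a) else aperm(a, c(2L, 1L, 3L))
      EBImage::writeImage(EBImage::Image(x,
        colormode = if (is.matrix(a)) "Grayscale" else "Color"),
        path, quality = quality)
    } else {
      stop("unsupported image format: .", ext, call. = FALSE)
    }
    TRUE
  }, error = function(e) stop("cannot write ", path, " (",
                              conditionMessage(e), ")", call. = FALSE))
  invisible(path)
}

#' Intensity histogram of an image
#'
#' Counts `n(i)` of pixels at each intensity level `i` in `[0, L - 1]`,
#' together with relative frequencies `p(i) = n(i) / N`. Channels are pooled
#' by default; `per_channel = TRUE` returns one count column per channel.
#' The histogram is the invariant that Random Pixel Swap preserves exactly:
#' a patch swap permutes pixels, so every `n(i)` is unchanged.
#'
#' @param img an `image_grid` in integer mode.
#' @param per_channel logical; tally each channel separately.
#' @return An `intensity_histogram`: list with `counts` (length-`L` vector, or
#'   `L x C` matrix if `per_channel`), `p`, `N` (pixels per tally) and `L`.
#' @export
intensity_histogram <- function(img, per_channel = FALSE) {
  assert_image(img)
  L <- n_levels(img)
  a <- ig_data(img)
  counts <- if (per_channel) {
    vapply(seq_len(dim(a)[3]),
           function(k) tabulate(a[, , k] + 1L, nbins = L),
           integer(L))
  } else {
    tabulate(a + 1L, nbins = L)
  }
  N <- if (per_channel) prod(dim(a)[1:2]) else length(a)
  structure(list(counts = counts, p = counts / N, N = N, L = L),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  nz <- sum(if (is.matrix(x$counts)) rowSums(x$counts) else x$counts > 0)
  cat(sprintf("<intensity_histogram> L = %d, N = %d, %d occupied level%s\n",
              x$L, x$N, nz, if (nz == 1L) "" else "s"))
  invisible(x)
}

#' Global intensity of an image
#'
#' The sum of all pixel intensities, `Ig = sum_i i * n(i)`, computed in exact
#' integer arithmetic. Any pixel permutation — in particular a Random Pixel
#' Swap — conserves `Ig` exactly.
#'
#' @param img an `image_grid` in integer mode.
#' @return A scalar (double holding an exact integer value).
#' @export
global_intensity <- function(img) {
  assert_image(img)
  sum(as.double(ig_data(img)))
}
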