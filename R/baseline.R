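#' Image with a class-probability label
#'
#' Pairs an [image_grid()] with a label vector of nonnegative class
#' probabilities summing to one (one-hot for hard labels). Only the
#' label-blending techniques ([mixup()], [cutmix()]) need this type; every
#' other augmentation leaves labels untouched by construction.
#'
#' @param image an `image_grid`.
#' @param label numeric probability vector, components >= 0 summing to 1.
#' @return A `labeled_image` object.
#' @export
labeled_image <- function(image, label) {
  assert_image(image)
  label <- as.numeric(label)
  if (any(label < 0) || abs(sum(label) - 1) > 1e-9)
    stop("label must be a probability vector summing to 1", call. = FALSE)
  structure(list(image = image, label = label), class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  print(x$image)
  cat("  label:", paste(signif(x$label, 4), collapse = " "), "\n")
  invisible(x)
}

#' Cutout augmentation
#'
#' Masks one square region of side `mask_side`, centered at a uniformly chosen
#' pixel, with a constant fill value; portions of the square falling outside
#' the image are clipped. Unlike RPS, Cutout destroys the masked intensities,
#' so it does not preserve the image histogram in general.
#'
#' @param img an [image_grid()].
#' @param mask_side side of the masked square, in pixels.
#' @param fill intensity used for masking (default 0, i.e. black).
#' @param prob probability of applying the mask.
#' @return A new `image_grid`.
#' @export
cutout <- function(img, mask_side = 16L, fill = 0L, prob = 1.0) {
  assert_image(img)
  mask_side <- as.integer(mask_side)
  if (is.na(mask_side) || mask_side < 1L)
    stop("`mask_side` must be a positive integer", call. = FALSE)
  if (fill < 0 || fill > n_levels(img) - 1L)
    stop("`fill` outside the intensity range", call. = FALSE)
  if (prob < 1 && stats::runif(1) >= prob) return(img)
  d <- dim(img)
  cr <- sample.int(d[1], 1L)
  cc <- sample.int(d[2], 1L)
  r <- max(1L, cr - (mask_side - 1L) %/% 2L):min(d[1], cr + mask_side %/% 2L)
  cl <- max(1L, cc - (mask_side - 1L) %/% 2L):min(d[2], cc + mask_side %/% 2L)
  out <- ig_data(img)
  out[r, cl, ] <- as.integer(fill)
  image_grid(out, levels = n_levels(img))
}

#' Random Erasing augmentation
#'
#' Erases one rectangle, whose area fraction and aspect ratio are drawn from
#' the given ranges, and fills it with independent uniform-random intensities.
#' If no feasible rectangle is found within `max_attempts` proposals the image
#' is returned unchanged with a warning. Defaults follow the technique's
#' original publication.
#'
#' @param img an [image_grid()].
#' @param prob probability of applying the erase.
#' @param area_range erased-area fraction bounds `(lo, hi)`, `0 < lo <= hi < 1`.
#' @param aspect_range aspect-ratio (height/width) bounds.
#' @param max_attempts proposals tried before giving up.
#' @return A new `image_grid`.
#' @export
random_erasing <- function(img, prob = 0.5, area_range = c(0.02, 0.33),
                           aspect_range = c(0.3, 3.3), max_attempts = 100L) {
  assert_image(img)
  if (!(area_range[1] > 0 && area_range[1] <= area_range[2] &&
        area_range[2] < 1))
    stop("`area_range` must satisfy 0 < lo <= hi < 1", call. = FALSE)
  if (prob < 1 && stats::runif(1) >= prob) return(img)
  d <- dim(img)
  area <- d[1] * d[2]
  for (i in seq_len(max_attempts)) {
    target <- stats::runif(1, area_range[1], area_range[2]) * area
    ratio <- stats::runif(1, aspect_range[1], aspect_range[2])
    eh <- as.integer(round(sqrt(target * ratio)))
    ew <- as.integer(round(sqrt(target / ratio)))
    if (eh < 1L || ew < 1L || eh > d[1] || ew > d[2]) next
    r0 <- sample.int(d[1] - eh + 1L, 1L)
    c0 <- sample.int(d[2] - ew + 1L, 1L)
    out <- ig_data(img)
    out[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L), ] <-
      sample.int(n_levels(img), eh * ew * d[3], replace = TRUE) - 1L
    return(image_grid(out, levels = n_levels(img)))
  }
  warning("random_erasing: no feasible rectangle found; returning input")
  img
}

#' MixUp augmentation
#'
#' Blends two labeled images by a convex combination with weight
#' `lambda ~ Beta(alpha, alpha)`: pixels are interpolated (rounded
#' half-to-even in integer mode and clamped to the intensity range) and labels
#' are interpolated with the same weight.
#'
#' @param a,b [labeled_image()] objects of identical shape.
#' @param alpha Beta concentration parameter (> 0).
#' @param lambda optional fixed mixing weight in `[0, 1]`, overriding the Beta
#'   draw (useful for testing).
#' @return A `labeled_image`.
#' @export
mixup <- function(a, b, alpha = 0.2, lambda = NULL) {
  check_pair(a, b)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  lam <- if (is.null(lambda)) stats::rbeta(1, alpha, alpha) else lambda
  if (lam < 0 || lam > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
  L <- n_levels(a$image)
  px <- round(lam * ig_data(a$image) + (1 - lam) * ig_data(b$image))
  px <- pmin(pmax(px, 0), L - 1L)
  labeled_image(image_grid(px, levels = L),
                lam * a$label + (1 - lam) * b$label)
}

#' CutMix augmentation
#'
#' Pastes one rectangle of image `b` into image `a`. The rectangle's area
#' fraction is `1 - lambda` with `lambda ~ Beta(alpha, alpha)`; its center is
#' uniform and it is clipped to the image bounds. Labels are blended with the
#' effective weight `lambda_eff = 1 - pasted_area / (H * W)`, recomputed after
#' clipping so the label mixture reflects the pixels actually pasted.
#'
#' @inheritParams mixup
#' @return A `labeled_image` with attribute `"lambda_eff"`.
#' @export
cutmix <- function(a, b, alpha = 0.2, lambda = NULL) {
  check_pair(a, b)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  lam <- if (is.null(lambda)) stats::rbeta(1, alpha, alpha) else lambda
  if (lam < 0 || lam > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
  d <- dim(a$image)
  cut <- sqrt(1 - lam)
  rh <- as.integer(round(d[1] * cut))
  rw <- as.integer(round(d[2] * cut))
  out <- ig_data(a$image)
  pasted <- 0L
  if (rh >= 1L && rw >= 1L) {
    cr <- sample.int(d[1], 1L)
    cc <- sample.int(d[2], 1L)
    r <- max(1L, cr - rh %/% 2L):min(d[1], cr - rh %/% 2L + rh - 1L)
    cl <- max(1L, cc - rw %/% 2L):min(d[2], cc - rw %/% 2L + rw - 1L)
    out[r, cl, ] <- ig_data(b$image)[r, cl, , drop = FALSE]
    pasted <- length(r) * length(cl)
  }
  lam_eff <- 1 - pasted / (d[1] * d[2])
  res <- labeled_image(image_grid(out, levels = n_levels(a$image)),
                       lam_eff * a$label + (1 - lam_eff) * b$label)
  attr(res, "lambda_eff") <- lam_eff
  res
}

check_pair <- function(a, b) {
  if (!inherits(a, "labeled_image") || !inherits(b, "labeled_image"))
    stop("expected labeled_image objects (see labeled_image())", call. = FALSE)
  if (!same_geometry(a$image, b$image))
    stop("images must have identical dimensions", call. = FALSE)
  if (length(a$label) != length(b$label))
    stop("labels must have the same number of classes", call. = FALSE)
  invisible(TRUE)
}

#' Mirror an image
#'
#' `"horizontal"` mirrors left-right (reverses columns); `"vertical"` mirrors
#' top-bottom (reverses rows). Flips permute pixels, so they preserve the
#' intensity histogram, and each is its own inverse.
#'
#' @param img an [image_grid()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return A new `image_grid` of the same shape.
#' @export
flip_image <- function(img, axis = c("horizontal", "vertical")) {
  assert_image(img)
  axis <- match.arg(axis)
  a <- ig_data(img)
  a <- if (axis == "horizontal") a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
       else a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  image_grid(a, levels = n_levels(img))
}

#' Quarter-turn rotation
#'
#' Rotates the image by 90 degrees. `"cw"` is clockwise (+90), `"ccw"`
#' counter-clockwise (-90). Height and width are exchanged; the histogram is
#' preserved and four equal turns restore the input. [random_rotation()]
#' picks the direction uniformly, matching the traditional "random rotation
#' (+/-90 degrees)" augmentation.
#'
#' @param img an [image_grid()].
#' @param direction `"cw"` or `"ccw"`.
#' @return A new `image_grid` with transposed dimensions.
#' @export
rotate90 <- function(img, direction = c("cw", "ccw")) {
  assert_image(img)
  direction <- match.arg(direction)
  a <- ig_data(img)
  a <- aperm(a, c(2L, 1L, 3L))
  a <- if (direction == "cw") a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
       else a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  image_grid(a, levels = n_levels(img))
}

#' @rdname rotate90
#' @export
random_rotation <- function(img) {
  rotate90(img, sample(c("cw", "ccw"), 1L))
}
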