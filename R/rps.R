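#' Axis-aligned pixel rectangle
#'
#' Rectangles are stored as a 1-based origin `(r0, c0)` plus an extent
#' `(h, w)`, covering rows `r0 .. r0 + h - 1` and columns `c0 .. c0 + w - 1`
#' inclusive.
#'
#' @param r0,c0 top-left pixel (1-based).
#' @param h,w height and width in pixels (>= 1).
#' @return A `patch_rect` object.
#' @export
patch_rect <- function(r0, c0, h, w) {
  v <- as.integer(c(r0, c0, h, w))
  if (anyNA(v) || v[3] < 1L || v[4] < 1L || v[1] < 1L || v[2] < 1L)
    stop("invalid rectangle: origin must be >= 1 and extent >= 1",
         call. = FALSE)
  structure(list(r0 = v[1], c0 = v[2], h = v[3], w = v[4]),
            class = "patch_rect")
}

#' @export
print.patch_rect <- function(x, ...) {
  cat(sprintf("<patch_rect> rows %d..%d, cols %d..%d (%d x %d, area %d)\n",
              x$r0, x$r0 + x$h - 1L, x$c0, x$c0 + x$w - 1L,
              x$h, x$w, rect_area(x)))
  invisible(x)
}

#' @rdname patch_rect
#' @param rect a `patch_rect`.
#' @export
rect_area <- function(rect) rect$h * rect$w

rect_shift <- function(rect, dr, dc)
  patch_rect(rect$r0 + dr, rect$c0 + dc, rect$h, rect$w)

rect_rows <- function(rect) seq.int(rect$r0, rect$r0 + rect$h - 1L)
rect_cols <- function(rect) seq.int(rect$c0, rect$c0 + rect$w - 1L)

rect_within <- function(inner, outer) {
  inner$r0 >= outer$r0 && inner$c0 >= outer$c0 &&
    inner$r0 + inner$h <= outer$r0 + outer$h &&
    inner$c0 + inner$w <= outer$c0 + outer$w
}

rect_disjoint <- function(a, b) {
  a$r0 + a$h <= b$r0 || b$r0 + b$h <= a$r0 ||
    a$c0 + a$w <= b$c0 || b$c0 + b$w <= a$c0
}

rect_in_image <- function(rect, H, W)
  rect_within(rect, patch_rect(1L, 1L, H, W))

#' Shrink a rectangle by a swap-area factor
#'
#' Scales each side of `rect` by `sqrt(sf)` about its center, rounding to the
#' nearest integer with a floor of one pixel, so the area of the result is the
#' fraction `sf` of the original up to integer rounding. `sf = 1` returns
#' `rect` unchanged; the result always lies inside `rect`.
#'
#' @param rect a [patch_rect()] with positive area.
#' @param sf swap-area factor in `[0.1, 1.0]`.
#' @return A `patch_rect` inside `rect`.
#' @export
scale_patch <- function(rect, sf) {
  check_sf(sf)
  if (sf == 1) return(rect)
  nh <- max(1L, as.integer(round(rect$h * sqrt(sf))))
  nw <- max(1L, as.integer(round(rect$w * sqrt(sf))))
  patch_rect(rect$r0 + (rect$h - nh) %/% 2L,
             rect$c0 + (rect$w - nw) %/% 2L, nh, nw)
}

check_sf <- function(sf) {
  if (!is.numeric(sf) || length(sf) != 1L || is.na(sf) ||
      sf < 0.1 || sf > 1.0)
    stop("swap-area factor must lie in [0.1, 1.0]", call. = FALSE)
  invisible(sf)
}

#' Swap-area-factor policies
#'
#' The swap-area factor `Sf` in `[0.1, 1.0]` controls what fraction of the
#' sampled sub-swap region is actually exchanged. `svsf()` (single-value swap
#' area factor) always uses one fixed value; `mvsf()` (multi-value) draws a
#' fresh factor uniformly from `[lo, hi]` at every augmentation call.
#'
#' @param value fixed factor for `svsf`.
#' @param lo,hi bounds for `mvsf`, `0.1 <= lo <= hi <= 1.0`.
#' @return A `swap_factor_policy` object.
#' @examples
#' svsf(1.0)      # the defaults used throughout the benchmark experiments
#' mvsf(0.1, 0.9)
#' @export
svsf <- function(value = 1.0) {
  check_sf(value)
  structure(list(mode = "svsf", value = value), class = "swap_factor_policy")
}

#' @rdname svsf
#' @export
mvsf <- function(lo, hi) {
  check_sf(lo); check_sf(hi)
  if (lo > hi) stop("mvsf requires lo <= hi", call. = FALSE)
  structure(list(mode = "mvsf", lo = lo, hi = hi),
            class = "swap_factor_policy")
}

#' @export
print.swap_factor_policy <- function(x, ...) {
  if (x$mode == "svsf") cat(sprintf("<svsf> Sf = %g\n", x$value))
  else cat(sprintf("<mvsf> Sf ~ U[%g, %g]\n", x$lo, x$hi))
  invisible(x)
}

draw_sf <- function(policy) {
  if (!inherits(policy, "swap_factor_policy"))
    stop("expected a swap_factor_policy (see svsf(), mvsf())", call. = FALSE)
  if (policy$mode == "svsf") policy$value else stats::runif(1, policy$lo, policy$hi)
}

rps_configs <- c("h", "w", "u", "d")

check_config <- function(config) {
  config <- match.arg(tolower(config), c(rps_configs, "random"))
  config
}

#' Source/target swap regions for an RPS configuration
#'
#' Each configuration partitions the image into two congruent, disjoint
#' regions related by a pure translation: `"h"` pairs the top and bottom
#' halves (vertical swap), `"w"` the left and right halves (horizontal swap),
#' `"u"` the lower-left and upper-right quadrants (upper-right diagonal), and
#' `"d"` the lower-right and upper-left quadrants (upper-left diagonal). For
#' odd dimensions the middle row/column belongs to neither region and is never
#' swapped.
#'
#' @param height,width image dimensions in pixels (>= 4).
#' @param config one of `"h"`, `"w"`, `"u"`, `"d"`.
#' @return List with source region `A1`, target region `A2` (both
#'   [patch_rect()]) and the integer translation `offset = c(dr, dc)` mapping
#'   `A1` onto `A2`.
#' @export
swap_regions <- function(height, width, config) {
  config <- check_config(config)
  if (config == "random")
    stop("swap_regions needs a concrete configuration", call. = FALSE)
  if (height < 4L || width < 4L)
    stop("image must be at least 4 x 4 for a pixel swap", call. = FALSE)
  h <- height %/% 2L
  w <- width %/% 2L
  res <- switch(config,
    h = list(A1 = patch_rect(1L, 1L, h, width),      offset = c(h, 0L)),
    w = list(A1 = patch_rect(1L, 1L, height, w),     offset = c(0L, w)),
    u = list(A1 = patch_rect(h + 1L, 1L, h, w),      offset = c(-h, w)),
    d = list(A1 = patch_rect(h + 1L, w + 1L, h, w),  offset = c(-h, -w)))
  res$A2 <- rect_shift(res$A1, res$offset[1], res$offset[2])
  res$config <- config
  res[c("config", "A1", "A2", "offset")]
}

#' Sample one concrete swap specification
#'
#' Draws the random geometry of a single Random Pixel Swap: two anchor points
#' `Pi`, `Pj` uniform in the source region `A1`; their inclusive bounding box
#' is the sub-swap rectangle `As1` (a coincident pair gives a legal 1x1
#' patch); `As2` is `As1` translated into the target region `A2`; and both are
#' shrunk by a swap-area factor drawn once from `policy` to give the swap
#' rectangles `Sa1`, `Sa2` that are actually exchanged.
#'
#' The returned spec always satisfies: `Sa1` and `Sa2` congruent, disjoint,
#' inside `A1`/`A2` respectively, area >= 1 pixel.
#'
#' @inheritParams swap_regions
#' @param config `"h"`, `"w"`, `"u"`, `"d"`, or `"random"` (uniform over the
#'   four).
#' @param policy a [svsf()] or [mvsf()] policy.
#' @return A `swap_spec` object.
#' @export
sample_swap_spec <- function(height, width, config = "random",
                             policy = svsf(1.0)) {
  config <- check_config(config)
  if (config == "random") config <- sample(rps_configs, 1L)
  reg <- swap_regions(height, width, config)
  pi_ <- c(reg$A1$r0 + sample.int(reg$A1$h, 1L) - 1L,
           reg$A1$c0 + sample.int(reg$A1$w, 1L) - 1L)
  pj_ <- c(reg$A1$r0 + sample.int(reg$A1$h, 1L) - 1L,
           reg$A1$c0 + sample.int(reg$A1$w, 1L) - 1L)
  as1 <- patch_rect(min(pi_[1], pj_[1]), min(pi_[2], pj_[2]),
                    abs(pi_[1] - pj_[1]) + 1L, abs(pi_[2] - pj_[2]) + 1L)
  as2 <- rect_shift(as1, reg$offset[1], reg$offset[2])
  sf <- draw_sf(policy)
  sa1 <- scale_patch(as1, sf)
  sa2 <- rect_shift(sa1, reg$offset[1], reg$offset[2])
  structure(list(config = config, Pi = pi_, Pj = pj_,
                 A1 = reg$A1, A2 = reg$A2,
                 As1 = as1, As2 = as2, Sa1 = sa1, Sa2 = sa2, sf = sf),
            class = "swap_spec")
}

#' @export
print.swap_spec <- function(x, ...) {
  cat(sprintf("<swap_spec> config %s, Sf = %.3f\n", toupper(x$config), x$sf))
  cat("  Sa1:"); print(x$Sa1)
  cat("  Sa2:"); print(x$Sa2)
  invisible(x)
}

#' Exchange the two swap rectangles of a spec
#'
#' Returns a copy of `img` in which the contents of `spec$Sa1` and `spec$Sa2`
#' are exchanged, all channels moving together. The operation is an
#' involution: applying the same spec twice restores the input.
#'
#' @param img an [image_grid()].
#' @param spec a `swap_spec` from [sample_swap_spec()] whose rectangles lie
#'   inside `img`.
#' @return A new `image_grid`; the input is not modified.
#' @export
apply_swap <- function(img, spec) {
  assert_image(img)
  if (!inherits(spec, "swap_spec")) stop("expected a swap_spec", call. = FALSE)
  d <- dim(img)
  if (!rect_in_image(spec$Sa1, d[1], d[2]) ||
      !rect_in_image(spec$Sa2, d[1], d[2]))
    stop("swap rectangles fall outside this image", call. = FALSE)
  out <- ig_data(img)
  r1 <- rect_rows(spec$Sa1); c1 <- rect_cols(spec$Sa1)
  r2 <- rect_rows(spec$Sa2); c2 <- rect_cols(spec$Sa2)
  block1 <- out[r1, c1, , drop = FALSE]
  out[r1, c1, ] <- out[r2, c2, , drop = FALSE]
  out[r2, c2, ] <- block1
  image_grid(out, levels = n_levels(img))
}

#' Random Pixel Swap augmentation
#'
#' The full RPS operator: with probability `prob` a swap configuration is
#' resolved (uniformly among the four if `config = "random"`), a swap
#' specification is sampled, and the two patches are exchanged; otherwise the
#' image is returned unchanged. Because the transform is a pixel permutation
#' within the image, its intensity histogram and global intensity are
#' preserved exactly, and class labels are never touched.
#'
#' Defaults (`Sf = 1`, `prob = 1`, random configuration) are the settings used
#' in the benchmark experiments the bundled results tables come from.
#'
#' @param img an [image_grid()] of at least 4 x 4 pixels.
#' @param config swap configuration: `"h"`, `"w"`, `"u"`, `"d"` or `"random"`.
#' @param policy a [svsf()] or [mvsf()] swap-area-factor policy.
#' @param prob probability in `[0, 1]` of applying the swap.
#' @return A new `image_grid` of identical dimensions.
#' @examples
#' set.seed(1)
#' img <- image_grid(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
#' aug <- rps(img)
#' identical(intensity_histogram(aug)$counts, intensity_histogram(img)$counts)
#' @export
rps <- function(img, config = "random", policy = svsf(1.0), prob = 1.0) {
  assert_image(img)
  if (!is.numeric(prob) || length(prob) != 1L || prob < 0 || prob > 1)
    stop("`prob` must lie in [0, 1]", call. = FALSE)
  if (prob < 1 && stats::runif(1) >= prob) return(img)
  d <- dim(img)
  spec <- sample_swap_spec(d[1], d[2], config = config, policy = policy)
  apply_swap(img, spec)
}

#' Build a reusable augmentation transform
#'
#' Wraps any of the package's augmentation techniques as a parameterized
#' callable (image in, image out) so techniques compose and are selectable by
#' name, e.g. in the command-line interface or a training pipeline.
#'
#' `"none"` is the identity. `"mixup"`/`"cutmix"` are pairwise techniques and
#' are not available through this single-image interface; see [mixup()] and
#' [cutmix()].
#'
#' @param technique one of `"rps"`, `"cutout"`, `"random_erasing"`,
#'   `"hflip"`, `"vflip"`, `"rot90"`, `"none"`.
#' @param ... parameters forwarded to the technique's function.
#' @return A function of one `image_grid` argument.
#' @examples
#' t <- augmenter("rps", config = "w", policy = svsf(0.5))
#' set.seed(7)
#' out <- t(image_grid(matrix(0:255, 16, 16)))
#' @export
augmenter <- function(technique, ...) {
  technique <- match.arg(technique,
    c("rps", "cutout", "random_erasing", "hflip", "vflip", "rot90", "none"))
  args <- list(...)
  fn <- switch(technique,
    rps = rps,
    cutout = cutout,
    random_erasing = random_erasing,
    hflip = function(img) flip_image(img, "horizontal"),
    vflip = function(img) flip_image(img, "vertical"),
    rot90 = random_rotation,
    none = identity)
  function(img) do.call(fn, c(list(img), args))
}
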