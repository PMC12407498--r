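#' Specification of a synthetic chest-CT phantom
#'
#' Describes one synthetic axial chest-CT-like slice: a dark background, a
#' bright body ellipse, two dark lung ellipses, and — for the tumor classes —
#' a bright nodule disk inside one lung. The benign class has a smooth
#' circular nodule; the malignant class perturbs the nodule boundary with a
#' sinusoidal irregularity, a deliberately simple stand-in for spiculation
#' with no claim of radiological realism. Intensities must be ordered
#' `background < lung < body`.
#'
#' @param height,width canvas size in pixels (default 512 x 512, the native
#'   resolution of typical axial CT slices; 224 mirrors common network input
#'   sizes).
#' @param class_label `"normal"`, `"benign"` or `"malignant"`.
#' @param background_intensity,lung_intensity,body_intensity intensities of
#'   the three tissue phases in `[0, levels - 1]`.
#' @param nodule_intensity nodule intensity; must exceed `lung_intensity`.
#' @param nodule_radius nodule radius in pixels; default scales with the lung.
#' @param irregularity boundary perturbation amplitude in pixels; forced to 0
#'   for benign and must be > 0 for malignant.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units of an 8-bit scale.
#' @param levels intensity levels `L` (default 256).
#' @param seed integer seed making the rendered sample a pure function of the
#'   spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 512L, width = 512L,
                         class_label = c("normal", "benign", "malignant"),
                         background_intensity = 10L, lung_intensity = 60L,
                         body_intensity = 200L, nodule_intensity = 160L,
                         nodule_radius = NULL, irregularity = NULL,
                         noise_sd = 5, levels = 256L, seed = 1L) {
  class_label <- match.arg(class_label)
  if (!(background_intensity < lung_intensity &&
        lung_intensity < body_intensity))
    stop("intensities must satisfy background < lung < body", call. = FALSE)
  if (nodule_intensity <= lung_intensity)
    stop("nodule must be brighter than lung tissue", call. = FALSE)
  if (height < 32L || width < 32L)
    stop("phantom canvas must be at least 32 x 32", call. = FALSE)
  if (is.null(irregularity))
    irregularity <- switch(class_label, normal = 0, benign = 0,
                           malignant = max(1.5, 0.02 * min(height, width)))
  if (class_label == "benign" && irregularity != 0)
    stop("benign nodules have a smooth boundary (irregularity 0)",
         call. = FALSE)
  if (class_label == "malignant" && irregularity <= 0)
    stop("malignant nodules require irregularity > 0", call. = FALSE)
  if (is.null(nodule_radius)) nodule_radius <- 0.045 * min(height, width)
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_label = class_label,
                 background_intensity = as.integer(background_intensity),
                 lung_intensity = as.integer(lung_intensity),
                 body_intensity = as.integer(body_intensity),
                 nodule_intensity = as.integer(nodule_intensity),
                 nodule_radius = nodule_radius,
                 irregularity = irregularity,
                 noise_sd = noise_sd, levels = as.integer(levels),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

in_ellipse <- function(rr, cc, center, ax_r, ax_c) {
  ((rr - center[1]) / ax_r)^2 + ((cc - center[2]) / ax_c)^2 <= 1
}

#' Render a phantom sample
#'
#' Renders the slice described by a [phantom_spec()]: background, body
#' ellipse, two lung ellipses, optional nodule (with sinusoidal boundary
#' perturbation when the irregularity amplitude is positive), then adds
#' Gaussian noise clipped to the intensity range. Identical spec (including
#' its seed) yields a byte-identical sample.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_sample`: list with `image` ([image_grid()]), `label`,
#'   `lung_mask` and `nodule_mask` ([binary_mask()]), `body_bbox`,
#'   `lung_bbox`, `lung_centers`, `nodule_center`, and the `spec` itself.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 96, width = 96,
#'                                     class_label = "malignant", seed = 3))
#' ph$label
#' sum(unclass(ph$nodule_mask))  # nodule area in pixels
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("expected a phantom_spec", call. = FALSE)
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)

  body_center <- c(H / 2, W / 2)
  body_ax <- c(0.40 * H, 0.44 * W)              # (row semi-axis, col semi-axis)
  lung_ax <- c(0.26 * H, 0.15 * W)
  lung_centers <- list(left  = c(H / 2, W / 2 - 0.22 * W),
                       right = c(H / 2, W / 2 + 0.22 * W))

  body <- in_ellipse(rr, cc, body_center, body_ax[1], body_ax[2])
  lungL <- in_ellipse(rr, cc, lung_centers$left,  lung_ax[1], lung_ax[2])
  lungR <- in_ellipse(rr, cc, lung_centers$right, lung_ax[1], lung_ax[2])
  lungs <- lungL | lungR

  base <- matrix(spec$background_intensity, H, W)
  base[body] <- spec$body_intensity
  base[lungs] <- spec$lung_intensity

  nodule <- matrix(FALSE, H, W)
  nodule_center <- NULL
  if (spec$class_label != "normal") {
    reach <- spec$nodule_radius + spec$irregularity
    if (reach >= min(lung_ax))
      stop("nodule (radius + irregularity) does not fit inside a lung",
           call. = FALSE)
    side <- sample(c("left", "right"), 1L)
    ctr <- lung_centers[[side]]
    # place the center so the whole perturbed disk stays inside the ellipse
    shrink_r <- lung_ax[1] - reach
    shrink_c <- lung_ax[2] - reach
    theta <- stats::runif(1, 0, 2 * pi)
    rho <- sqrt(stats::runif(1))
    nodule_center <- c(ctr[1] + rho * shrink_r * sin(theta),
                       ctr[2] + rho * shrink_c * cos(theta))
    phase <- stats::runif(1, 0, 2 * pi)
    dr <- rr - nodule_center[1]
    dc <- cc - nodule_center[2]
    radius_at <- spec$nodule_radius +
      spec$irregularity * sin(5 * atan2(dr, dc) + phase)
    nodule <- sqrt(dr^2 + dc^2) <= radius_at
    nodule <- nodule & lungs
    base[nodule] <- spec$nodule_intensity
  }

  if (spec$noise_sd > 0)
    base <- base + stats::rnorm(H * W, 0, spec$noise_sd)
  px <- pmin(pmax(round(base), 0), spec$levels - 1L)

  bbox_of <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(r0 = min(idx[, 1]), c0 = min(idx[, 2]),
      r1 = max(idx[, 1]), c1 = max(idx[, 2]))
  }
  structure(list(image = image_grid(matrix(px, H, W), levels = spec$levels),
                 label = spec$class_label,
                 lung_mask = binary_mask(lungs),
                 nodule_mask = binary_mask(nodule),
                 body_bbox = bbox_of(body),
                 lung_bbox = bbox_of(lungs),
                 lung_centers = lung_centers,
                 nodule_center = nodule_center,
                 spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s, %d x %d, nodule pixels: %d\n",
              x$label, x$spec$height, x$spec$width, sum(x$nodule_mask)))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom PNG images (plus lung-mask PNGs) and a manifest CSV with
#' columns `file, label, seed, nodule_r, nodule_c, nodule_radius`. Class
#' counts follow `class_mix` up to rounding; per-image seeds are derived from
#' `seed`, so the whole dataset is a pure function of its arguments.
#'
#' @param n number of images (>= 1).
#' @param class_mix proportions for (normal, benign, malignant), summing to 1.
#' @param base_spec a [phantom_spec()] supplying geometry/intensity defaults.
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param write_masks also write `*_lungmask.png` ground-truth masks.
#' @return The manifest as a data frame, invisibly; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n, class_mix = c(1, 1, 1) / 3,
                             base_spec = phantom_spec(), seed = 1L,
                             out_dir, write_masks = TRUE) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-9)
    stop("`class_mix` must be 3 proportions summing to 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  classes <- c("normal", "benign", "malignant")
  counts <- diff(c(0L, round(cumsum(class_mix) * n)))
  labels <- rep(classes, counts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$class_label <- labels[i]
    sp$irregularity <- switch(labels[i], malignant = max(1.5,
      0.02 * min(sp$height, sp$width)), 0)
    sp$seed <- as.integer(seed + i)
    ph <- generate_phantom(sp)
    file <- sprintf("phantom_%04d_%s.png", i, labels[i])
    save_image(ph$image, file.path(out_dir, file))
    if (write_masks)
      save_image(image_grid(mask_values(ph$lung_mask) * 255L),
                 file.path(out_dir, sub("\\.png$", "_lungmask.png", file)))
    rows[[i]] <- data.frame(
      file = file, label = labels[i], seed = sp$seed,
      nodule_r = if (is.null(ph$nodule_center)) NA_real_
                 else ph$nodule_center[1],
      nodule_c = if (is.null(ph$nodule_center)) NA_real_
                 else ph$nodule_center[2],
      nodule_radius = if (labels[i] == "normal") NA_real_
                      else sp$nodule_radius)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
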