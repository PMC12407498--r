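spec_invariants_ok <- function(spec, H, W) {
  ok <- spec$Sa1$h == spec$Sa2$h && spec$Sa1$w == spec$Sa2$w
  ok <- ok && rpswap:::rect_disjoint(spec$Sa1, spec$Sa2)
  ok <- ok && rpswap:::rect_within(spec$Sa1, spec$A1)
  ok <- ok && rpswap:::rect_within(spec$Sa2, spec$A2)
  ok <- ok && rpswap:::rect_in_image(spec$Sa1, H, W)
  ok <- ok && rpswap:::rect_in_image(spec$Sa2, H, W)
  ok && rect_area(spec$Sa1) >= 1L
}

test_that("swap regions are congruent, disjoint translates for all configs", {
  for (H in c(4, 5, 17, 100)) for (W in c(4, 9, 100)) {
    for (cf in c("h", "w", "u", "d")) {
      reg <- swap_regions(H, W, cf)
      expect_identical(c(reg$A1$h, reg$A1$w), c(reg$A2$h, reg$A2$w))
      expect_true(rpswap:::rect_disjoint(reg$A1, reg$A2))
      expect_true(rpswap:::rect_in_image(reg$A1, H, W))
      expect_true(rpswap:::rect_in_image(reg$A2, H, W))
    }
  }
  expect_error(swap_regions(3, 10, "h"), "at least 4 x 4")
})

test_that("scale_patch shrinks about the center with area ratio near sf", {
  r <- patch_rect(1, 1, 10, 10)
  expect_identical(scale_patch(r, 1.0), r)
  q <- scale_patch(r, 0.25)
  expect_identical(c(q$h, q$w), c(5L, 5L))
  expect_identical(c(q$r0, q$c0), c(3L, 3L))   # centered in the original
  expect_error(scale_patch(r, 0.05), "0.1")
  expect_error(scale_patch(r, 1.5), "0.1")

  set.seed(21)
  for (i in 1:200) {
    rect <- patch_rect(sample(1:20, 1), sample(1:20, 1),
                       sample(1:30, 1), sample(1:30, 1))
    for (sf in seq(0.1, 1.0, by = 0.1)) {
      out <- scale_patch(rect, sf)
      expect_true(rpswap:::rect_within(out, rect))
      slack <- 2 * (2 * (rect$h + rect$w)) / rect_area(rect)
      ratio <- rect_area(out) / rect_area(rect)
      expect_gte(ratio, sf - slack)
      expect_lte(ratio, sf + slack)
    }
  }
})

test_that("area ratio is monotone nondecreasing in sf for fixed anchors", {
  rect <- patch_rect(3, 5, 17, 23)
  areas <- vapply(seq(0.1, 1.0, by = 0.1),
                  function(sf) rect_area(scale_patch(rect, sf)), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("single-point anchors in a 4x4 image give the minimal legal swap", {
  # with Pi = Pj forced to the region origin, As1 is a legal 1x1 patch and
  # the vertical config translates it by half the height
  found <- FALSE
  for (s in 1:200) {
    set.seed(s)
    spec <- sample_swap_spec(4, 4, "h", svsf(1.0))
    if (all(spec$Pi == c(1, 1)) && all(spec$Pj == c(1, 1))) {
      expect_identical(spec$Sa1, patch_rect(1, 1, 1, 1))
      expect_identical(spec$Sa2, patch_rect(3, 1, 1, 1))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("sampled swap specs always satisfy the geometric invariants", {
  set.seed(22)
  for (i in 1:2000) {
    H <- sample(4:64, 1); W <- sample(4:64, 1)
    cf <- sample(c("h", "w", "u", "d", "random"), 1)
    pol <- if (runif(1) < 0.5) svsf(sample(1:10, 1) / 10) else mvsf(0.1, 1.0)
    spec <- sample_swap_spec(H, W, cf, pol)
    expect_true(spec_invariants_ok(spec, H, W))
    expect_true(spec$config %in% c("h", "w", "u", "d"))
    expect_gte(spec$sf, 0.1)
    expect_lte(spec$sf, 1.0)
  }
})

test_that("with Sf = 1 the swap rectangle equals the sub-swap rectangle", {
  set.seed(23)
  for (i in 1:50) {
    spec <- sample_swap_spec(100, 100, "w", svsf(1.0))
    expect_identical(rect_area(spec$Sa1), rect_area(spec$As1))
    expect_identical(spec$Sa1, spec$As1)
  }
})

test_that("MVSF draws stay in bounds; SVSF uses exactly its value", {
  set.seed(24)
  draws <- replicate(300, sample_swap_spec(16, 16, "h", mvsf(0.3, 0.6))$sf)
  expect_true(all(draws >= 0.3 & draws <= 0.6))
  expect_gt(length(unique(draws)), 100)   # genuinely multi-valued
  svs <- replicate(20, sample_swap_spec(16, 16, "h", svsf(0.4))$sf)
  expect_true(all(svs == 0.4))
  expect_error(mvsf(0.6, 0.3), "lo <= hi")
  expect_error(svsf(0.05), "0.1")
})

test_that("apply_swap exchanges exactly the two blocks", {
  img <- image_grid(matrix(0:15, 4, 4, byrow = TRUE))
  spec <- sample_swap_spec(4, 4, "w", svsf(1.0))
  spec$Sa1 <- patch_rect(2, 1, 2, 2)
  spec$Sa2 <- patch_rect(2, 3, 2, 2)
  out <- apply_swap(img, spec)
  expected <- rbind(c(0L, 1L, 2L, 3L),
                    c(6L, 7L, 4L, 5L),
                    c(10L, 11L, 8L, 9L),
                    c(12L, 13L, 14L, 15L))
  expect_identical(as.matrix(out), expected)
})

test_that("apply_swap is an involution, local, and a no-op on constants", {
  set.seed(25)
  for (i in 1:100) {
    H <- sample(4:40, 1); W <- sample(4:40, 1)
    img <- random_image(H, W, channels = sample(c(1, 3), 1))
    spec <- sample_swap_spec(H, W, "random", mvsf(0.1, 1.0))
    once <- apply_swap(img, spec)
    expect_identical(pix(apply_swap(once, spec)), pix(img))
    # locality: outside Sa1 and Sa2 nothing changes
    changed <- which(pix(once) != pix(img), arr.ind = TRUE)
    if (nrow(changed)) {
      in_rect <- function(r, c, rect)
        r >= rect$r0 & r < rect$r0 + rect$h &
        c >= rect$c0 & c < rect$c0 + rect$w
      expect_true(all(in_rect(changed[, 1], changed[, 2], spec$Sa1) |
                      in_rect(changed[, 1], changed[, 2], spec$Sa2)))
    }
  }
  const <- image_grid(matrix(7L, 8, 8))
  spec <- sample_swap_spec(8, 8, "u", svsf(1.0))
  expect_identical(pix(apply_swap(const, spec)), pix(const))
  # out-of-bounds spec rejected
  big <- sample_swap_spec(64, 64, "h", svsf(1.0))
  expect_error(apply_swap(image_grid(matrix(0L, 4, 5)), big), "outside")
})

test_that("rps preserves histogram, intensity and shape; labels untouched", {
  set.seed(26)
  img <- random_image(128, 128)
  out <- rps(img, policy = svsf(1.0), prob = 1.0)
  expect_identical(hist_counts(out), hist_counts(img))
  expect_identical(global_intensity(out), global_intensity(img))
  expect_identical(dim(out), dim(img))
  # multichannel: channels move together, so per-channel histograms hold too
  set.seed(27)
  rgb <- random_image(32, 32, channels = 3)
  out3 <- rps(rgb)
  expect_identical(intensity_histogram(out3, per_channel = TRUE)$counts,
                   intensity_histogram(rgb, per_channel = TRUE)$counts)
})

test_that("rps gating, determinism and effectiveness", {
  set.seed(28)
  img <- random_image(16, 16)
  expect_identical(pix(rps(img, prob = 0)), pix(img))

  set.seed(301); a <- rps(img)
  set.seed(301); b <- rps(img)
  expect_identical(pix(a), pix(b))

  # an all-distinct image must change in at least 2 pixels at prob = 1
  d <- distinct_image(8, 8)
  set.seed(29)
  for (i in 1:20) {
    out <- rps(d, policy = mvsf(0.1, 1.0))
    expect_gte(sum(pix(out) != pix(d)), 2)
  }
})

test_that("the transform-callable contract composes techniques", {
  set.seed(30)
  img <- random_image(16, 16)
  chain <- function(x) augmenter("hflip")(augmenter("rps", config = "w")(x))
  out <- chain(img)
  expect_identical(hist_counts(out), hist_counts(img))
  expect_identical(pix(augmenter("none")(img)), pix(img))
})
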