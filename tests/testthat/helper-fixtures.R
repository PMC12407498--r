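# Fixture builders shared by the test files. All randomness is drawn from the
# global RNG, so each test seeds explicitly.

random_image <- function(h = 16, w = h, channels = 1, levels = 256) {
  image_grid(array(sample.int(levels, h * w * channels, replace = TRUE) - 1L,
                   dim = c(h, w, channels)),
             levels = levels)
}

# image whose pixel values are all distinct (up to L-1 pixels)
distinct_image <- function(h = 8, w = 8) {
  stopifnot(h * w <= 256)
  image_grid(matrix(seq_len(h * w) - 1L, h, w, byrow = TRUE))
}

pix <- function(img) {
  a <- unclass(img)
  attributes(a) <- list(dim = dim(a))
  a
}

hist_counts <- function(img) intensity_histogram(img)$counts

small_results_table <- function() {
  results_table(data.frame(
    technique = rep(c("Base model", "A", "B"), each = 2),
    model = rep(c("m1", "m2"), 3),
    accuracy = c(80, 82, 90, 95, 85, 88),
    auroc = c(81, 83, 91, 96, 86, 89)))
}
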