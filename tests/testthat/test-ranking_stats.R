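test_that("results_table validates the technique x model grid", {
  expect_s3_class(small_results_table(), "results_table")
  expect_error(results_table(data.frame(technique = "A", model = "m")),
               "missing columns")
  dup <- data.frame(technique = c("A", "A"), model = c("m", "m"),
                    accuracy = c(1, 2), auroc = c(3, 4))
  expect_error(results_table(dup), "exactly one row")
  bad <- data.frame(technique = "A", model = "m", accuracy = 120, auroc = 50)
  expect_error(results_table(bad), "\\[0, 100\\]")
})

test_that("cumulative scores sum accuracy + AUROC over models exactly", {
  one <- results_table(data.frame(technique = "X", model = "m",
                                  accuracy = 90, auroc = 95))
  expect_equal(cumulative_scores(one), c(X = 185))

  zero <- results_table(data.frame(technique = c("X", "Y"), model = "m",
                                   accuracy = 0, auroc = 0))
  expect_equal(unname(cumulative_scores(zero)), c(0, 0))

  # the published four-model row for the pixel-swap technique sums to 697.78
  t1 <- benchmark_table("iqothnccd_224")
  C <- cumulative_scores(t1)
  expect_identical(unname(C["Random Pixel Swap"]), 697.78)
})

test_that("score accumulation is linear in a constant metric shift", {
  tb <- small_results_table()
  C0 <- cumulative_scores(tb)
  shifted <- tb
  shifted$accuracy[shifted$technique == "A"] <-
    shifted$accuracy[shifted$technique == "A"] + 2
  shifted$auroc[shifted$technique == "A"] <-
    shifted$auroc[shifted$technique == "A"] + 2
  C1 <- cumulative_scores(results_table(shifted))
  expect_equal(C1["A"] - C0["A"], c(A = 2 * 2 * 2))  # n_models * 2 metrics * c
  expect_equal(C1["B"], C0["B"])
  expect_equal(C1["Base model"], C0["Base model"])
})

test_that("ranking is order-invariant and handles ties deterministically", {
  tb <- small_results_table()
  r1 <- rank_techniques(tb)
  shuffled <- results_table(tb[c(5, 2, 6, 1, 4, 3), ])
  r2 <- rank_techniques(shuffled)
  expect_identical(r1, r2)
  expect_identical(r1$rank, seq_len(3L))
  expect_identical(r1$technique[1], "A")

  tie <- results_table(data.frame(technique = c("Zed", "Abe"), model = "m",
                                  accuracy = c(90, 90), auroc = c(95, 95)))
  expect_warning(rt <- rank_techniques(tie), "tied")
  expect_identical(rt$rank, c(1L, 1L))
  expect_identical(rt$technique, c("Abe", "Zed"))  # lexicographic listing
})

test_that("include_base drops the unaugmented row before ranking", {
  tb <- small_results_table()
  with_base <- rank_techniques(tb, include_base = TRUE)
  without <- rank_techniques(tb, include_base = FALSE)
  expect_true("Base model" %in% with_base$technique)
  expect_false("Base model" %in% without$technique)
  expect_identical(nrow(without), 2L)
})

test_that("near-tie scores rank exactly at two-decimal precision", {
  # 0.01 percent-point gaps must never be lost to binary floating error
  tb <- results_table(data.frame(
    technique = c("P", "Q"), model = "m",
    accuracy = c(73.17, 73.18), auroc = c(74.64, 74.63)))
  expect_warning(r <- rank_techniques(tb), "tied")
  expect_identical(r$rank, c(1L, 1L))
  tb2 <- results_table(data.frame(
    technique = c("P", "Q"), model = "m",
    accuracy = c(73.17, 73.18), auroc = c(74.64, 74.64)))
  r2 <- rank_techniques(tb2)
  expect_identical(r2$technique[r2$rank == 1L], "Q")
})

test_that("paired t test matches its closed form and is antisymmetric", {
  res <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$statistic, -2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(res$statistic, 4), -3.4641)
  expect_identical(res$df, 2L)
  expect_equal(res$p.value, 2 * pt(-abs(res$statistic), 2), tolerance = 1e-15)

  swapped <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p.value, res$p.value)

  same <- paired_t_test(c(3, 1, 4), c(3, 1, 4))
  expect_true(same$degenerate)
  expect_identical(same$p.value, 1)
  shiftd <- paired_t_test(c(4, 2, 5), c(3, 1, 4))
  expect_true(shiftd$degenerate)
  expect_identical(shiftd$p.value, 0)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("paired t test agrees with stats::t.test on seeded random pairs", {
  set.seed(71)
  for (i in 1:1000) {
    k <- sample(3:12, 1)
    x <- rnorm(k, 80, 10)
    y <- x + rnorm(k, 0.5, 2)
    mine <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    expect_identical(mine$df, as.integer(ref$parameter))
  }
})

test_that("compare_techniques pairs per-model metrics from a table", {
  tb <- benchmark_table("iqothnccd_224")
  res <- compare_techniques(tb, "Random Pixel Swap", "Cutout", metric = "acc")
  rows_a <- tb[tb$technique == "Random Pixel Swap", ]
  rows_b <- tb[tb$technique == "Cutout", ]
  ref <- t.test(rows_a$accuracy[order(rows_a$model)],
                rows_b$accuracy[order(rows_b$model)], paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_error(compare_techniques(tb, "Nope", "Cutout"), "not in table")
})

test_that("read_results_csv round-trips the bundled dialect", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "r.csv")
  write.csv(as.data.frame(small_results_table()), f, row.names = FALSE)
  back <- read_results_csv(f)
  expect_equal(cumulative_scores(back), cumulative_scores(small_results_table()))
  expect_error(read_results_csv(file.path(dir, "missing.csv")), "not found")
})
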