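#' Results table of accuracy and AUROC per technique and model
#'
#' A complete technique x model grid of accuracy and AUROC percentages, the
#' input to cumulative-score ranking. Every (technique, model) pair must have
#' both metrics, each in `[0, 100]`.
#'
#' @param df data frame with columns `technique`, `model`, `accuracy`,
#'   `auroc` (percent, up to 2 decimals).
#' @return A `results_table` (a validated data frame).
#' @export
results_table <- function(df) {
  req <- c("technique", "model", "accuracy", "auroc")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[req]
  if (anyNA(df)) stop("results table contains missing values", call. = FALSE)
  if (any(df$accuracy < 0 | df$accuracy > 100 |
          df$auroc < 0 | df$auroc > 100))
    stop("metrics must be percentages in [0, 100]", call. = FALSE)
  grid <- table(df$technique, df$model)
  if (any(grid != 1L)) {
    bad <- which(grid != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf("cell (%s, %s) occurs %d times; need exactly one row per pair",
                 rownames(grid)[bad[1]], colnames(grid)[bad[2]],
                 grid[bad[1], bad[2]]), call. = FALSE)
  }
  class(df) <- c("results_table", "data.frame")
  df
}

#' Read a results CSV
#'
#' Expects the dialect `technique,model,accuracy,auroc` with percentages as
#' decimals with up to two fraction digits.
#'
#' @param path CSV file path.
#' @return A [results_table()].
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  results_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled augmentation benchmark tables
#'
#' Published accuracy/AUROC grids of four networks (ResNet-34, MobileNetV3,
#' Vision Transformer, Swin Transformer) trained on two public chest-CT
#' collections under six conditions (no augmentation plus five augmentation
#' techniques). Shipped with the package as plain CSV so the cumulative-score
#' ranking can be reproduced without any model training.
#'
#' @param name one of `"iqothnccd_224"` (four models, 224px),
#'   `"iqothnccd_512"` (two CNNs, 512px), `"chestct_512"` (two CNNs, 512px),
#'   `"crossdataset_224"` (train/validate on different collections, four
#'   models).
#' @return A [results_table()].
#' @examples
#' rank_techniques(benchmark_table("iqothnccd_224"), include_base = FALSE)
#' @export
benchmark_table <- function(name = c("iqothnccd_224", "iqothnccd_512",
                                     "chestct_512", "crossdataset_224")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("benchmark_", name, ".csv"),
                      package = "rpswap", mustWork = TRUE)
  read_results_csv(path)
}

# exact decimal accumulation: metrics are printed with two decimals, so sum
# them as scaled integers to keep near-ties exact
scaled_sum <- function(x) sum(as.integer(round(x * 100)))

#' Cumulative scores of augmentation techniques
#'
#' For each technique, the cumulative score is
#' `C = sum over models of (accuracy + AUROC)`, in percent-points.
#' Accumulation is exact at the tables' two-decimal printed precision
#' (scaled-integer arithmetic), so rank comparisons are immune to binary
#' floating error on near-ties.
#'
#' @param table a [results_table()].
#' @return Named numeric vector of scores `C`, one per technique, in the
#'   order of first appearance.
#' @export
cumulative_scores <- function(table) {
  if (!inherits(table, "results_table")) table <- results_table(table)
  techs <- unique(table$technique)
  vapply(techs, function(t) {
    rows <- table[table$technique == t, ]
    scaled_sum(rows$accuracy + rows$auroc) / 100
  }, numeric(1))
}

#' Rank techniques by cumulative score
#'
#' Sorts techniques by cumulative score `C` descending and assigns 1-based
#' ranks (rank 1 = highest `C`). Ties share the smaller rank, are listed in
#' lexicographic technique order, and raise a warning. Published prose
#' rankings usually exclude the unaugmented base model; drop it with
#' `include_base = FALSE`.
#'
#' @param table a [results_table()].
#' @param include_base keep the base-model row in the ranking?
#' @param base name of the base (unaugmented) technique row.
#' @return A `ranking_result` data frame with columns `technique`, `C`,
#'   `rank`.
#' @export
rank_techniques <- function(table, include_base = TRUE, base = "Base model") {
  if (!inherits(table, "results_table")) table <- results_table(table)
  if (!include_base) table <- table[table$technique != base, ]
  if (nrow(table) == 0L) stop("no techniques left to rank", call. = FALSE)
  C <- cumulative_scores(table)
  ord <- order(-C, names(C), method = "radix")
  C <- C[ord]
  rank <- rank(-C, ties.method = "min")
  if (anyDuplicated(rank))
    warning("tied cumulative scores; tied techniques share the smaller rank")
  res <- data.frame(technique = names(C), C = unname(C), rank = unname(rank),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("ranking_result", "data.frame")
  res
}

#' Look up one technique's rank
#'
#' Convenience accessor over [rank_techniques()].
#'
#' @inheritParams rank_techniques
#' @param technique technique name to look up.
#' @return Integer 1-based rank.
#' @export
technique_rank <- function(table, technique, include_base = TRUE,
                           base = "Base model") {
  r <- rank_techniques(table, include_base = include_base, base = base)
  hit <- r$rank[r$technique == technique]
  if (length(hit) != 1L)
    stop("technique not in table: ", technique, call. = FALSE)
  hit
}

#' Paired-sample t test
#'
#' The textbook paired t statistic `t = mean(d) / (sd(d) / sqrt(k))` with
#' `d = x - y`, sample standard deviation (`k - 1` denominator),
#' `df = k - 1`, and a two-sided p value from the t distribution. Degenerate
#' zero-variance differences are flagged: all-zero differences give `p = 1`,
#' constant nonzero differences give `p = 0`.
#'
#' @param x,y paired numeric vectors of equal length `k >= 2`.
#' @return A `paired_t` list: `statistic`, `df`, `p.value`, `mean_diff`,
#'   `degenerate`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 4, 6))  # t = -3.4641, df = 2
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  k <- length(x)
  if (k < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- as.numeric(x) - as.numeric(y)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    res <- list(statistic = if (m == 0) 0 else sign(m) * Inf,
                df = k - 1L, p.value = if (m == 0) 1 else 0,
                mean_diff = m, degenerate = TRUE)
  } else {
    t <- m / (s / sqrt(k))
    res <- list(statistic = t, df = k - 1L,
                p.value = 2 * stats::pt(-abs(t), df = k - 1L),
                mean_diff = m, degenerate = FALSE)
  }
  structure(res, class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t test: t = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p.value,
              if (x$degenerate) " (degenerate: zero-variance differences)"
              else ""))
  invisible(x)
}

#' Paired comparison of two techniques from a results table
#'
#' Pairs the per-model values of a chosen metric for two techniques and runs
#' [paired_t_test()]. The paired quantity can be accuracy, AUROC, or their
#' sum.
#'
#' @param table a [results_table()].
#' @param a,b technique names to compare (`a - b` differences).
#' @param metric `"acc"`, `"auroc"` or `"sum"`.
#' @return A `paired_t` object.
#' @export
compare_techniques <- function(table, a, b, metric = c("sum", "acc", "auroc")) {
  if (!inherits(table, "results_table")) table <- results_table(table)
  metric <- match.arg(metric)
  pick <- function(t) {
    rows <- table[table$technique == t, ]
    if (nrow(rows) == 0L) stop("technique not in table: ", t, call. = FALSE)
    rows <- rows[order(rows$model), ]
    switch(metric, acc = rows$accuracy, auroc = rows$auroc,
           sum = rows$accuracy + rows$auroc)
  }
  paired_t_test(pick(a), pick(b))
}
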