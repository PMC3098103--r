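# Train/test splitting and one-vs-rest sensitivity/specificity benchmarking.

#' Split a labeled dataset into training and test sets
#'
#' Stratified (per subfamily) random split, reproducible given the seed.
#' Per-subfamily training proportions are within one sequence of
#' `train_fraction`.
#'
#' @param dataset a labeled [acs_dataset].
#' @param train_fraction proportion assigned to training (0 < f < 1).
#' @param seed integer seed.
#' @param stratified split per subfamily (default `TRUE`).
#' @return list with `train` and `test` ([acs_dataset]s; disjoint, union =
#'   input).
#' @export
split_dataset <- function(dataset, train_fraction = 0.7, seed = 1,
                          stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(dataset)
  .with_seed(seed, {
    if (stratified) {
      labs <- dataset$label
      if (any(is.na(labs))) stop("stratified split requires labels on every record")
      tab <- table(labs)
      if (any(tab < 2)) {
        stop("subfamily with fewer than 2 members cannot be split: ",
             paste(names(tab)[tab < 2], collapse = ", "))
      }
      train_idx <- integer(0)
      for (f in names(tab)) {
        idx <- which(labs == f)
        k <- round(train_fraction * length(idx))
        k <- min(max(k, 1L), length(idx) - 1L)  # both sides non-empty
        train_idx <- c(train_idx, sample(idx, k))
      }
    } else {
      k <- min(max(round(train_fraction * n), 1L), n - 1L)
      train_idx <- sample(n, k)
    }
    train_idx <- sort(train_idx)
    list(train = dataset[train_idx],
         test = dataset[setdiff(seq_len(n), train_idx)])
  })
}

#' One-vs-rest confusion statistics
#'
#' For each subfamily: TP (true label f, predicted f), FP (other label,
#' predicted f), FN (true f, predicted other), TN (rest); sensitivity
#' `Sn = TP / (TP + FN)` and specificity `Sp = TN / (TN + FP)`.
#' Division by zero yields `NA` (undefined), never 0.
#'
#' @param truth character vector of true subfamily labels.
#' @param predicted character vector of predicted labels (same length).
#' @return data frame of class `confusion_stats`: one row per subfamily with
#'   `TP`, `FP`, `TN`, `FN`, `Sn`, `Sp`; micro-accuracy as attribute
#'   `"accuracy"`.
#' @export
evaluate <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty prediction list")
  stopifnot(length(truth) == length(predicted))
  fams <- sort(unique(c(truth, predicted)))
  rows <- lapply(fams, function(f) {
    tp <- sum(truth == f & predicted == f)
    fp <- sum(truth != f & predicted == f)
    fn <- sum(truth == f & predicted != f)
    tn <- sum(truth != f & predicted != f)
    data.frame(subfamily = f, TP = tp, FP = fp, TN = tn, FN = fn,
               Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "accuracy") <- mean(truth == predicted)
  class(out) <- c("confusion_stats", "data.frame")
  out
}

#' Write a benchmark report
#' @param stats a `confusion_stats` data frame.
#' @param path output path; `.json` writes JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(stats, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_subfamily = as.data.frame(stats),
                              accuracy = attr(stats, "accuracy")),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
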