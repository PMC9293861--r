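# Recovery metrics used to compare calls against planted truth.

#' Macro-averaged F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall, with empty classes
#' contributing 0) averaged over the union of classes present in truth or
#' prediction.
#'
#' @param truth,pred Equal-length label vectors, aligned element-wise.
#' @return Macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  classes <- union(unique(truth), unique(pred))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (1 = identical up to
#' relabelling, ~0 = random).
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Sensitivity and specificity of a binary call
#'
#' @param truth_pos,called_pos Logical vectors: planted positives and called
#'   positives.
#' @return A one-row tibble with `sensitivity` and `specificity`.
#' @export
call_performance <- function(truth_pos, called_pos) {
  stopifnot(length(truth_pos) == length(called_pos))
  tibble::tibble(
    sensitivity = sum(truth_pos & called_pos) / sum(truth_pos),
    specificity = sum(!truth_pos & !called_pos) / sum(!truth_pos)
  )
}
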