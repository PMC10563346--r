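#' Stratified 70/30 dataset split
#'
#' Randomized per-class assignment with floor(frac * class size) rows in the
#' training portion and the remainder held out.
#'
#' @param n_path,n_benign Class sizes.
#' @param frac Training fraction in (0,1), default 0.7.
#' @param seed RNG seed.
#' @return List of class \code{"pdivas_split"}: \code{train}/\code{test}
#'   named count vectors and \code{idx} with the per-class training indices.
#' @export
split_dataset <- function(n_path, n_benign, frac = 0.7, seed = 1) {
  stopifnot(n_path >= 1, n_benign >= 1)
  if (!(frac > 0 && frac < 1)) stop("frac must lie strictly in (0,1)")
  set.seed(seed)
  tp <- sample(n_path, floor(frac * n_path))
  tb <- sample(n_benign, floor(frac * n_benign))
  structure(list(
    train = c(pathogenic = length(tp), benign = length(tb)),
    test = c(pathogenic = n_path - length(tp),
             benign = n_benign - length(tb)),
    idx = list(path_train = sort(tp), benign_train = sort(tb))),
    class = "pdivas_split")
}

#' @export
print.pdivas_split <- function(x, ...) {
  cat(sprintf("train: %d pathogenic / %d benign; test: %d / %d\n",
              x$train["pathogenic"], x$train["benign"],
              x$test["pathogenic"], x$test["benign"]))
  invisible(x)
}

check_two_class <- function(y) {
  if (length(unique(y)) < 2)
    stop("both classes must be present")
  y
}

#' Average precision
#'
#' Step-sum of precision weighted by recall increments over descending-score
#' thresholds (no interpolation): \eqn{\sum_i (R_i - R_{i-1}) P_i}.
#'
#' @param labels Binary labels (1/"pathogenic" = positive).
#' @param scores Numeric scores.
#' @return Average precision in [0,1] (1 for a perfect ranking).
#' @export
average_precision <- function(labels, scores) {
  y <- check_two_class(as_label01(labels))
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y)
  n <- seq_along(y)
  # thresholds at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  P <- tp[last] / n[last]
  R <- tp[last] / sum(y)
  sum(diff(c(0, R)) * P)
}

mcc_from_counts <- function(tp, fp, fn, tn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Maximum Matthews correlation over a threshold grid
#'
#' Sweeps thresholds 0, step, 2*step, ..., 1; a variant is predicted
#' positive when score >= threshold. An MCC with any zero denominator factor
#' is 0. Returns the maximum and the smallest threshold achieving it.
#'
#' @param labels Binary labels.
#' @param scores Numeric scores.
#' @param step Threshold increment (default 0.001).
#' @return List with \code{threshold} and \code{mcc}.
#' @export
max_mcc <- function(labels, scores, step = 0.001) {
  y <- check_two_class(as_label01(labels))
  ts <- seq.int(0L, round(1 / step)) * step
  np <- sum(y == 1); nn <- sum(y == 0)
  sp <- scores[y == 1]; sn <- scores[y == 0]
  best <- -Inf; best_t <- 0
  for (t in ts) {
    tp <- sum(sp >= t); fp <- sum(sn >= t)
    m <- mcc_from_counts(tp, fp, np - tp, nn - fp)
    # float-equal MCCs from different confusion matrices keep the smaller t
    if (m > best + 1e-12) { best <- m; best_t <- t }
  }
  list(threshold = best_t, mcc = best)
}

#' Min-max normalization to [0,1]
#'
#' Rank-preserving rescale \code{(s - min) / (max - min)} used to place
#' comparator predictors on a common score axis.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Rescaled scores in [0,1].
#' @export
min_max_normalize <- function(scores) {
  rng <- range(scores)
  if (rng[1] == rng[2]) stop("cannot min-max normalize a constant vector")
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Score threshold achieving a target sensitivity
#'
#' The largest threshold t such that the fraction of pathogenic scores >= t
#' is at least level/100: the score of the ceil(level/100 * n)-th ranked
#' pathogenic variant from the top. The realized sensitivity at the returned
#' threshold is never below the requested level.
#'
#' @param path_scores Scores of known pathogenic variants.
#' @param level Sensitivity level in percent, in (0, 100].
#' @return Threshold score.
#' @export
threshold_for_sensitivity <- function(path_scores, level) {
  stopifnot(length(path_scores) >= 1)
  if (!(level > 0 && level <= 100)) stop("level must lie in (0, 100]")
  k <- ceiling(level / 100 * length(path_scores))
  sort(path_scores, decreasing = TRUE)[k]
}

#' Sensitivity-calibrated threshold table
#'
#' @param path_scores Scores of pathogenic variants in the test set.
#' @param levels Sensitivity levels in percent (default 60..95 by 5).
#' @return data.frame with columns \code{sensitivity} and \code{threshold}
#'   (thresholds non-increasing in sensitivity).
#' @export
threshold_table <- function(path_scores, levels = seq(60, 95, by = 5)) {
  data.frame(sensitivity = levels,
             threshold = vapply(levels, function(l)
               threshold_for_sensitivity(path_scores, l), 0.0))
}

#' Precision-recall and MCC curves over a threshold grid
#'
#' @param labels Binary labels.
#' @param scores Numeric scores.
#' @param step Threshold increment.
#' @return data.frame of class \code{"pdivas_eval"} with columns
#'   \code{threshold}, \code{precision}, \code{recall}, \code{mcc};
#'   attributes \code{ap}, \code{max_mcc}, \code{mcc_threshold}.
#' @export
eval_curves <- function(labels, scores, step = 0.001) {
  y <- check_two_class(as_label01(labels))
  ts <- seq.int(0L, round(1 / step)) * step
  np <- sum(y == 1); nn <- sum(y == 0)
  prec <- rec <- mcc <- numeric(length(ts))
  sp <- scores[y == 1]; sn <- scores[y == 0]
  for (i in seq_along(ts)) {
    t <- ts[i]
    tp <- sum(sp >= t); fp <- sum(sn >= t)
    prec[i] <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec[i] <- tp / np
    mcc[i] <- mcc_from_counts(tp, fp, np - tp, nn - fp)
  }
  out <- data.frame(threshold = ts, precision = prec, recall = rec,
                    mcc = mcc)
  attr(out, "ap") <- average_precision(y, scores)
  mm <- max_mcc(y, scores, step)
  attr(out, "max_mcc") <- mm$mcc
  attr(out, "mcc_threshold") <- mm$threshold
  class(out) <- c("pdivas_eval", "data.frame")
  out
}

#' @export
print.pdivas_eval <- function(x, ...) {
  cat(sprintf("evaluation over %d thresholds: AP = %.4f, max MCC = %.4f at %.3f\n",
              nrow(x), attr(x, "ap"), attr(x, "max_mcc"),
              attr(x, "mcc_threshold")))
  invisible(x)
}

#' @export
plot.pdivas_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ok <- !is.na(x$precision)
  graphics::plot(x$recall[ok], x$precision[ok], type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
                 main = sprintf("PR curve (AP = %.3f)", attr(x, "ap")))
  graphics::plot(x$threshold, x$mcc, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Score threshold", ylab = "MCC",
                 main = sprintf("MCC curve (max = %.3f)", attr(x, "max_mcc")))
  invisible(x)
}
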