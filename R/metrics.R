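#' Per-class confusion counts between two segmentation masks
#'
#' Tallies, for every class `c` in `0:(num_classes - 1)`, the pixel counts
#' `tp` (predicted `c`, truly `c`), `fp` (predicted `c`, truly other),
#' `fn` (predicted other, truly `c`) and `tn` (the remainder). These counts
#' are the common core from which IoU, precision, recall and Dice derive.
#'
#' @param pred integer mask (any shape) of predicted class indices, 0-based.
#' @param true integer mask of the same shape with the reference classes.
#' @param num_classes number of classes including background (class 0).
#' @return an object of class `confusion_counts`: a list with numeric vectors
#'   `tp`, `fp`, `fn`, `tn` (one entry per class, named `class0`, `class1`,
#'   ...), the class count and the total pixel count.
#' @examples
#' confusion_counts(matrix(c(0, 1, 1, 1), 2), matrix(c(0, 0, 1, 1), 2), 2)
#' @export
confusion_counts <- function(pred, true, num_classes) {
  pred <- as.vector(pred); true <- as.vector(true)
  if (length(pred) != length(true))
    stop("`pred` and `true` must have the same shape")
  if (num_classes < 2) stop("`num_classes` must be at least 2")
  pv <- as.integer(pred); tv <- as.integer(true)
  if (any(pv < 0L | pv >= num_classes) || any(tv < 0L | tv >= num_classes))
    stop("mask values must lie in [0, num_classes)")
  cm <- matrix(tabulate(tv * num_classes + pv + 1L, nbins = num_classes^2),
               num_classes, num_classes)  # cm[p+1, t+1]
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  total <- length(pv)
  nm <- paste0("class", seq_len(num_classes) - 1L)
  structure(list(tp = stats::setNames(tp, nm), fp = stats::setNames(fp, nm),
                 fn = stats::setNames(fn, nm),
                 tn = stats::setNames(total - tp - fp - fn, nm),
                 num_classes = num_classes, total = total),
            class = "confusion_counts")
}

check_counts <- function(counts, class) {
  if (!inherits(counts, "confusion_counts")) stop("not a confusion_counts object")
  if (class < 0 || class >= counts$num_classes) stop("class out of range")
  i <- class + 1L
  list(tp = counts$tp[[i]], fp = counts$fp[[i]], fn = counts$fn[[i]])
}

## Empty-denominator convention: a class absent from both masks
## (tp = fp = fn = 0) scores 1; a zero denominator otherwise scores 0.
safe_ratio <- function(num, den, absent) {
  if (absent) return(1)
  if (den == 0) return(0)
  num / den
}

#' Intersection over union for one class
#'
#' `tp / (tp + fp + fn)`. A class absent from both masks scores 1; any other
#' empty denominator scores 0 (never `NaN`).
#' @param counts a [confusion_counts()] object.
#' @param class 0-based class index.
#' @return a ratio in `[0, 1]`.
#' @export
iou <- function(counts, class) {
  k <- check_counts(counts, class)
  safe_ratio(k$tp, k$tp + k$fp + k$fn, k$tp + k$fp + k$fn == 0)
}

#' Precision for one class
#'
#' `tp / (tp + fp)`, the proportion of pixels predicted as the class that
#' truly belong to it.
#' @inheritParams iou
#' @return a ratio in `[0, 1]`.
#' @export
precision <- function(counts, class) {
  k <- check_counts(counts, class)
  safe_ratio(k$tp, k$tp + k$fp, k$tp + k$fp + k$fn == 0)
}

#' Recall (sensitivity) for one class
#'
#' `tp / (tp + fn)`, the proportion of true class pixels that were found.
#' @inheritParams iou
#' @return a ratio in `[0, 1]`.
#' @export
recall <- function(counts, class) {
  k <- check_counts(counts, class)
  safe_ratio(k$tp, k$tp + k$fn, k$tp + k$fp + k$fn == 0)
}

#' Dice overlap coefficient for one class
#'
#' `2 tp / (2 tp + fp + fn)`; algebraically `2 IoU / (1 + IoU)`.
#' @inheritParams iou
#' @return a ratio in `[0, 1]`.
#' @export
dice <- function(counts, class) {
  k <- check_counts(counts, class)
  safe_ratio(2 * k$tp, 2 * k$tp + k$fp + k$fn, k$tp + k$fp + k$fn == 0)
}

#' F1 score: harmonic mean of (macro) precision and recall
#'
#' The network's headline F1 is computed from the macro-averaged precision
#' and recall, `2 P R / (P + R)`. For a single foreground class this equals
#' that class's Dice coefficient; over macro means the two differ, and both
#' are reported by [metrics_report()].
#'
#' @param precision,recall values in `[0, 1]`, not both 0.
#' @return the harmonic mean.
#' @examples
#' f1_score(0.9738, 0.9693)
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Full evaluation report from confusion counts
#'
#' Per-class IoU, precision, recall and Dice, plus the macro means `mIoU`,
#' `mPrecision`, `mRecall` (over all classes, background included), the F1
#' score as the harmonic mean of the macro precision/recall, and the Dice
#' score averaged over foreground classes only.
#'
#' @param counts a [confusion_counts()] object.
#' @return an object of class `metrics_report` (a list; see Details), with
#'   `print` and `as.data.frame` methods producing the conventional
#'   mIoU/mPrecision/mRecall/F1-score/Dice-score layout.
#' @export
metrics_report <- function(counts) {
  nc <- counts$num_classes
  cls <- seq_len(nc) - 1L
  per <- data.frame(
    class = cls,
    iou = vapply(cls, function(c) iou(counts, c), 0),
    precision = vapply(cls, function(c) precision(counts, c), 0),
    recall = vapply(cls, function(c) recall(counts, c), 0),
    dice = vapply(cls, function(c) dice(counts, c), 0)
  )
  mp <- mean(per$precision); mr <- mean(per$recall)
  structure(list(
    per_class = per,
    miou = mean(per$iou),
    mprecision = mp,
    mrecall = mr,
    f1 = f1_score(mp, mr),
    dice_score = mean(per$dice[per$class > 0]),
    num_classes = nc
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Segmentation metrics (", x$num_classes, " classes)\n", sep = "")
  print(round(as.data.frame(x), digits), row.names = FALSE)
  cat("Per class:\n")
  print(round(x$per_class, digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(mIoU = x$miou, mPrecision = x$mprecision, mRecall = x$mrecall,
             F1.score = x$f1, Dice.score = x$dice_score)
}

#' Focal loss settings
#'
#' @param alpha class-balance weight in `[0, 1]` given to the foreground
#'   (`y = 1`) term; background is weighted `1 - alpha`. Default 0.5.
#' @param gamma focusing exponent (>= 0) that down-weights well-classified
#'   pixels. Default 2.
#' @return a list with class `focal_loss_params`.
#' @export
focal_loss_params <- function(alpha = 0.5, gamma = 2) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (gamma < 0) stop("`gamma` must be nonnegative")
  structure(list(alpha = alpha, gamma = gamma), class = "focal_loss_params")
}

#' Focal loss
#'
#' Mean over pixels of `-alpha (1 - p)^gamma log p` where the target is 1 and
#' `-(1 - alpha) p^gamma log(1 - p)` where it is 0. At `gamma = 0` this is
#' alpha-weighted cross-entropy. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' For more than two classes pass `prob` with one trailing class dimension
#' (e.g. `H x W x C`) and integer targets in `0:(C-1)`; the loss is then
#' `-alpha_c (1 - p_t)^gamma log p_t` on the true-class probability with the
#' per-class weight vector `c(1 - alpha, alpha, alpha, ...)`.
#'
#' @param prob predicted probability of the positive class, same shape as
#'   `target`; or an array with a trailing class dimension (multi-class).
#' @param target 0/1 (binary) or 0-based class indices (multi-class).
#' @param params a [focal_loss_params()] object.
#' @return a nonnegative scalar.
#' @examples
#' focal_loss(0.5, 1)                      # 0.5 * 0.25 * log(2)
#' focal_loss(c(0.9, 0.2), c(1, 0))
#' @export
focal_loss <- function(prob, target, params = focal_loss_params()) {
  stopifnot(inherits(params, "focal_loss_params"))
  eps <- 1e-7
  a <- params$alpha; g <- params$gamma
  if (length(prob) == length(target)) {
    tv <- as.vector(target)
    if (!all(tv %in% c(0, 1))) stop("binary targets must be 0 or 1")
    p <- pmin(pmax(as.vector(prob), eps), 1 - eps)
    li <- ifelse(tv == 1, -a * (1 - p)^g * log(p),
                 -(1 - a) * p^g * log(1 - p))
    return(mean(li))
  }
  dm <- dim(prob)
  C <- dm[length(dm)]
  if (length(prob) != length(target) * C)
    stop("`prob` must match `target`, or add one trailing class dimension")
  pm <- matrix(prob, ncol = C)
  tv <- as.integer(target) + 1L
  if (any(tv < 1L | tv > C)) stop("targets out of class range")
  alpha_vec <- c(1 - a, rep(a, C - 1))
  pt <- pmin(pmax(pm[cbind(seq_along(tv), tv)], eps), 1 - eps)
  mean(-alpha_vec[tv] * (1 - pt)^g * log(pt))
}
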