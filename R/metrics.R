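# Pixel-wise evaluation: binarization, confusion counts (vessel = positive
# class), and the standard segmentation metrics. Counts are pooled over all
# evaluated pixels of a split (micro-aggregation) before ratios are formed.

#' Threshold a probability map into a binary mask
#'
#' @param p probability map.
#' @param threshold decision threshold in `(0, 1)`; ties (`p == threshold`)
#'   go to foreground.
#' @return 0/1 mask of the same shape.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  out <- p
  out[] <- as.numeric(p >= threshold)
  out
}

#' Confusion counts between a predicted and a reference mask
#'
#' @param pred,gt 0/1 masks of identical shape.
#' @return a `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, gt) {
  check_same_shape(pred, gt, "prediction and ground truth")
  check_binary(pred, "pred"); check_binary(gt, "gt")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "confusion_counts")
}

# elementwise sum of confusion counts, for micro-aggregation over a split
add_confusion <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp,
                 tn = a$tn + b$tn, fn = a$fn + b$fn),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' ACC, SEN (recall), SPE, F1 and IoU on the 0-1 scale. A ratio with a zero
#' denominator is reported as `NA`, never silently as 0.
#'
#' @param c a `confusion_counts` object (or list with tp/fp/tn/fn).
#' @param percent multiply by 100 for reporting.
#' @return named numeric vector `ACC`, `SEN`, `SPE`, `F1`, `IOU`.
#' @export
compute_metrics <- function(c, percent = FALSE) {
  n <- c$tp + c$fp + c$tn + c$fn
  if (n == 0) stop("confusion counts are all zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- c(ACC = ratio(c$tp + c$tn, n),
         SEN = ratio(c$tp, c$tp + c$fn),
         SPE = ratio(c$tn, c$tn + c$fp),
         F1 = ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn),
         IOU = ratio(c$tp, c$tp + c$fp + c$fn))
  if (percent) m * 100 else m
}

#' Evaluate a model over a dataset split
#'
#' Pads each image, runs inference, crops back, binarizes at the threshold
#' and pools confusion counts over every pixel of the split.
#'
#' @param net a `unet`.
#' @param samples list of samples (elements `image` and a target mask).
#' @param target which mask to score against (`"gt"`, `"thin"`, `"thick"`).
#' @param spec padding passed to [pad_to_spec()].
#' @param threshold binarization threshold.
#' @return list with pooled `metrics`, pooled `counts`, and a `per_image`
#'   data.frame.
#' @export
evaluate_set <- function(net, samples, target = "gt", spec = "auto16",
                         threshold = 0.5) {
  if (length(samples) == 0) stop("empty split", call. = FALSE)
  pooled <- structure(list(tp = 0, fp = 0, tn = 0, fn = 0),
                      class = "confusion_counts")
  rows <- list()
  for (smp in samples) {
    y <- smp[[target]]
    if (is.null(y)) stop(sprintf("sample %s has no '%s' mask", smp$id, target),
                         call. = FALSE)
    pad <- pad_to_spec(smp$image, spec)
    z <- unet_forward(net, pad$image)
    z <- unpad(z[, , 1], pad)
    pred <- binarize(sigmoid(z), threshold)
    cc <- confusion(pred, y)
    pooled <- add_confusion(pooled, cc)
    rows[[length(rows) + 1]] <- data.frame(
      id = smp$id, t(compute_metrics(cc)))
  }
  list(metrics = compute_metrics(pooled), counts = pooled,
       per_image = do.call(rbind, rows))
}
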