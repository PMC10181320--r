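# Composite segmentation loss: a class-weighted cross entropy on both heads
# plus a Lovasz-softmax term on the voxel head, and the IoU/mIoU metrics.

#' Inverse-frequency class weights
#'
#' Weight of class k is the reciprocal of its frequency in the training
#' labels, so under-represented classes (the stem) contribute more to the
#' loss. Classes absent from the labels get weight 0 and are excluded.
#'
#' @param labels integer 0-based training labels (pooled over the training
#'   set, not per batch, so the loss scale is deterministic).
#' @param num_classes number of classes.
#' @return a `class_weights` list with `weights` and `frequencies`.
#' @export
class_weights <- function(labels, num_classes = 3L) {
  if (length(labels) == 0L) stop("cannot compute class weights of no labels")
  labels <- as.integer(labels)
  stopifnot(all(labels >= 0L & labels < num_classes))
  counts <- tabulate(labels + 1L, nbins = num_classes)
  freq <- counts / length(labels)
  w <- ifelse(freq > 0, 1 / freq, 0)
  structure(list(weights = w, frequencies = freq), class = "class_weights")
}

as_weight_vec <- function(weights, num_classes) {
  if (inherits(weights, "class_weights")) weights$weights
  else if (is.null(weights)) rep(1, num_classes)
  else rep_len(as.numeric(weights), num_classes)
}

#' Class-weighted cross entropy
#'
#' Mean over points of `w[y_i] * (-log softmax(logits)[y_i])`; with unit
#' weights this is the ordinary cross entropy.
#'
#' @param logits N x K matrix.
#' @param labels integer 0-based labels.
#' @param weights a [class_weights()] object, a numeric vector of length K,
#'   or `NULL` for unit weights.
#' @return scalar loss.
#' @export
weighted_ce <- function(logits, labels, weights = NULL) {
  logits <- as.matrix(logits)
  w <- as_weight_vec(weights, ncol(logits))
  ag_weighted_ce(ag_const(logits), as.integer(labels), w)$value[1L, 1L]
}

#' Lovasz-softmax loss
#'
#' The Lovasz extension of the Jaccard loss evaluated on softmax
#' probabilities, averaged over the classes present in `labels`. For hard
#' 0/1 probability rows the per-class value equals `1 - Jaccard` of the
#' predicted vs. true sets.
#'
#' @param probs N x K matrix of rows on the probability simplex.
#' @param labels integer 0-based labels.
#' @return scalar loss in `[0, 1]`.
#' @export
lovasz_softmax <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (max(abs(rowSums(probs) - 1)) > 1e-5 || any(probs < -1e-5))
    stop("probs rows must lie on the probability simplex")
  ag_lovasz_softmax(ag_const(probs), as.integer(labels))$value[1L, 1L]
}

#' Composite two-head training loss
#'
#' `Loss = Loss_v + Loss_p` with
#' `Loss_v = weighted_ce(voxel) + lovasz_softmax(softmax(voxel))` and
#' `Loss_p = weighted_ce(point)` — the voxel head gets the IoU surrogate,
#' the point head plain weighted cross entropy.
#'
#' @param voxel_logits,voxel_labels M x K logits and 0-based labels of the
#'   voxel head.
#' @param point_logits,point_labels N x K logits and labels of the point
#'   head.
#' @param weights class weights shared by both heads.
#' @return list with `total`, `loss_v`, `loss_p` (scalars).
#' @export
total_loss <- function(voxel_logits, voxel_labels, point_logits, point_labels,
                       weights = NULL) {
  parts <- total_loss_node(ag_const(as.matrix(voxel_logits)),
                           as.integer(voxel_labels),
                           ag_const(as.matrix(point_logits)),
                           as.integer(point_labels),
                           as_weight_vec(weights, ncol(as.matrix(voxel_logits))))
  lapply(parts[c("total", "loss_v", "loss_p")],
         function(n) n$value[1L, 1L])
}

total_loss_node <- function(voxel_logits, voxel_labels, point_logits,
                            point_labels, w) {
  ce_v <- ag_weighted_ce(voxel_logits, voxel_labels, w)
  lov <- ag_lovasz_softmax(ag_softmax_rows(voxel_logits), voxel_labels)
  loss_v <- ag_add(ce_v, lov)
  loss_p <- ag_weighted_ce(point_logits, point_labels, w)
  list(total = ag_add(loss_v, loss_p), loss_v = loss_v, loss_p = loss_p)
}

#' Confusion matrix, per-class IoU and mIoU
#'
#' `IoU_k = TP_k / (TP_k + FN_k + FP_k)`; mIoU is the arithmetic mean over
#' all K classes. A class absent from both truth and prediction scores a
#' vacuous IoU of 1; absent from truth but predicted scores 0.
#'
#' @param pred_labels,true_labels equal-length integer 0-based label vectors.
#' @param num_classes number of classes K.
#' @param class_names optional names for printing.
#' @return a `segmentation_report` with `confusion` (rows = truth),
#'   `per_class_iou` and `miou`.
#' @export
evaluate_segmentation <- function(pred_labels, true_labels, num_classes = 3L,
                                  class_names = NULL) {
  pred_labels <- as.integer(pred_labels)
  true_labels <- as.integer(true_labels)
  if (length(pred_labels) != length(true_labels))
    stop("prediction and truth must have equal length")
  stopifnot(all(pred_labels >= 0L & pred_labels < num_classes),
            all(true_labels >= 0L & true_labels < num_classes))
  conf <- matrix(tabulate(true_labels * num_classes + pred_labels + 1L,
                          nbins = num_classes * num_classes),
                 num_classes, num_classes, byrow = TRUE)
  if (is.null(class_names))
    class_names <- if (num_classes == 3L) semantic_classes()
                   else paste0("class", seq_len(num_classes) - 1L)
  dimnames(conf) <- list(truth = class_names, prediction = class_names)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  denom <- tp + fn + fp
  iou <- ifelse(denom > 0, tp / denom, 1)   # vacuous class convention
  structure(list(confusion = conf,
                 per_class_iou = stats::setNames(iou, class_names),
                 miou = mean(iou)),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("mIoU %6.2f | %s\n", 100 * x$miou,
              paste(sprintf("%s %6.2f", names(x$per_class_iou),
                            100 * x$per_class_iou), collapse = " | ")))
  invisible(x)
}

#' Serialise a report as a one-row data frame (percentages)
#'
#' Column order: mIoU, then the classes in their fixed order, as percentages
#' with two decimals.
#'
#' @param report a `segmentation_report`.
#' @return a `data.frame`.
#' @export
report_table <- function(report) {
  v <- round(100 * c(mIoU = report$miou, report$per_class_iou), 2L)
  as.data.frame(as.list(v), check.names = FALSE)
}
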