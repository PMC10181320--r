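# Training, evaluation, cross-validation and prediction drivers. Batches are
# lists of whole clouds (no down-sampling); gradients are averaged over the
# batch and applied with Adam at a constant learning rate. Everything is
# deterministic under a fixed seed in single-threaded mode.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 10) {
  gnorm2 <- 0
  for (p in params) if (!is.null(p$grad)) gnorm2 <- gnorm2 + sum(p$grad^2)
  scale <- if (clip_norm > 0 && sqrt(gnorm2) > clip_norm)
    clip_norm / sqrt(gnorm2) else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- if (is.null(p$grad)) p$value * 0 else p$grad * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    p$value <- p$value -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}

# one forward/backward on a cloud; returns loss parts and train confusion
ffnet_step_graph <- function(model, cloud, geometry, wvec) {
  fw <- ffnet_forward(model, cloud, keep_graph = TRUE, geometry = geometry)
  vl <- voxel_labels(cloud$labels, fw$assignment, model$config$num_classes)
  parts <- total_loss_node(fw$voxel_logits_node, vl,
                           fw$point_logits_node, cloud$labels, wvec)
  list(parts = parts, fw = fw)
}

#' Train a model on a labelled bundle
#'
#' Iterates `config$epochs` epochs over whole-cloud batches of size
#' `config$batch_size` (gradient averaging), logging total loss, both loss
#' components and training mIoU per epoch. The checkpoint with the best
#' training mIoU is retained. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param bundle a `dataset_bundle` whose clouds carry semantic labels (the
#'   `"train"` side is used; if no cloud is marked train, all clouds are).
#' @param config an [ffnet_config()].
#' @param checkpoint optional path; the best model is saved there.
#' @param log_file optional path for a tab-separated per-epoch metrics file.
#' @param verbose print per-epoch lines.
#' @return list with `model` (best checkpoint), `final_model`, `history`
#'   (data frame of per-epoch metrics), `weights` (class weights used).
#' @export
ffnet_train <- function(bundle, config, checkpoint = NULL, log_file = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(config, "ffnet_config"))
  clouds <- bundle$clouds
  in_train <- vapply(clouds, function(cl)
    identical(unname(bundle$split[cl$plant_id]), "train"), TRUE)
  if (any(in_train)) clouds <- clouds[in_train]
  if (length(clouds) == 0L) stop("bundle has no training clouds")
  for (cl in clouds)
    if (is.null(cl$labels)) stop("training requires labelled clouds")
  K <- config$num_classes
  cw <- class_weights(unlist(lapply(clouds, `[[`, "labels")), K)
  wvec <- cw$weights

  model <- ffnet_init(config)
  state <- adam_init(model$params)
  geoms <- lapply(clouds, function(cl) ffnet_geometry(config, cl))

  n <- length(clouds)
  bs <- min(config$batch_size, n)
  history <- vector("list", config$epochs)
  best <- list(miou = -Inf, values = NULL)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + epoch, sample.int(n))
    conf <- matrix(0, K, K)
    ep_loss <- ep_v <- ep_p <- 0
    starts <- seq(1L, n, by = bs)
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + bs - 1L, n)]
      for (p in model$params) p$grad <- NULL
      acc <- NULL
      batch_loss <- 0
      for (ci in idx) {
        sg <- ffnet_step_graph(model, clouds[[ci]], geoms[[ci]], wvec)
        loss <- sg$parts$total$value[1L, 1L]
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (cloud %d): %s",
                       epoch, ci, format(loss)))
        scaled <- ag_scale(sg$parts$total, 1 / length(idx))
        ag_backward(scaled)
        if (is.null(acc)) {
          acc <- lapply(model$params, function(p) p$grad)
        } else {
          for (nm in names(acc)) {
            g <- model$params[[nm]]$grad
            if (!is.null(g))
              acc[[nm]] <- if (is.null(acc[[nm]])) g else acc[[nm]] + g
          }
        }
        batch_loss <- batch_loss + loss / length(idx)
        ep_loss <- ep_loss + loss
        ep_v <- ep_v + sg$parts$loss_v$value[1L, 1L]
        ep_p <- ep_p + sg$parts$loss_p$value[1L, 1L]
        pred <- predict_labels(sg$fw$point_logits)
        conf <- conf + evaluate_segmentation(pred, clouds[[ci]]$labels,
                                             K)$confusion
      }
      for (nm in names(model$params)) model$params[[nm]]$grad <- acc[[nm]]
      state <- adam_step(model$params, state, config$lr)
    }
    tp <- diag(conf); fn <- rowSums(conf) - tp; fp <- colSums(conf) - tp
    denom <- tp + fn + fp
    miou <- mean(ifelse(denom > 0, tp / denom, 1))
    history[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / n,
                                   loss_v = ep_v / n, loss_p = ep_p / n,
                                   train_miou = miou)
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  (voxel %.4f, point %.4f)  train mIoU %.4f",
        epoch, ep_loss / n, ep_v / n, ep_p / n, miou))
    if (miou > best$miou)
      best <- list(miou = miou,
                   values = lapply(model$params, function(p) p$value))
  }
  history <- do.call(rbind, history)
  final <- model
  best_model <- ffnet_init(config)
  for (nm in names(best$values)) best_model$params[[nm]]$value <- best$values[[nm]]
  if (!is.null(checkpoint)) ffnet_save(best_model, checkpoint)
  if (!is.null(log_file))
    utils::write.table(history, log_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(model = best_model, final_model = final, history = history,
       weights = cw)
}

#' Predict labels for one cloud
#'
#' @param model an `ffnet_model`.
#' @param cloud a `point_cloud`.
#' @return integer 0-based semantic labels, one per point, in input order.
#' @export
ffnet_predict <- function(model, cloud) {
  predict_labels(ffnet_forward(model, cloud)$point_logits)
}

#' Evaluate a model on a bundle
#'
#' Predicts every cloud on the requested side of the split and pools one
#' confusion matrix over the whole bundle.
#'
#' @param model an `ffnet_model`.
#' @param bundle a labelled `dataset_bundle`.
#' @param subset `"test"`, `"train"` or `"all"`.
#' @return a `segmentation_report`.
#' @export
ffnet_evaluate <- function(model, bundle, subset = c("test", "train", "all")) {
  subset <- match.arg(subset)
  stopifnot(inherits(model, "ffnet_model"), inherits(bundle, "dataset_bundle"))
  clouds <- bundle$clouds
  if (subset != "all") {
    keep <- vapply(clouds, function(cl)
      identical(unname(bundle$split[cl$plant_id]), subset), TRUE)
    clouds <- clouds[keep]
  }
  if (length(clouds) == 0L) stop("no clouds to evaluate in subset '",
                                 subset, "'")
  K <- model$config$num_classes
  conf <- matrix(0, K, K)
  for (cl in clouds) {
    if (is.null(cl$labels)) stop("evaluation requires labelled clouds")
    if (!is.null(cl$class_names) &&
        length(cl$class_names) != K)
      stop("class count mismatch between model and cloud")
    pred <- ffnet_predict(model, cl)
    conf <- conf + evaluate_segmentation(pred, cl$labels, K)$confusion
  }
  tp <- diag(conf); fn <- rowSums(conf) - tp; fp <- colSums(conf) - tp
  denom <- tp + fn + fp
  iou <- ifelse(denom > 0, tp / denom, 1)
  nm <- if (K == 3L) semantic_classes() else paste0("class", 0:(K - 1L))
  dimnames(conf) <- list(truth = nm, prediction = nm)
  structure(list(confusion = conf, per_class_iou = stats::setNames(iou, nm),
                 miou = mean(iou)),
            class = "segmentation_report")
}

#' Cross-validate a trained model on a different dataset
#'
#' Same mechanics as [ffnet_evaluate()], with the report annotated by source
#' and target names — the train-on-A / test-on-B protocol used to probe
#' generalisation across crops.
#'
#' @param model a model trained on bundle A.
#' @param bundle the target bundle B.
#' @param source_name,target_name labels for the report.
#' @param subset which side of B's split to use (default all of B).
#' @return a `segmentation_report` with `source` and `target` fields.
#' @export
ffnet_cross_validate <- function(model, bundle, source_name = "A",
                                 target_name = "B", subset = "all") {
  rep <- ffnet_evaluate(model, bundle, subset = subset)
  rep$source <- source_name
  rep$target <- target_name
  rep
}

#' Predict a file of points and write the labelled result
#'
#' Reads a text or PLY cloud (by extension), predicts per-point labels with
#' a checkpointed model, and writes coordinates plus labels in the same
#' format, preserving point order.
#'
#' @param checkpoint path to a [ffnet_save()] checkpoint.
#' @param input input cloud (`.txt`/`.xyz` or `.ply`).
#' @param output output path (`.txt` or `.ply`).
#' @return the output path, invisibly.
#' @export
ffnet_predict_file <- function(checkpoint, input, output) {
  model <- ffnet_load(checkpoint)
  ext <- tolower(tools::file_ext(input))
  cloud <- if (ext == "ply") import_ply(input) else read_points_txt(input)
  labels <- ffnet_predict(model, cloud)
  out <- point_cloud(cloud$coords, labels, semantic_classes(),
                     cloud$plant_id, cloud$day, input)
  if (tolower(tools::file_ext(output)) == "ply") export_ply(out, output)
  else write_points_txt(out, output)
  invisible(output)
}
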