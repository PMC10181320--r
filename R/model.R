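# The full two-branch network. Voxel branch: a 9-dim adaptive per-point
# feature (raw coordinates, offset from the voxel centroid, offset from the
# voxel min corner) through a shared MLP and per-voxel max-reduction, then a
# sparse U-Net of asymmetric residual (ASPC) blocks with strided
# downsampling and inverse-convolution (ISPC) decoding. Point branch: a
# mini-PointNet on normalised coordinates refined by per-stage
# Voxel-PointNet (VPN) blocks that treat voxels as neighbourhoods. The
# branches are fused per point by channel-wise attention, feeding a point
# head; a voxel head supervises the decoder output.

#' Model configuration
#'
#' @param num_classes number of semantic classes (3: ground, stem, leaf).
#' @param widths channel widths per U-Net stage; `length(widths) - 1` strided
#'   downsamplings (and as many ISPC decoder blocks). The default gives four
#'   decoder blocks at widths 32-64-128-256.
#' @param voxel_resolution voxels along the longest bounding-box axis.
#' @param attn_hidden hidden width of the fusion MLPs; defaults to
#'   `widths[1]`.
#' @param lrelu_slope negative slope of the leaky rectifier.
#' @param voxel_corner `"min"` (border coordinates) or `"center"`: the voxel
#'   reference point subtracted in the adaptive feature.
#' @param scalar_attention if `TRUE`, the fusion uses one score per branch
#'   instead of one per channel.
#' @param lr,epochs,batch_size training protocol defaults (Adam, constant
#'   learning rate; batches are lists of whole clouds).
#' @param seed seed for weight initialisation.
#' @return an `ffnet_config` list.
#' @export
ffnet_config <- function(num_classes = 3L,
                         widths = c(32L, 64L, 128L, 256L, 256L),
                         voxel_resolution = 128L, attn_hidden = NULL,
                         lrelu_slope = 0.1, voxel_corner = c("min", "center"),
                         scalar_attention = FALSE,
                         lr = 0.001, epochs = 200L, batch_size = 4L,
                         seed = 42L) {
  voxel_corner <- match.arg(voxel_corner)
  stopifnot(num_classes >= 2L, all(widths > 0L), length(widths) >= 2L,
            voxel_resolution >= 2L, lr > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(num_classes = as.integer(num_classes),
                 widths = as.integer(widths),
                 voxel_resolution = as.integer(voxel_resolution),
                 attn_hidden = if (is.null(attn_hidden)) as.integer(widths[1L])
                               else as.integer(attn_hidden),
                 lrelu_slope = lrelu_slope, voxel_corner = voxel_corner,
                 scalar_attention = isTRUE(scalar_attention),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ffnet_config")
}

# ---- parameter store --------------------------------------------------------

# Fan-in-scaled uniform initialisation, deterministic in creation order.
p_init <- function(nr, nc, fan_in) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

add_linear <- function(p, name, cin, cout) {
  p[[paste0(name, ".W")]] <- ag_param(p_init(cin, cout, cin))
  p[[paste0(name, ".b")]] <- ag_param(matrix(0, 1L, cout))
  p
}

add_conv <- function(p, name, kshape, cin, cout) {
  k <- prod(kshape)
  p[[paste0(name, ".W")]] <- ag_param(p_init(k * cin, cout, k * cin))
  p[[paste0(name, ".b")]] <- ag_param(matrix(0, 1L, cout))
  p
}

add_bn <- function(p, name, c) {
  p[[paste0(name, ".g")]] <- ag_param(matrix(1, 1L, c))
  p[[paste0(name, ".s")]] <- ag_param(matrix(0, 1L, c))
  p
}

apply_linear <- function(p, name, x)
  ag_add_bias(ag_matmul(x, p[[paste0(name, ".W")]]), p[[paste0(name, ".b")]])

apply_conv <- function(p, name, x, rb)
  ag_sparse_conv(x, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]], rb)

apply_bn <- function(p, name, x)
  ag_batchnorm(x, p[[paste0(name, ".g")]], p[[paste0(name, ".s")]])

# Asymmetric kernel pair of the residual block
ASPC_K1 <- c(3L, 1L, 3L)
ASPC_K2 <- c(1L, 3L, 3L)

add_aspc <- function(p, name, cin, cout) {
  p <- add_conv(p, paste0(name, ".a1"), ASPC_K1, cin, cout)
  p <- add_bn(p, paste0(name, ".a1bn"), cout)
  p <- add_conv(p, paste0(name, ".a2"), ASPC_K2, cout, cout)
  p <- add_bn(p, paste0(name, ".a2bn"), cout)
  p <- add_conv(p, paste0(name, ".b1"), ASPC_K2, cin, cout)
  p <- add_bn(p, paste0(name, ".b1bn"), cout)
  p <- add_conv(p, paste0(name, ".b2"), ASPC_K1, cout, cout)
  p <- add_bn(p, paste0(name, ".b2bn"), cout)
  if (cin != cout) p <- add_conv(p, paste0(name, ".sc"), c(1L, 1L, 1L),
                                 cin, cout)
  p
}

# Residual block with two parallel asymmetric submanifold paths
# (3x1x3 -> 1x3x3 and 1x3x3 -> 3x1x3), summed with the shortcut.
apply_aspc <- function(p, name, x, rbs, cin, cout, slope) {
  a <- ag_lrelu(apply_bn(p, paste0(name, ".a1bn"),
                         apply_conv(p, paste0(name, ".a1"), x, rbs$k1)), slope)
  a <- apply_bn(p, paste0(name, ".a2bn"),
                apply_conv(p, paste0(name, ".a2"), a, rbs$k2))
  b <- ag_lrelu(apply_bn(p, paste0(name, ".b1bn"),
                         apply_conv(p, paste0(name, ".b1"), x, rbs$k2)), slope)
  b <- apply_bn(p, paste0(name, ".b2bn"),
                apply_conv(p, paste0(name, ".b2"), b, rbs$k1))
  sc <- if (cin != cout) apply_conv(p, paste0(name, ".sc"), x, rbs$k111) else x
  ag_lrelu(ag_add(ag_add(a, b), sc), slope)
}

stage_rulebooks <- function(coords, dims) {
  list(k1 = build_rulebook(coords, ASPC_K1, mode = "submanifold", dims = dims),
       k2 = build_rulebook(coords, ASPC_K2, mode = "submanifold", dims = dims),
       k111 = build_rulebook(coords, c(1L, 1L, 1L), mode = "submanifold",
                             dims = dims))
}

# ---- model ------------------------------------------------------------------

#' Initialise a model
#'
#' @param config an [ffnet_config()].
#' @return an `ffnet_model` holding named parameter nodes and the config.
#' @export
ffnet_init <- function(config) {
  stopifnot(inherits(config, "ffnet_config"))
  w <- config$widths
  S <- length(w)
  K <- config$num_classes
  h <- config$attn_hidden
  attn_out <- if (config$scalar_attention) 2L else 2L * w[1L]
  with_seed(config$seed, {
    p <- list()
    p <- add_linear(p, "vfe1", 9L, w[1L])
    p <- add_linear(p, "vfe2", w[1L], w[1L])
    for (s in seq_len(S - 1L)) {
      p <- add_aspc(p, sprintf("enc%d", s), w[s], w[s])
      p <- add_conv(p, sprintf("down%d", s), c(2L, 2L, 2L), w[s], w[s + 1L])
      p <- add_bn(p, sprintf("down%dbn", s), w[s + 1L])
    }
    p <- add_aspc(p, "bottom", w[S], w[S])
    for (s in rev(seq_len(S - 1L))) {
      up_in <- if (s == S - 1L) w[S] else w[s + 1L]
      p <- add_conv(p, sprintf("up%d", s), c(2L, 2L, 2L), up_in, w[s])
      p <- add_bn(p, sprintf("up%dbn", s), w[s])
      p <- add_conv(p, sprintf("dec%d", s), c(1L, 1L, 1L), 2L * w[s], w[s])
      p <- add_bn(p, sprintf("dec%dbn", s), w[s])
    }
    p <- add_linear(p, "pn1", 3L, w[1L])
    p <- add_linear(p, "pn2", w[1L], w[1L])
    for (s in seq_len(S)) {
      ws <- if (s == S) w[S] else w[s]
      p <- add_linear(p, sprintf("vpn%d", s), w[1L] + ws, w[1L])
    }
    p <- add_linear(p, "att_v1", w[1L], h)
    p <- add_linear(p, "att_v2", h, attn_out)
    p <- add_linear(p, "att_p1", w[1L], h)
    p <- add_linear(p, "att_p2", h, attn_out)
    p <- add_linear(p, "head_p1", w[1L], w[1L])
    p <- add_linear(p, "head_p2", w[1L], K)
    p <- add_linear(p, "head_v", w[1L], K)
    structure(list(params = p, config = config), class = "ffnet_model")
  })
}

#' @export
print.ffnet_model <- function(x, ...) {
  n <- sum(vapply(x$params, function(q) length(q$value), 0))
  cat(sprintf("<ffnet_model> %d parameter arrays, %d weights, widths %s\n",
              length(x$params), n,
              paste(x$config$widths, collapse = "-")))
  invisible(x)
}

# Adaptive per-point voxel feature of the encoder:
# [ p_i ; p_i - centroid(voxel members) ; p_i - voxel reference corner ]
voxel_point_features <- function(cloud, assignment, corner = "min") {
  p <- cloud$coords
  a <- assignment
  cent <- rowsum(p, a$point_to_voxel, reorder = TRUE) / a$counts
  ref <- sweep(a$active_coords, 2L, a$spec$voxel_size, "*")
  ref <- sweep(ref, 2L, a$spec$origin, "+")
  if (corner == "center")
    ref <- sweep(ref, 2L, a$spec$voxel_size / 2, "+")
  out <- cbind(p, p - cent[a$point_to_voxel, , drop = FALSE],
               p - ref[a$point_to_voxel, , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Per-point adaptive voxel features, encoded to the voxel grid
#'
#' Builds the 9-dimensional adaptive feature per point, applies the shared
#' two-layer perceptron and max-reduces per voxel.
#'
#' @param cloud a `point_cloud`.
#' @param assignment its `voxel_assignment`.
#' @param model an `ffnet_model` (or `NULL` to return the raw 9-dim features).
#' @return with a model, an M x C matrix of voxel features; otherwise N x 9.
#' @export
voxel_feature_encoder <- function(cloud, assignment, model = NULL) {
  f9 <- voxel_point_features(cloud, assignment,
                             if (is.null(model)) "min"
                             else model$config$voxel_corner)
  if (is.null(model)) return(f9)
  ffnet_encode_node(model, f9, assignment)$value
}

ffnet_encode_node <- function(model, f9, assignment) {
  p <- model$params
  sl <- model$config$lrelu_slope
  x <- ag_lrelu(apply_linear(p, "vfe1", ag_const(f9)), sl)
  x <- ag_lrelu(apply_linear(p, "vfe2", x), sl)
  ag_scatter_max(x, assignment$point_to_voxel, nrow(assignment$active_coords))
}

#' Shared per-point perceptron of the point branch
#'
#' No cross-point mixing: duplicated rows give duplicated outputs and row
#' permutations commute with the map.
#'
#' @param coords N x 3 matrix of coordinates (normalised to the grid's unit
#'   box inside the full model).
#' @param model an `ffnet_model`.
#' @return N x C feature matrix.
#' @export
mini_pointnet <- function(coords, model) {
  mini_pointnet_node(model, ag_const(as.matrix(coords)))$value
}

mini_pointnet_node <- function(model, x) {
  p <- model$params
  sl <- model$config$lrelu_slope
  ag_lrelu(apply_linear(p, "pn2",
                        ag_lrelu(apply_linear(p, "pn1", x), sl)), sl)
}

# VPN block: voxel context gathered to points, concatenated, mixed by a
# shared perceptron, with a residual shortcut.
vpn_node <- function(model, s, point_feats, stage_grid_node, p2v) {
  p <- model$params
  sl <- model$config$lrelu_slope
  ctx <- ag_rows(stage_grid_node, p2v)
  mixed <- ag_lrelu(apply_linear(p, sprintf("vpn%d", s),
                                 ag_concat_cols(point_feats, ctx)), sl)
  ag_add(point_feats, mixed)
}

#' Attention-based fusion of branch features
#'
#' Per-branch scores are summed and softmax-normalised over the branch axis,
#' channel by channel, giving convex weights `alpha_v + alpha_p = 1`; the
#' fused feature is `alpha_v * f_v + alpha_p * f_p`, so each channel lies
#' between the two branch values. Inside the full model the scores come from
#' the two branch MLPs; here they can be supplied directly.
#'
#' @param f_v,f_p N x C voxel-branch and point-branch features.
#' @param score_v,score_p N x C score (logit) matrices; defaults of zero give
#'   equal weights 1/2.
#' @return list with `fused`, `alpha_v`, `alpha_p` (all N x C).
#' @export
attention_fusion <- function(f_v, f_p, score_v = NULL, score_p = NULL) {
  f_v <- as.matrix(f_v); f_p <- as.matrix(f_p)
  stopifnot(all(dim(f_v) == dim(f_p)))
  if (is.null(score_v)) score_v <- matrix(0, nrow(f_v), ncol(f_v))
  if (is.null(score_p)) score_p <- matrix(0, nrow(f_p), ncol(f_p))
  stopifnot(all(dim(score_v) == dim(f_v)), all(dim(score_p) == dim(f_p)))
  av <- 1 / (1 + exp(-(score_v - score_p)))   # softmax over the branch pair
  list(fused = av * f_v + (1 - av) * f_p, alpha_v = av, alpha_p = 1 - av)
}

fusion_node <- function(model, f_v, f_p) {
  p <- model$params
  cfg <- model$config
  sl <- cfg$lrelu_slope
  C <- cfg$widths[1L]
  sv <- apply_linear(p, "att_v2",
                     ag_lrelu(apply_linear(p, "att_v1", f_v), sl))
  sp <- apply_linear(p, "att_p2",
                     ag_lrelu(apply_linear(p, "att_p1", f_p), sl))
  logits <- ag_add(sv, sp)                    # summed branch scores
  if (cfg$scalar_attention) {
    d <- ag_sub(ag_cols(logits, 1L), ag_cols(logits, 2L))
    av <- ag_sigmoid(d)
    n <- nrow(f_v$value)
    ones <- ag_const(matrix(1, n, C))
    av_full <- ag_matmul(av, ag_const(matrix(1, 1L, C)))
    ap_full <- ag_sub(ones, av_full)
    fused <- ag_add(ag_mul(av_full, f_v), ag_mul(ap_full, f_p))
    list(fused = fused, alpha_v = av_full$value)
  } else {
    a <- ag_cols(logits, seq_len(C))
    b <- ag_cols(logits, C + seq_len(C))
    av <- ag_sigmoid(ag_sub(a, b))
    ones <- ag_const(matrix(1, nrow(f_v$value), C))
    fused <- ag_add(ag_mul(av, f_v), ag_mul(ag_sub(ones, av), f_p))
    list(fused = fused, alpha_v = av$value)
  }
}

# ---- forward pass -----------------------------------------------------------

# Per-cloud geometry: voxel assignments per stage and every rulebook the
# U-Net needs. Independent of the weights, so it is computed once per cloud
# and reused across training steps.
ffnet_geometry <- function(config, cloud) {
  S <- length(config$widths)
  spec <- fit_grid(cloud, config$voxel_resolution)
  asg <- vector("list", S)
  asg[[1L]] <- voxel_assign(cloud, spec)
  if (S > 1L) for (s in 2:S) asg[[s]] <- coarsen(asg[[s - 1L]], 2L)
  rbs <- vector("list", S)
  downs <- vector("list", S - 1L)
  ups <- vector("list", S - 1L)
  dec111 <- vector("list", S - 1L)
  for (s in seq_len(S)) {
    rbs[[s]] <- stage_rulebooks(asg[[s]]$active_coords, asg[[s]]$spec$dims)
    if (s < S) {
      downs[[s]] <- build_rulebook(asg[[s]]$active_coords, c(2L, 2L, 2L),
                                   c(2L, 2L, 2L), "strided",
                                   dims = asg[[s]]$spec$dims)
      ups[[s]] <- build_rulebook(NULL, mode = "inverse",
                                 forward_rulebook = downs[[s]])
      dec111[[s]] <- rbs[[s]]$k111
    }
  }
  box <- spec$dims * spec$voxel_size
  list(spec = spec, asg = asg, rbs = rbs, downs = downs, ups = ups,
       dec111 = dec111,
       f9 = voxel_point_features(cloud, asg[[1L]], config$voxel_corner),
       pn_in = sweep(sweep(cloud$coords, 2L, spec$origin, "-"), 2L, box, "/"))
}

#' Full forward pass over one cloud
#'
#' The entire cloud is processed without down-sampling. Returns per-point and
#' per-voxel class logits plus the voxel assignment used.
#'
#' @param model an `ffnet_model`.
#' @param cloud a `point_cloud`.
#' @param keep_graph if `TRUE`, also return autograd nodes for training.
#' @param geometry optional cached result of the internal geometry pass for
#'   this exact cloud (reused across training steps).
#' @return list with `point_logits` (N x K), `voxel_logits` (M x K),
#'   `assignment`, `alpha_v`, and (with `keep_graph`) the logit nodes.
#' @export
ffnet_forward <- function(model, cloud, keep_graph = FALSE, geometry = NULL) {
  stopifnot(inherits(model, "ffnet_model"), inherits(cloud, "point_cloud"))
  cfg <- model$config
  p <- model$params
  sl <- cfg$lrelu_slope
  w <- cfg$widths
  S <- length(w)
  if (is.null(geometry)) geometry <- ffnet_geometry(cfg, cloud)
  asg <- geometry$asg

  # voxel branch
  x <- ffnet_encode_node(model, geometry$f9, asg[[1L]])
  skips <- vector("list", S - 1L)
  taps <- vector("list", S)
  for (s in seq_len(S - 1L)) {
    x <- apply_aspc(p, sprintf("enc%d", s), x, geometry$rbs[[s]],
                    w[s], w[s], sl)
    skips[[s]] <- x
    taps[[s]] <- x
    x <- ag_lrelu(apply_bn(p, sprintf("down%dbn", s),
                           apply_conv(p, sprintf("down%d", s), x,
                                      geometry$downs[[s]])), sl)
  }
  x <- apply_aspc(p, "bottom", x, geometry$rbs[[S]], w[S], w[S], sl)
  taps[[S]] <- x
  for (s in rev(seq_len(S - 1L))) {
    x <- ag_lrelu(apply_bn(p, sprintf("up%dbn", s),
                           apply_conv(p, sprintf("up%d", s), x,
                                      geometry$ups[[s]])), sl)
    x <- ag_concat_cols(x, skips[[s]])
    x <- ag_lrelu(apply_bn(p, sprintf("dec%dbn", s),
                           apply_conv(p, sprintf("dec%d", s), x,
                                      geometry$dec111[[s]])), sl)
  }
  voxel_logits <- apply_linear(p, "head_v", x)

  # point branch on grid-normalised coordinates
  f_p <- mini_pointnet_node(model, ag_const(geometry$pn_in))
  for (s in seq_len(S)) {
    f_p <- vpn_node(model, s, f_p, taps[[s]], asg[[s]]$point_to_voxel)
  }

  f_v <- ag_rows(x, asg[[1L]]$point_to_voxel)
  fus <- fusion_node(model, f_v, f_p)
  pl <- ag_lrelu(apply_linear(p, "head_p1", fus$fused), sl)
  point_logits <- apply_linear(p, "head_p2", pl)

  out <- list(point_logits = point_logits$value,
              voxel_logits = voxel_logits$value,
              assignment = asg[[1L]], stage_assignments = asg,
              alpha_v = fus$alpha_v,
              f_v = f_v$value, f_p = f_p$value)
  if (keep_graph) {
    out$point_logits_node <- point_logits
    out$voxel_logits_node <- voxel_logits
  }
  out
}

#' Decode logits to labels
#'
#' Per-row argmax with ties broken toward the lowest class index.
#'
#' @param logits N x K matrix.
#' @return integer vector of 0-based labels.
#' @export
predict_labels <- function(logits) {
  max.col(as.matrix(logits), ties.method = "first") - 1L
}

#' Majority-vote voxel labels
#'
#' The ground-truth label of a voxel is the most frequent label among its
#' member points, ties going to the smaller class id.
#'
#' @param labels integer point labels (0-based).
#' @param assignment a `voxel_assignment`.
#' @param num_classes number of classes.
#' @return integer vector of length M.
#' @export
voxel_labels <- function(labels, assignment, num_classes = 3L) {
  n <- length(labels)
  hot <- matrix(0L, n, num_classes)
  hot[cbind(seq_len(n), labels + 1L)] <- 1L
  counts <- rowsum(hot, assignment$point_to_voxel, reorder = TRUE)
  max.col(counts, ties.method = "first") - 1L
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of the named parameter arrays plus
#' the configuration; values round-trip bit-exactly.
#'
#' @param model an `ffnet_model`.
#' @param path checkpoint file.
#' @export
ffnet_save <- function(model, path) {
  stopifnot(inherits(model, "ffnet_model"))
  saveRDS(list(config = unclass(model$config),
               values = lapply(model$params, function(p) p$value)),
          path)
  invisible(path)
}

#' @rdname ffnet_save
#' @export
ffnet_load <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "ffnet_config")
  model <- ffnet_init(cfg)
  stopifnot(identical(names(model$params), names(ck$values)))
  for (nm in names(ck$values)) model$params[[nm]]$value <- ck$values[[nm]]
  model
}
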