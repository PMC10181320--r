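# Independent brute-force oracles used across the suite. These are written
# against the mathematical definitions, not against the package internals.

# Dense 3D convolution restricted to the rulebook's output sites.
# Weight block k multiplies the input at site (out + offset_k) for
# submanifold kernels, or (out * stride + offset_k) for strided ones;
# offsets enumerate the kernel with the first axis fastest.
dense_conv_oracle <- function(occ, X, W, dims, mode,
                              kernel = c(3L, 3L, 3L), stride = c(2L, 2L, 2L),
                              out_coords = NULL) {
  cin <- ncol(X)
  cout <- ncol(W)
  D <- array(0, c(dims, cin))
  for (i in seq_len(nrow(occ)))
    D[occ[i, 1] + 1, occ[i, 2] + 1, occ[i, 3] + 1, ] <- X[i, ]
  if (mode == "submanifold") {
    h <- kernel %/% 2L
    offs <- as.matrix(expand.grid(-h[1]:h[1], -h[2]:h[2], -h[3]:h[3]))
    oc <- occ
  } else {
    offs <- as.matrix(expand.grid(0:(stride[1] - 1L), 0:(stride[2] - 1L),
                                  0:(stride[3] - 1L)))
    oc <- out_coords
  }
  ref <- matrix(0, nrow(oc), cout)
  for (o in seq_len(nrow(oc))) {
    base <- if (mode == "strided") oc[o, ] * stride else oc[o, ]
    for (k in seq_len(nrow(offs))) {
      src <- base + offs[k, ]
      if (any(src < 0) || any(src >= dims)) next
      Wk <- W[((k - 1L) * cin + 1L):(k * cin), , drop = FALSE]
      ref[o, ] <- ref[o, ] +
        as.numeric(D[src[1] + 1, src[2] + 1, src[3] + 1, ] %*% Wk)
    }
  }
  ref
}

# Transposed strided convolution: fine site f receives from coarse site
# floor(f / stride) through the weight block of f's position in its window.
dense_inverse_oracle <- function(fine_coords, coarse_coords, Y, W, stride) {
  cin <- ncol(Y)
  cout <- ncol(W)
  ckey <- function(m) (m[, 1] * 1e6 + m[, 2]) * 1e6 + m[, 3]
  ref <- matrix(0, nrow(fine_coords), cout)
  for (f in seq_len(nrow(fine_coords))) {
    cc <- fine_coords[f, ] %/% stride
    pos <- fine_coords[f, ] %% stride
    k <- pos[1] + (pos[2] + pos[3] * stride[2]) * stride[1] + 1L
    ci <- match(ckey(matrix(cc, 1)), ckey(coarse_coords))
    Wk <- W[((k - 1L) * cin + 1L):(k * cin), , drop = FALSE]
    ref[f, ] <- as.numeric(Y[ci, ] %*% Wk)
  }
  ref
}

# Per-class 1 - Jaccard of hard predictions, averaged over classes present
# in the truth, by explicit set arithmetic.
jaccard_loss_oracle <- function(pred, truth) {
  classes <- sort(unique(truth))
  vals <- vapply(classes, function(c) {
    A <- which(pred == c)
    B <- which(truth == c)
    inter <- length(intersect(A, B))
    uni <- length(union(A, B))
    if (uni == 0) 0 else 1 - inter / uni
  }, 0)
  mean(vals)
}

# Independent evaluation of the Lovasz extension via the sorted-error
# formula, computing the interpolation coefficients as finite differences of
# the prefix Jaccard losses (a different route than the packaged gradient).
lovasz_reference <- function(probs, labels) {
  classes <- sort(unique(labels))
  total <- 0
  for (c in classes) {
    fg <- as.numeric(labels == c)
    err <- abs(fg - probs[, c + 1L])
    o <- order(err, decreasing = TRUE)
    fg_s <- fg[o]
    n <- length(fg_s)
    prefix_loss <- numeric(n)
    for (m in seq_len(n)) {
      # commit the m largest errors: misclassify exactly those points
      inter <- sum(fg_s[seq_len(m)] == 0) * 0 + sum(fg_s) - sum(fg_s[seq_len(m)])
      uni <- sum(fg_s) + sum(1 - fg_s[seq_len(m)])
      prefix_loss[m] <- 1 - inter / uni
    }
    coef <- diff(c(0, prefix_loss))
    total <- total + sum(err[o] * coef)
  }
  total / length(classes)
}

# Brute-force per-voxel reductions by explicit loops.
scatter_max_oracle <- function(x, groups, m) {
  out <- matrix(-Inf, m, ncol(x))
  for (i in seq_len(nrow(x)))
    out[groups[i], ] <- pmax(out[groups[i], ], x[i, ])
  out
}

# Brute-force confusion / IoU by set intersection.
iou_oracle <- function(pred, truth, k) {
  vapply(seq_len(k) - 1L, function(c) {
    A <- which(pred == c)
    B <- which(truth == c)
    uni <- length(union(A, B))
    if (uni == 0) 1 else length(intersect(A, B)) / uni
  }, 0)
}

# Small labelled cloud for IO round-trips.
tiny_cloud <- function(n = 50L, seed = 1L, labelled = TRUE) {
  set.seed(seed)
  point_cloud(matrix(stats::runif(3 * n), ncol = 3),
              if (labelled) sample(0:2, n, replace = TRUE),
              semantic_classes(), plant_id = "p1", day = 2L)
}

small_config <- function(...) {
  ffnet_config(widths = c(8L, 12L), voxel_resolution = 16L, seed = 7L, ...)
}
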