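# Submanifold / strided / inverse sparse 3D convolution on hash-indexed
# voxel coordinates. A rulebook lists, per kernel offset, the (input row,
# output row) pairs that offset connects; convolution is then a gather,
# a per-offset matrix product and a scatter-add. Coordinates are exact
# integer tuples keyed into doubles — no lossy hashing.

#' Build a sparse-convolution rulebook
#'
#' Three modes:
#' * `submanifold` — output sites equal input sites; a pair `(i -> o)` exists
#'   for a centred kernel offset `k` iff `in_coords[i] == out_coords[o] + k`.
#'   Sparsity never dilates.
#' * `strided` — output sites are the unique `floor(in / stride)` sites; each
#'   input contributes to its stride window at the offset given by its
#'   position inside the window (`kernel_shape` must equal `stride`).
#' * `inverse` — transpose of a stored strided rulebook: features flow from
#'   the coarse sites back to the exact pre-stride site set.
#'
#' @param in_coords M x 3 integer matrix of unique active voxel coordinates
#'   (0-based).
#' @param kernel_shape 3 positive integers (odd for submanifold).
#' @param stride 3 positive integers; only used in `strided` mode.
#' @param mode one of `"submanifold"`, `"strided"`, `"inverse"`.
#' @param dims grid dimensions (3 integers) bounding `in_coords`.
#' @param batch optional integer vector of batch indices (length M); batch
#'   elements never share voxels.
#' @param forward_rulebook the stored strided rulebook, required for
#'   `mode = "inverse"`.
#' @return a `rulebook` with per-offset pair lists and `out_coords`.
#' @export
build_rulebook <- function(in_coords, kernel_shape = c(3L, 3L, 3L),
                           stride = c(1L, 1L, 1L),
                           mode = c("submanifold", "strided", "inverse"),
                           dims = NULL, batch = NULL,
                           forward_rulebook = NULL) {
  mode <- match.arg(mode)
  if (mode == "inverse") {
    rb <- forward_rulebook
    if (is.null(rb) || rb$mode != "strided")
      stop("inverse mode requires the stored rulebook of a strided conv")
    pairs <- lapply(rb$pairs, function(pr) {
      if (is.null(pr)) NULL else list(i = pr$o, o = pr$i)
    })
    return(structure(list(kernel_shape = rb$kernel_shape, stride = rb$stride,
                          mode = "inverse", pairs = pairs,
                          in_coords = rb$out_coords, out_coords = rb$in_coords,
                          in_batch = rb$out_batch, out_batch = rb$in_batch,
                          dims = rb$dims),
                     class = "rulebook"))
  }
  in_coords <- as.matrix(in_coords)
  storage.mode(in_coords) <- "integer"
  m <- nrow(in_coords)
  kernel_shape <- as.integer(rep_len(kernel_shape, 3L))
  stride <- as.integer(rep_len(stride, 3L))
  if (any(stride < 1L)) stop("stride must be >= 1")
  if (is.null(dims)) dims <- apply(in_coords, 2L, max) + 1L
  dims <- as.integer(rep_len(dims, 3L))
  if (is.null(batch)) batch <- rep(1L, m)
  nb <- max(batch)
  bkey <- function(ijk, b) (as.numeric(b) - 1) * prod(as.numeric(dims)) +
    coord_key(ijk, dims)

  if (mode == "submanifold") {
    if (any(kernel_shape %% 2L == 0L))
      stop("submanifold kernels must have odd shape")
    half <- kernel_shape %/% 2L
    offs <- as.matrix(expand.grid(dx = -half[1L]:half[1L],
                                  dy = -half[2L]:half[2L],
                                  dz = -half[3L]:half[3L]))[, 1:3, drop = FALSE]
    in_key <- bkey(in_coords, batch)   # unique by precondition
    pairs <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
      src <- sweep(in_coords, 2L, offs[k, ], "+")   # candidate inputs i = o + k
      ok <- src[, 1L] >= 0L & src[, 1L] < dims[1L] &
            src[, 2L] >= 0L & src[, 2L] < dims[2L] &
            src[, 3L] >= 0L & src[, 3L] < dims[3L]
      if (!any(ok)) next
      i_idx <- match(bkey(src[ok, , drop = FALSE], batch[ok]), in_key)
      hit <- !is.na(i_idx)
      if (!any(hit)) next
      pairs[[k]] <- list(i = i_idx[hit], o = which(ok)[hit])
    }
    out_coords <- in_coords
    out_batch <- batch
  } else {                             # strided
    if (!all(kernel_shape == stride))
      stop("strided mode uses kernel_shape == stride")
    offs <- as.matrix(expand.grid(dx = 0:(stride[1L] - 1L),
                                  dy = 0:(stride[2L] - 1L),
                                  dz = 0:(stride[3L] - 1L)))[, 1:3, drop = FALSE]
    coarse <- sweep(in_coords, 2L, stride, "%/%")
    cdims <- pmax(1L, as.integer(ceiling(dims / stride)))
    ckey <- (as.numeric(batch) - 1) * prod(as.numeric(cdims)) +
      coord_key(coarse, cdims)
    act <- sort(unique(ckey))
    o_idx <- match(ckey, act)
    pos <- in_coords - sweep(coarse, 2L, stride, "*")   # offset within window
    # offset ids follow expand.grid order: first axis fastest
    pos_id <- pos[, 1L] + (pos[, 2L] + pos[, 3L] * stride[2L]) * stride[1L] + 1L
    pairs <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
      sel <- which(pos_id == k)
      if (length(sel) > 0L) pairs[[k]] <- list(i = sel, o = o_idx[sel])
    }
    first <- match(act, ckey)          # act is sorted by key
    out_coords <- coarse[first, , drop = FALSE]
    out_batch <- batch[first]
    dims <- cdims
  }
  structure(list(kernel_shape = kernel_shape, stride = stride, mode = mode,
                 pairs = pairs, in_coords = in_coords, out_coords = out_coords,
                 in_batch = batch, out_batch = out_batch, dims = dims),
            class = "rulebook")
}

#' @export
print.rulebook <- function(x, ...) {
  np <- sum(vapply(x$pairs, function(p) if (is.null(p)) 0L else length(p$i), 0L))
  cat(sprintf("<rulebook> %s, kernel %s, %d -> %d sites, %d pairs\n",
              x$mode, paste(x$kernel_shape, collapse = "x"),
              nrow(x$in_coords), nrow(x$out_coords), np))
  invisible(x)
}

#' Apply a sparse convolution (plain matrices)
#'
#' `out[o, ] = bias + sum over offsets k and pairs (i -> o) of
#' features[i, ] %*% W[k]`, where `W[k]` is the `k`-th `Cin x Cout` block of
#' `weights`.
#'
#' @param features M x Cin matrix over the rulebook's input sites.
#' @param rulebook a [build_rulebook()] result.
#' @param weights `(K * Cin) x Cout` matrix, `K` the kernel volume.
#' @param bias optional length-`Cout` numeric.
#' @return M' x Cout matrix over the rulebook's output sites.
#' @export
sparse_conv <- function(features, rulebook, weights, bias = NULL) {
  x <- ag_const(as.matrix(features))
  w <- ag_const(as.matrix(weights))
  b <- if (is.null(bias)) NULL else ag_const(matrix(bias, nrow = 1L))
  ag_sparse_conv(x, w, b, rulebook)$value
}

# autograd node for sparse convolution
ag_sparse_conv <- function(x, w, b, rb) {
  xv <- x$value
  wv <- w$value
  cin <- ncol(xv)
  cout <- ncol(wv)
  k_total <- length(rb$pairs)
  if (nrow(wv) != k_total * cin)
    stop("weight rows must equal kernel volume x input channels")
  m_out <- nrow(rb$out_coords)
  out <- matrix(0, m_out, cout)
  for (k in seq_len(k_total)) {
    pr <- rb$pairs[[k]]
    if (is.null(pr)) next
    wk <- wv[((k - 1L) * cin + 1L):(k * cin), , drop = FALSE]
    out <- acc_rows(out, pr$o, xv[pr$i, , drop = FALSE] %*% wk)
  }
  if (!is.null(b)) out <- out + rep(as.numeric(b$value), each = m_out)
  parents <- list(x, w)
  vjps <- list(
    function(g) {
      dx <- matrix(0, nrow(xv), cin)
      for (k in seq_len(k_total)) {
        pr <- rb$pairs[[k]]
        if (is.null(pr)) next
        wk <- wv[((k - 1L) * cin + 1L):(k * cin), , drop = FALSE]
        dx <- acc_rows(dx, pr$i, tcrossprod(g[pr$o, , drop = FALSE], wk))
      }
      dx
    },
    function(g) {
      dw <- matrix(0, nrow(wv), cout)
      for (k in seq_len(k_total)) {
        pr <- rb$pairs[[k]]
        if (is.null(pr)) next
        rows <- ((k - 1L) * cin + 1L):(k * cin)
        dw[rows, ] <- dw[rows, ] +
          t(xv[pr$i, , drop = FALSE]) %*% g[pr$o, , drop = FALSE]
      }
      dw
    }
  )
  if (!is.null(b)) {
    parents <- c(parents, list(b))
    vjps <- c(vjps, list(function(g) matrix(colSums(g), nrow = 1L)))
  }
  ag_node(out, parents, vjps)
}
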