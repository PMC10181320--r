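# Minimal tape-free reverse-mode automatic differentiation over dense matrices.
# Each node is an environment holding a value, its parents, and one
# vector-Jacobian-product closure per differentiable parent. backward() does a
# depth-first topological sort from the loss node, so graphs are rebuilt every
# forward pass while parameter nodes persist across iterations.

.ag_state <- new.env(parent = emptyenv())
.ag_state$id <- 0L
.ag_state$token <- 0L

ag_node <- function(value, parents = list(), vjps = list(), req = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjps <- vjps
  e$grad <- NULL
  if (is.null(req)) {
    req <- FALSE
    for (p in parents) if (isTRUE(p$req)) { req <- TRUE; break }
  }
  e$req <- req
  .ag_state$id <- .ag_state$id + 1L
  e$id <- .ag_state$id
  e$token <- -1L
  class(e) <- "ag_node"
  e
}

#' @noRd
ag_const <- function(x) ag_node(as_matrix(x), req = FALSE)

#' @noRd
ag_param <- function(x) {
  n <- ag_node(as_matrix(x), req = TRUE)
  n$is_param <- TRUE
  n
}

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

is_ag <- function(x) inherits(x, "ag_node")
val <- function(x) if (is_ag(x)) x$value else x

# Topological order by iterative post-order DFS (deepest first after reversal).
ag_topo <- function(root) {
  .ag_state$token <- .ag_state$token + 1L
  tok <- .ag_state$token
  order <- vector("list", 64L)
  n_ord <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (node$token == tok) next
      node$token <- tok
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (isTRUE(p$req) && p$token != tok)
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  order[seq_len(n_ord)]
}

#' Run reverse-mode differentiation from a scalar loss node
#'
#' Accumulates gradients into every parameter node reachable from `root`.
#' Gradients from a previous call are discarded.
#'
#' @param root an `ag_node` holding a 1x1 value.
#' @return invisibly, the list of visited nodes.
#' @noRd
ag_backward <- function(root) {
  order <- ag_topo(root)          # post-order: parents before children
  for (n in order) n$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  for (k in rev(seq_along(order))) {
    node <- order[[k]]
    g <- node$grad
    if (is.null(g)) next
    vj <- node$vjps
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!isTRUE(p$req) || is.null(vj[[j]])) next
      contrib <- vj[[j]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
  }
  invisible(order)
}

# ---- primitive operations ---------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), list(
    function(g) tcrossprod(g, bv),
    function(g) crossprod(av, g)
  ))
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), list(
    function(g) g,
    function(g) g
  ))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), list(
    function(g) g,
    function(g) -g
  ))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), list(
    function(g) g * bv,
    function(g) g * av
  ))
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), list(function(g) g * s))
}

# bias is a parameter of length ncol(a), broadcast across rows
ag_add_bias <- function(a, bias) {
  bv <- as.numeric(bias$value)
  av <- a$value
  ag_node(av + rep(bv, each = nrow(av)), list(a, bias), list(
    function(g) g,
    function(g) matrix(colSums(g), nrow = 1L)
  ))
}

ag_lrelu <- function(a, slope = 0.1) {
  av <- a$value
  mask <- slope + (1 - slope) * (av > 0)
  ag_node(av * mask, list(a), list(function(g) g * mask))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), list(function(g) g * s * (1 - s)))
}

ag_concat_cols <- function(a, b) {
  ca <- ncol(a$value)
  cb <- ncol(b$value)
  ag_node(cbind(a$value, b$value), list(a, b), list(
    function(g) g[, seq_len(ca), drop = FALSE],
    function(g) g[, ca + seq_len(cb), drop = FALSE]
  ))
}

# slice columns (constant index)
ag_cols <- function(a, idx) {
  nc <- ncol(a$value)
  ag_node(a$value[, idx, drop = FALSE], list(a), list(function(g) {
    z <- matrix(0, nrow(g), nc)
    z[, idx] <- g
    z
  }))
}

# gather rows by index; scatter-add on the way back
ag_rows <- function(a, idx) {
  nr <- nrow(a$value)
  ag_node(a$value[idx, , drop = FALSE], list(a), list(function(g) {
    acc_rows(matrix(0, nr, ncol(g)), idx, g)
  }))
}

ag_sum <- function(a) {
  dims <- dim(a$value)
  ag_node(matrix(sum(a$value), 1L, 1L), list(a), list(
    function(g) matrix(as.numeric(g) , dims[1L], dims[2L])
  ))
}

ag_mean <- function(a) {
  dims <- dim(a$value)
  n <- prod(dims)
  ag_node(matrix(mean(a$value), 1L, 1L), list(a), list(
    function(g) matrix(as.numeric(g) / n, dims[1L], dims[2L])
  ))
}

# scatter-add rows of `vals` into `base` at (possibly repeated) indices
acc_rows <- function(base, idx, vals) {
  rs <- rowsum(vals, group = idx, reorder = FALSE)
  tgt <- as.integer(rownames(rs))
  base[tgt, ] <- base[tgt, , drop = FALSE] + rs
  base
}

# ---- grouped reductions -----------------------------------------------------

# Per-group, per-column maximum with argmax bookkeeping; `group` maps each row
# of `a` to a group in 1..ngroups and every group must be non-empty.
grouped_max <- function(x, group, ngroups) {
  nc <- ncol(x)
  out <- matrix(0, ngroups, nc)
  arg <- matrix(0L, ngroups, nc)
  for (j in seq_len(nc)) {
    o <- order(group, x[, j])          # within group, max is the last element
    gs <- group[o]
    last <- which(gs != c(gs[-1L], -1L))  # final position of each group run
    out[gs[last], j] <- x[o[last], j]
    arg[gs[last], j] <- o[last]
  }
  list(max = out, argmax = arg)
}

ag_scatter_max <- function(a, group, ngroups) {
  gm <- grouped_max(a$value, group, ngroups)
  arg <- gm$argmax
  nr <- nrow(a$value)
  ag_node(gm$max, list(a), list(function(g) {
    z <- matrix(0, nr, ncol(g))
    for (j in seq_len(ncol(g))) {
      z[arg[, j], j] <- z[arg[, j], j] + g[, j]
    }
    z
  }))
}

# ---- normalisation ----------------------------------------------------------

# Per-channel normalisation over active sites (batch statistics) with learned
# scale and shift. Statistics are recomputed from the current batch in both
# training and inference; with whole clouds as batches this is deterministic.
ag_batchnorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = n)
  v <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_sd, each = n)
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  ag_node(y, list(a, gamma, beta), list(
    function(g) {
      gg <- g * rep(gv, each = n)                 # dL/dxhat
      m1 <- colMeans(gg)
      m2 <- colMeans(gg * xhat)
      (gg - rep(m1, each = n) - xhat * rep(m2, each = n)) *
        rep(inv_sd, each = n)
    },
    function(g) matrix(colSums(g * xhat), nrow = 1L),
    function(g) matrix(colSums(g), nrow = 1L)
  ))
}

# ---- softmax and losses -----------------------------------------------------

row_max <- function(x) {
  m <- x[, 1L]
  nc <- ncol(x)
  if (nc > 1L) for (j in 2:nc) m <- pmax(m, x[, j])
  m
}

row_softmax <- function(x) {
  e <- exp(x - row_max(x))
  e / rowSums(e)
}

ag_softmax_rows <- function(a) {
  p <- row_softmax(a$value)
  ag_node(p, list(a), list(function(g) {
    p * (g - rowSums(g * p))
  }))
}

# Class-weighted cross entropy from logits; labels are 0-based integers.
ag_weighted_ce <- function(logits, labels, weights) {
  x <- logits$value
  n <- nrow(x)
  k <- ncol(x)
  stopifnot(all(labels >= 0L & labels < k))
  p <- row_softmax(x)
  idx <- cbind(seq_len(n), labels + 1L)
  w <- weights[labels + 1L]
  loss <- mean(w * (-log(pmax(p[idx], 1e-12))))
  ag_node(matrix(loss, 1L, 1L), list(logits), list(function(g) {
    hot <- matrix(0, n, k)
    hot[idx] <- 1
    as.numeric(g) * (w / n) * (p - hot)
  }))
}

# Gradient of the Lovasz extension of the Jaccard loss for a ground-truth
# indicator vector already sorted by decreasing error.
lovasz_grad_sorted <- function(gt_sorted) {
  n <- length(gt_sorted)
  gts <- sum(gt_sorted)
  inter <- gts - cumsum(gt_sorted)
  union <- gts + cumsum(1 - gt_sorted)
  jacc <- 1 - inter / union
  if (n > 1L) jacc[2:n] <- jacc[2:n] - jacc[1:(n - 1L)]
  jacc
}

# Lovasz-softmax over the classes present in `labels` (0-based). `probs` rows
# must lie on the simplex. The Jaccard-extension coefficients are treated as
# constants in the backward pass (they are piecewise constant in the errors).
ag_lovasz_softmax <- function(probs, labels) {
  p <- probs$value
  n <- nrow(p)
  present <- sort(unique(labels))
  m <- length(present)
  dloss <- matrix(0, n, ncol(p))
  total <- 0
  for (c in present) {
    fg <- as.numeric(labels == c)
    err <- abs(fg - p[, c + 1L])
    o <- order(err, decreasing = TRUE)
    coef <- lovasz_grad_sorted(fg[o])
    total <- total + sum(err[o] * coef)
    sgn <- ifelse(fg == 1, -1, 1)          # d err / d p[, c]
    cu <- numeric(n)
    cu[o] <- coef
    dloss[, c + 1L] <- dloss[, c + 1L] + sgn * cu / m
  }
  ag_node(matrix(total / m, 1L, 1L), list(probs), list(function(g) {
    as.numeric(g) * dloss
  }))
}
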