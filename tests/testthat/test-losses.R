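test_that("class weights are reciprocal frequencies", {
  cw <- class_weights(c(rep(0L, 5), rep(1L, 5)), 2L)
  expect_equal(cw$weights, c(2, 2))
  cw3 <- class_weights(rep(0:2, times = c(500, 50, 450)), 3L)
  expect_equal(cw3$frequencies, c(0.5, 0.05, 0.45))
  expect_equal(cw3$weights, c(2, 20, 1 / 0.45))
  # shares close to a maize-like training distribution
  cwm <- class_weights(rep(0:2, times = c(497, 55, 448)), 3L)
  expect_equal(cwm$weights, c(1000 / 497, 1000 / 55, 1000 / 448))
  expect_equal(round(cwm$weights, 3), c(2.012, 18.182, 2.232))
  # an absent class gets weight zero rather than infinity
  expect_equal(class_weights(c(0L, 0L), 3L)$weights[2:3], c(0, 0))
  expect_error(class_weights(integer(0)), "no labels")
})

test_that("weighted cross entropy has the expected closed forms", {
  expect_equal(weighted_ce(matrix(0, 7, 3), rep(0:2, length.out = 7)),
               log(3))
  big <- matrix(-50, 5, 3)
  big[cbind(1:5, c(1, 2, 3, 1, 2))] <- 50
  expect_lt(weighted_ce(big, c(0L, 1L, 2L, 0L, 1L)), 1e-10)

  set.seed(8)
  logits <- matrix(rnorm(30), 10, 3)
  y <- sample(0:2, 10, replace = TRUE)
  plain <- -mean(log(exp(logits[cbind(1:10, y + 1)]) /
                       rowSums(exp(logits))))
  expect_equal(weighted_ce(logits, y, c(1, 1, 1)), plain, tolerance = 1e-7)
  w <- c(2, 20, 2.2)
  expect_equal(weighted_ce(logits, y, 2 * w),
               2 * weighted_ce(logits, y, w))
  expect_error(weighted_ce(logits, c(y[-10], 5L)), "labels")
})

test_that("Lovasz-softmax equals 1 - Jaccard on hard predictions", {
  # 5 foreground points, 3 predicted right, 1 false positive, 2 false
  # negatives: the foreground class scores 1 - 3/6 = 0.5
  truth <- c(1L, 1L, 1L, 1L, 1L, 0L)
  pred <- c(1L, 1L, 1L, 0L, 0L, 1L)
  P <- matrix(0, 6, 2)
  P[cbind(1:6, pred + 1L)] <- 1
  expect_equal(lovasz_softmax(P, truth),
               jaccard_loss_oracle(pred, truth))
  fg_only <- 1 - 3 / 6
  expect_equal(jaccard_loss_oracle(pred, truth), (fg_only + 1) / 2)

  exact <- matrix(0, 6, 2)
  exact[cbind(1:6, truth + 1L)] <- 1
  expect_equal(lovasz_softmax(exact, truth), 0)

  set.seed(3)
  for (t in 1:50) {
    n <- sample(2:8, 1)
    y <- sample(0:2, n, replace = TRUE)
    p <- sample(0:2, n, replace = TRUE)
    Ph <- matrix(0, n, 3)
    Ph[cbind(1:n, p + 1L)] <- 1
    expect_equal(lovasz_softmax(Ph, y), jaccard_loss_oracle(p, y),
                 tolerance = 1e-12)
  }
})

test_that("Lovasz-softmax on soft inputs matches the independent reference", {
  set.seed(14)
  for (t in 1:40) {
    n <- sample(2:6, 1)
    k <- sample(2:3, 1)
    y <- sample(seq_len(k) - 1L, n, replace = TRUE)
    raw <- matrix(rexp(n * k), n, k)
    P <- raw / rowSums(raw)
    expect_equal(lovasz_softmax(P, y), lovasz_reference(P, y),
                 tolerance = 1e-10)
  }
  expect_error(lovasz_softmax(matrix(c(0.9, 0.9, 0.1, 0.2), 2), c(0L, 1L)),
               "simplex")
})

test_that("Lovasz-softmax is invariant under point permutation", {
  set.seed(15)
  for (t in 1:20) {
    n <- 7L
    y <- sample(0:2, n, replace = TRUE)
    raw <- matrix(rexp(n * 3), n, 3)
    P <- raw / rowSums(raw)
    perm <- sample(n)
    expect_equal(lovasz_softmax(P[perm, ], y[perm]),
                 lovasz_softmax(P, y), tolerance = 1e-12)
  }
})

test_that("the composite loss is the exact sum of its parts", {
  set.seed(5)
  vl <- matrix(rnorm(24), 8, 3)
  vy <- sample(0:2, 8, replace = TRUE)
  pl <- matrix(rnorm(36), 12, 3)
  py <- sample(0:2, 12, replace = TRUE)
  w <- c(2, 20, 2.2)
  parts <- total_loss(vl, vy, pl, py, w)
  probs <- exp(vl - apply(vl, 1, max))
  probs <- probs / rowSums(probs)
  expect_identical(parts$total, parts$loss_v + parts$loss_p)
  expect_equal(parts$loss_v,
               weighted_ce(vl, vy, w) + lovasz_softmax(probs, vy),
               tolerance = 1e-12)
  expect_equal(parts$loss_p, weighted_ce(pl, py, w), tolerance = 1e-12)

  big <- matrix(-50, 12, 3)
  big[cbind(1:12, py + 1L)] <- 50
  perf_p <- total_loss(vl, vy, big, py, w)
  expect_equal(perf_p$total, perf_p$loss_v, tolerance = 1e-10)

  bigv <- matrix(-50, 8, 3)
  bigv[cbind(1:8, vy + 1L)] <- 50
  expect_lt(total_loss(bigv, vy, big, py, w)$total, 1e-10)
})

test_that("composite loss gradients match finite differences", {
  set.seed(6)
  vy <- sample(0:2, 6, replace = TRUE)
  py <- sample(0:2, 10, replace = TRUE)
  w <- c(1.5, 10, 2)
  v <- ffnet:::ag_param(matrix(rnorm(18), 6, 3))
  p <- ffnet:::ag_param(matrix(rnorm(30), 10, 3))
  parts <- ffnet:::total_loss_node(v, vy, p, py, w)
  ffnet:::ag_backward(parts$total)
  eps <- 1e-6
  for (node in list(v, p)) {
    for (t in 1:5) {
      i <- sample(length(node$value), 1)
      v0 <- node$value[i]
      f <- function(x) {
        node$value[i] <- x
        out <- ffnet:::total_loss_node(v, vy, p, py, w)$total$value[1, 1]
        node$value[i] <- v0
        out
      }
      num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
      expect_equal(node$grad[i], num, tolerance = 1e-4)
    }
  }
})

test_that("segmentation evaluation matches hand counts and conventions", {
  r <- evaluate_segmentation(c(0L, 1L, 1L, 1L, 0L), c(0L, 0L, 1L, 1L, 1L), 2L)
  expect_equal(unname(r$per_class_iou), c(1 / 3, 1 / 2))
  expect_equal(r$miou, 5 / 12)
  expect_equal(sum(r$confusion), 5)

  y <- sample(0:2, 50, replace = TRUE)
  perfect <- evaluate_segmentation(y, y, 3L)
  expect_equal(unname(perfect$per_class_iou), rep(1, 3))
  expect_equal(perfect$miou, 1)

  # class 2 absent everywhere: vacuous IoU 1; absent but predicted: 0
  vac <- evaluate_segmentation(c(0L, 1L), c(0L, 1L), 3L)
  expect_equal(unname(vac$per_class_iou[3]), 1)
  fp <- evaluate_segmentation(c(0L, 2L), c(0L, 1L), 3L)
  expect_equal(unname(fp$per_class_iou[3]), 0)
  expect_error(evaluate_segmentation(c(0L, 1L), c(0L, 1L, 2L), 3L), "length")
})

test_that("evaluation is symmetric under simultaneous class permutation", {
  set.seed(7)
  y <- sample(0:2, 300, replace = TRUE)
  p <- sample(0:2, 300, replace = TRUE)
  base <- evaluate_segmentation(p, y, 3L)
  perm <- c(2L, 0L, 1L)
  swapped <- evaluate_segmentation(perm[p + 1L], perm[y + 1L], 3L)
  expect_equal(sort(unname(swapped$per_class_iou)),
               sort(unname(base$per_class_iou)))
  expect_equal(swapped$miou, base$miou)
})

test_that("report serialisation mirrors the mIoU/class column layout", {
  r <- evaluate_segmentation(c(0L, 1L, 2L, 2L), c(0L, 1L, 2L, 1L), 3L)
  tab <- report_table(r)
  expect_equal(names(tab), c("mIoU", "ground", "stem", "leaf"))
  expect_equal(tab$mIoU, round(100 * r$miou, 2))
})
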