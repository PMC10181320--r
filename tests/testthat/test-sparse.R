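random_occupancy <- function(dims, p = 0.3, seed = 1L) {
  set.seed(seed)
  occ <- which(array(runif(prod(dims)) < p, dims), arr.ind = TRUE) - 1L
  if (nrow(occ) == 0L) occ <- matrix(0L, 1L, 3L)
  dimnames(occ) <- NULL
  storage.mode(occ) <- "integer"
  occ[order(ffnet:::coord_key(occ, dims)), , drop = FALSE]
}

test_that("submanifold rulebooks enumerate exactly the in-range neighbours", {
  # single active site: only the centre offset pairs
  rb <- build_rulebook(matrix(3L, 1, 3), c(3L, 3L, 3L), dims = c(8L, 8L, 8L))
  np <- vapply(rb$pairs, function(p) if (is.null(p)) 0L else length(p$i), 0L)
  expect_equal(sum(np), 1L)
  expect_equal(which(np == 1L), 14L)        # centre of the 27 offsets
  expect_identical(rb$out_coords, rb$in_coords)

  # two adjacent sites along x with a 3x1x1 kernel: self + neighbour = 4 pairs
  co <- rbind(c(2L, 2L, 2L), c(3L, 2L, 2L))
  rb2 <- build_rulebook(co, c(3L, 1L, 1L), dims = c(8L, 8L, 8L))
  expect_equal(sum(vapply(rb2$pairs, function(p)
    if (is.null(p)) 0L else length(p$i), 0L)), 4L)

  expect_error(build_rulebook(co, c(2L, 1L, 1L)), "odd")
  expect_error(build_rulebook(co, stride = c(0L, 1L, 1L), mode = "strided"),
               "stride")
  expect_error(build_rulebook(co, mode = "inverse"), "stored rulebook")
})

test_that("rulebook pair lists match triple-loop enumeration on random grids", {
  dims <- c(6L, 6L, 6L)
  occ <- random_occupancy(dims, 0.3, 99L)
  key <- ffnet:::coord_key(occ, dims)
  rb <- build_rulebook(occ, c(3L, 3L, 3L), dims = dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (k in seq_len(27)) {
    want <- list(i = integer(0), o = integer(0))
    for (o in seq_len(nrow(occ))) {        # brute force: in = out + offset
      src <- occ[o, ] + offs[k, ]
      if (any(src < 0L) || any(src >= dims)) next
      i <- match(ffnet:::coord_key(matrix(src, 1), dims), key)
      if (!is.na(i)) { want$i <- c(want$i, i); want$o <- c(want$o, o) }
    }
    got <- rb$pairs[[k]]
    if (length(want$i) == 0L) {
      expect_null(got)
    } else {
      ord_w <- order(want$o); ord_g <- order(got$o)
      expect_equal(got$i[ord_g], want$i[ord_w])
      expect_equal(got$o[ord_g], want$o[ord_w])
    }
  }
})

test_that("sparse convolution passes identity, bias and linearity checks", {
  dims <- c(5L, 5L, 5L)
  occ <- random_occupancy(dims, 0.4, 3L)
  m <- nrow(occ)
  cin <- 3L
  rb <- build_rulebook(occ, c(3L, 3L, 3L), dims = dims)
  x <- matrix(rnorm(m * cin), ncol = cin)

  w_id <- matrix(0, 27 * cin, cin)
  w_id[(13L * cin + 1L):(14L * cin), ] <- diag(cin)   # centre block = I
  expect_equal(sparse_conv(x, rb, w_id), x)

  w0 <- matrix(0, 27 * cin, 2L)
  b <- c(-1.5, 2.25)
  expect_equal(sparse_conv(x, rb, w0, b),
               matrix(b, m, 2L, byrow = TRUE))

  w <- matrix(rnorm(27 * cin * 2L), ncol = 2L)
  y <- matrix(rnorm(m * cin), ncol = cin)
  expect_equal(sparse_conv(2 * x - 3 * y, rb, w),
               2 * sparse_conv(x, rb, w) - 3 * sparse_conv(y, rb, w),
               tolerance = 1e-12)
})

test_that("all three conv modes agree with the dense oracle", {
  for (seed in 1:8) {
    dims <- sample(4:8, 3L, replace = TRUE)
    occ <- random_occupancy(dims, 0.35, seed + 100L)
    m <- nrow(occ)
    x <- matrix(rnorm(m * 2L), ncol = 2L)

    rb <- build_rulebook(occ, c(3L, 1L, 3L), dims = dims)
    w <- matrix(rnorm(9 * 2 * 3), ncol = 3L)
    expect_equal(sparse_conv(x, rb, w),
                 dense_conv_oracle(occ, x, w, dims, "submanifold",
                                   kernel = c(3L, 1L, 3L)),
                 tolerance = 1e-10)

    rb_s <- build_rulebook(occ, c(2L, 2L, 2L), c(2L, 2L, 2L), "strided",
                           dims = dims)
    ws <- matrix(rnorm(8 * 2 * 3), ncol = 3L)
    expect_equal(sparse_conv(x, rb_s, ws),
                 dense_conv_oracle(occ, x, ws, dims, "strided",
                                   out_coords = rb_s$out_coords),
                 tolerance = 1e-10)

    rb_i <- build_rulebook(NULL, mode = "inverse", forward_rulebook = rb_s)
    expect_identical(rb_i$out_coords, occ)   # exact restoration of sites
    y <- matrix(rnorm(nrow(rb_s$out_coords) * 2L), ncol = 2L)
    expect_equal(sparse_conv(y, rb_i, ws),
                 dense_inverse_oracle(occ, rb_s$out_coords, y, ws,
                                      c(2L, 2L, 2L)),
                 tolerance = 1e-10)
  }
})

test_that("sparse conv gradients match finite differences", {
  dims <- c(4L, 4L, 4L)
  occ <- random_occupancy(dims, 0.4, 17L)
  m <- nrow(occ)
  rb <- build_rulebook(occ, c(3L, 1L, 3L), dims = dims)
  set.seed(2)
  x <- ffnet:::ag_param(matrix(rnorm(m * 2L), ncol = 2L))
  w <- ffnet:::ag_param(matrix(rnorm(9 * 2 * 2), ncol = 2L))
  b <- ffnet:::ag_param(matrix(rnorm(2), 1L))
  loss <- ffnet:::ag_sum(ffnet:::ag_mul(ffnet:::ag_sparse_conv(x, w, b, rb),
                                        ffnet:::ag_sparse_conv(x, w, b, rb)))
  ffnet:::ag_backward(loss)
  eps <- 1e-6
  for (p in list(x, w, b)) {
    for (t in 1:4) {
      i <- sample(length(p$value), 1L)
      v0 <- p$value[i]
      f <- function(v) {
        p$value[i] <- v
        out <- ffnet:::ag_sparse_conv(x, w, b, rb)$value
        p$value[i] <- v0
        sum(out * out)
      }
      num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
      expect_equal(p$grad[i], num, tolerance = 1e-4)
    }
  }
})

test_that("ASPC blocks preserve active sites and reduce to the shortcut", {
  cfg <- small_config()
  cl <- generate_plant(plant_recipe(n_points_target = 800L, seed = 2L))
  geo <- ffnet:::ffnet_geometry(cfg, cl)
  a <- geo$asg[[1L]]
  m <- nrow(a$active_coords)
  C <- cfg$widths[1L]
  model <- ffnet_init(cfg)
  x <- ffnet:::ag_const(matrix(rnorm(m * C), ncol = C))

  out <- ffnet:::apply_aspc(model$params, "enc1", x, geo$rbs[[1L]],
                            C, C, cfg$lrelu_slope)
  expect_equal(nrow(out$value), m)         # site set unchanged

  # zero conv weights: the residual path vanishes, the shortcut remains
  zero <- ffnet_init(cfg)
  for (nm in grep("^enc1\\.(a|b)", names(zero$params), value = TRUE))
    if (grepl("\\.W$|\\.b$", nm)) zero$params[[nm]]$value[] <- 0
  for (nm in grep("^enc1\\..*bn\\.g$", names(zero$params), value = TRUE))
    zero$params[[nm]]$value[] <- 1
  out0 <- ffnet:::apply_aspc(zero$params, "enc1", x, geo$rbs[[1L]],
                             C, C, slope = 1)   # slope 1: linear activation
  expect_equal(out0$value, x$value, tolerance = 1e-8)
})

test_that("downsample-then-upsample restores encoder coordinates exactly", {
  for (seed in c(4L, 8L)) {
    dims <- c(8L, 8L, 8L)
    occ <- random_occupancy(dims, 0.25, seed)
    rb_s <- build_rulebook(occ, c(2L, 2L, 2L), c(2L, 2L, 2L), "strided",
                           dims = dims)
    rb_i <- build_rulebook(NULL, mode = "inverse", forward_rulebook = rb_s)
    expect_identical(rb_i$out_coords, occ)
    expect_identical(rb_i$in_coords, rb_s$out_coords)
  }
})

test_that("the voxel U-Net keeps full-resolution coords and coarsens stages", {
  cfg <- small_config()
  model <- ffnet_init(cfg)
  cl <- generate_plant(plant_recipe(n_points_target = 1500L, seed = 6L))
  fw <- ffnet_forward(model, cl)
  expect_equal(nrow(fw$voxel_logits), nrow(fw$assignment$active_coords))
  counts <- vapply(fw$stage_assignments,
                   function(a) nrow(a$active_coords), 0L)
  expect_true(all(diff(counts) <= 0))      # non-increasing active sites

  solo <- point_cloud(matrix(c(0, 0, 0, 1, 1, 1), 2, byrow = TRUE))
  fw1 <- ffnet_forward(model, solo)
  expect_equal(nrow(fw1$point_logits), 2L)
})
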