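test_that("adaptive voxel features vanish where the definition says so", {
  # three points; the first sits exactly at the bounding-box min corner
  co <- rbind(c(0, 0, 0), c(0.9, 0.9, 0.9), c(0.95, 0.85, 0.9))
  cl <- point_cloud(co)
  a <- voxel_assign(cl, fit_grid(cl, 2L, pad = 0))
  f9 <- voxel_feature_encoder(cl, a)
  expect_equal(dim(f9), c(3L, 9L))
  expect_equal(f9[, 1:3], co)                       # raw coordinates block
  expect_equal(f9[1, 4:6], c(0, 0, 0))              # alone in its voxel
  expect_equal(f9[1, 7:9], c(0, 0, 0))              # exactly at the corner
  # two points sharing a voxel: centred offsets are opposite
  expect_equal(f9[2, 4:6], -f9[3, 4:6])
  # identity reduction: voxel feature = elementwise max of member rows
  vf <- scatter_max(f9, a)
  shared <- a$point_to_voxel[2]
  expect_equal(vf[shared, ], pmax(f9[2, ], f9[3, ]))
})

test_that("mini-PointNet is a pointwise map", {
  model <- ffnet_init(small_config())
  set.seed(4)
  x <- matrix(runif(60), ncol = 3)
  f <- mini_pointnet(x, model)
  expect_equal(nrow(f), 20L)
  expect_equal(mini_pointnet(x[c(1, 1, 5), ], model), f[c(1, 1, 5), ])
  perm <- sample(20)
  expect_equal(mini_pointnet(x[perm, ], model), f[perm, ])
})

test_that("VPN block matches a hand-rolled gather+concat+mix and residual", {
  cfg <- small_config()
  model <- ffnet_init(cfg)
  C <- cfg$widths[1L]
  set.seed(9)
  n <- 12L
  p2v <- c(rep(1L, 7), rep(2L, 5))                 # two-voxel toy case
  fp <- matrix(rnorm(n * C), ncol = C)
  vf <- matrix(rnorm(2L * C), ncol = C)
  out <- ffnet:::vpn_node(model, 1L, ffnet:::ag_const(fp),
                          ffnet:::ag_const(vf), p2v)$value
  W <- model$params[["vpn1.W"]]$value
  b <- as.numeric(model$params[["vpn1.b"]]$value)
  pre <- cbind(fp, vf[p2v, ]) %*% W + matrix(b, n, C, byrow = TRUE)
  sl <- cfg$lrelu_slope
  expect_equal(out, fp + pre * (sl + (1 - sl) * (pre > 0)), tolerance = 1e-12)
  # all points in one voxel: identical context everywhere
  one <- ffnet:::vpn_node(model, 1L, ffnet:::ag_const(fp),
                          ffnet:::ag_const(vf[1, , drop = FALSE]),
                          rep(1L, n))$value - fp
  expect_equal(one, (cbind(fp, vf[rep(1L, n), ]) %*% W +
                       matrix(b, n, C, byrow = TRUE)) |>
                 (\(m) m * (sl + (1 - sl) * (m > 0)))())
  # zero voxel features and zero mixing weights: residual path only
  zero <- model
  zero$params[["vpn1.W"]]$value[] <- 0
  zero$params[["vpn1.b"]]$value[] <- 0
  expect_equal(ffnet:::vpn_node(zero, 1L, ffnet:::ag_const(fp),
                                ffnet:::ag_const(0 * vf), p2v)$value, fp)
})

test_that("attention fusion is a convex per-channel blend", {
  set.seed(11)
  fv <- matrix(rnorm(12), 4, 3)
  fp <- matrix(rnorm(12), 4, 3)
  eq <- attention_fusion(fv, fp)                    # zero scores
  expect_equal(eq$alpha_v, matrix(0.5, 4, 3))
  expect_equal(eq$fused, (fv + fp) / 2)

  sat <- attention_fusion(fv, fp, score_v = matrix(1e4, 4, 3),
                          score_p = matrix(-1e4, 4, 3))
  expect_equal(sat$fused, fv)                       # saturated towards voxel

  sv <- matrix(rnorm(12), 4, 3)
  sp <- matrix(rnorm(12), 4, 3)
  got <- attention_fusion(fv, fp, sv, sp)
  # explicit two-way softmax per channel
  av <- exp(sv) / (exp(sv) + exp(sp))
  expect_equal(got$alpha_v, av, tolerance = 1e-12)
  expect_equal(got$alpha_v + got$alpha_p, matrix(1, 4, 3))
  expect_equal(got$fused, av * fv + (1 - av) * fp, tolerance = 1e-12)
  expect_true(all(got$fused <= pmax(fv, fp) + 1e-12 &
                    got$fused >= pmin(fv, fp) - 1e-12))
})

test_that("forward pass obeys the shape contract and permutation equivariance", {
  cfg <- small_config()
  model <- ffnet_init(cfg)
  cl <- generate_plant(plant_recipe(n_points_target = 1200L, seed = 13L))
  fw <- ffnet_forward(model, cl)
  n <- nrow(cl$coords)
  expect_equal(dim(fw$point_logits), c(n, 3L))
  expect_equal(dim(fw$voxel_logits),
               c(nrow(fw$assignment$active_coords), 3L))
  expect_true(all(abs(fw$alpha_v - 0.5) <= 0.5))    # alpha in [0, 1]

  set.seed(3)
  perm <- sample(n)
  cp <- point_cloud(cl$coords[perm, ], cl$labels[perm], cl$class_names)
  fwp <- ffnet_forward(model, cp)
  expect_equal(fwp$point_logits, fw$point_logits[perm, ], tolerance = 1e-8)
})

test_that("initialisation and forward are reproducible for a fixed seed", {
  cfg <- small_config()
  cl <- generate_plant(plant_recipe(n_points_target = 600L, seed = 21L))
  m1 <- ffnet_init(cfg)
  m2 <- ffnet_init(cfg)
  for (nm in names(m1$params))
    expect_identical(m1$params[[nm]]$value, m2$params[[nm]]$value)
  expect_identical(ffnet_forward(m1, cl)$point_logits,
                   ffnet_forward(m2, cl)$point_logits)
})

test_that("label decoding takes the argmax with low-index ties", {
  expect_equal(predict_labels(rbind(c(0, 5, 1))), 1L)
  expect_equal(predict_labels(rbind(c(2, 2, 2))), 0L)
  hot <- diag(3)[c(2, 3, 1, 3), ]
  expect_equal(predict_labels(hot), c(1L, 2L, 0L, 2L))
})

test_that("voxel labels are the member majority with low-class ties", {
  co <- matrix(runif(18), ncol = 3)
  a <- structure(list(point_to_voxel = c(1L, 1L, 1L, 2L, 2L, 3L),
                      active_coords = matrix(0L, 3, 3)),
                 class = "voxel_assignment")
  expect_equal(voxel_labels(c(2L, 2L, 0L, 1L, 2L, 0L), a), c(2L, 1L, 0L))
  # tie between classes 1 and 2 goes to the smaller id
  expect_equal(voxel_labels(c(1L, 2L, 1L, 2L, 2L, 1L), a)[1], 1L)
})

test_that("checkpoints round-trip parameters and predictions bit-exactly", {
  cfg <- small_config()
  model <- ffnet_init(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  ffnet_save(model, f)
  back <- ffnet_load(f)
  for (nm in names(model$params))
    expect_identical(back$params[[nm]]$value, model$params[[nm]]$value)
  cl <- generate_plant(plant_recipe(n_points_target = 500L, seed = 30L))
  expect_identical(ffnet_forward(back, cl)$point_logits,
                   ffnet_forward(model, cl)$point_logits)
})
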