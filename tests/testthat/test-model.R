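test_that("the conv stack shrinks the timebase by the stride product", {
  g <- tiny_grammar()
  cfg <- xchar_config(concepts = LETTERS[1:6], classes = letters[1:5])
  expect_equal(t_prime_len(1024L, cfg), 256L)
  expect_equal(t_prime_len(1023L, cfg), 256L)
  expect_equal(t_prime_len(10L, cfg), 3L)
})

test_that("forward outputs are valid distributions of the right shape", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  x <- matrix(rnorm(2 * 41), 2)
  pred <- predict(m, x)
  expect_equal(nrow(pred$concept_matrix), t_prime_len(41L, cfg))
  expect_equal(ncol(pred$concept_matrix), 4)  # 3 concepts + blank
  expect_equal(unname(rowSums(pred$concept_matrix)),
               rep(1, nrow(pred$concept_matrix)), tolerance = 1e-6)
  expect_equal(sum(pred$class_probs), 1, tolerance = 1e-6)
  # zero input stays numerically sane
  pred0 <- predict(m, matrix(0, 2, 41))
  expect_false(anyNA(pred0$concept_matrix))
  expect_false(anyNA(pred0$class_probs))
})

test_that("building twice from one seed gives identical models", {
  m1 <- build_model(tiny_config(seed = 5))
  m2 <- build_model(tiny_config(seed = 5))
  expect_identical(m1$params, m2$params)
  x <- matrix(rnorm(2 * 30), 2)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("a batch of identical windows yields identical outputs", {
  m <- build_model(tiny_config())
  x <- matrix(rnorm(2 * 36), 2)
  fwd <- xchar:::model_forward(m, list(x, x))
  expect_equal(fwd$class_logP[1, ], fwd$class_logP[2, ], tolerance = 1e-12)
  rows1 <- 1:fwd$t2[1]
  rows2 <- (fwd$off[2] + 1):(fwd$off[2] + fwd$t2[2])
  expect_equal(fwd$P[rows1, ], fwd$P[rows2, ], tolerance = 1e-12)
})

test_that("permuting channels together with per-sensor weights is a no-op", {
  m <- build_model(tiny_config())
  x <- matrix(rnorm(2 * 36), 2)
  perm <- c(2L, 1L)
  m2 <- m
  # conv1 is per-sensor, so weight s must follow channel s; the cross-sensor
  # conv consumes blocks of conv1 filters per sensor, so its kernel blocks
  # move with the channels too
  for (s in seq_along(perm)) {
    m2$params[[paste0("conv1_W_", s)]] <- m$params[[paste0("conv1_W_", perm[s])]]
    m2$params[[paste0("conv1_b_", s)]] <- m$params[[paste0("conv1_b_", perm[s])]]
  }
  f1 <- m$config$conv1_filters; K <- m$config$conv2_kernel
  # conv2_W rows are ordered (channel-block c, kernel offset k); remap the
  # channel blocks according to the permutation
  cols_of_sensor <- function(s) ((s - 1) * f1 + 1):(s * f1)
  row_block <- function(c) ((c - 1) * K + 1):(c * K)
  W2 <- m$params$conv2_W
  W2p <- W2
  for (s in seq_along(perm)) {
    src_channels <- cols_of_sensor(perm[s])
    dst_channels <- cols_of_sensor(s)
    for (j in seq_along(src_channels)) {
      W2p[row_block(dst_channels[j]), ] <- W2[row_block(src_channels[j]), ]
    }
  }
  m2$params$conv2_W <- W2p
  p1 <- predict(m, x)
  p2 <- predict(m2, x[perm, ])
  expect_equal(p1$class_probs, p2$class_probs, tolerance = 1e-12)
  expect_equal(unclass(p1$concept_matrix), unclass(p2$concept_matrix),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  cfg <- tiny_config(seed = 3)
  m <- build_model(cfg)
  xs <- list(matrix(rnorm(2 * 29), 2), matrix(rnorm(2 * 37), 2))
  targets <- list(c("A", "B"), c("C", "A", "A"))
  y <- c(1L, 2L)
  loss_of <- function(mm) {
    fwd <- xchar:::model_forward(mm, xs, with_cache = TRUE)
    xchar:::model_backward(mm, xs, targets, y, fwd)
  }
  ref <- loss_of(m)
  eps <- 1e-6
  for (nm in names(m$params)) {
    ks <- sample(seq_along(m$params[[nm]]), min(2, length(m$params[[nm]])))
    for (k in ks) {
      mp <- m; mp$params[[nm]][k] <- m$params[[nm]][k] + eps
      mn <- m; mn$params[[nm]][k] <- m$params[[nm]][k] - eps
      num <- (loss_of(mp)$loss - loss_of(mn)$loss) / (2 * eps)
      expect_equal(ref$grads[[nm]][k], num, tolerance = 1e-4,
                   info = paste("param", nm, "index", k))
    }
  }
})

test_that("training logs a history satisfying the loss decomposition", {
  d <- tiny_windows(n_per_class = 4, seed = 2)
  cfg <- tiny_config(seed = 1, epochs = 2)
  m <- train_model(build_model(cfg), d, d, verbose = FALSE)
  h <- m$history
  expect_equal(nrow(h), 2)
  expect_equal(h$loss,
               cfg$beta * h$class_loss + (1 - cfg$beta) * h$concept_loss,
               tolerance = 1e-6)
  expect_true(all(is.finite(h$loss)))
  expect_true(all(h$val_macro_f1 >= 0 & h$val_macro_f1 <= 1))
})

test_that("training is reproducible under a fixed seed", {
  d <- tiny_windows(n_per_class = 3, seed = 4)
  m1 <- train_model(build_model(tiny_config(seed = 9)), d, epochs = 1)
  m2 <- train_model(build_model(tiny_config(seed = 9)), d, epochs = 1)
  expect_identical(m1$params, m2$params)
})

test_that("invalid inputs are rejected", {
  m <- build_model(tiny_config())
  expect_error(predict(m, matrix(0, 5, 30)), "channels")
  expect_error(predict(m, matrix(0, 2, 2)), "too short")
  d <- tiny_windows(n_per_class = 2, seed = 2)
  # a window whose concept sequence cannot fit its output timebase
  bad <- sensor_window(matrix(0, 2, 8), "one", rep(c("A", "A"), 3))
  expect_error(train_model(build_model(tiny_config()), c(d, list(bad))),
               "CTC-infeasible")
  # class outside the model's label set
  alien <- sensor_window(matrix(0, 2, 30), "zz", c("A", "B"))
  expect_error(train_model(build_model(tiny_config()), c(d, list(alien))),
               "not in the model's classes")
})

test_that("argmax prediction breaks ties toward the lowest class index", {
  m <- build_model(tiny_config())
  # degenerate zero-variance input: whatever the probabilities, the label
  # must be the first maximal class
  pred <- predict(m, matrix(0, 2, 30))
  expect_equal(pred$class_label,
               m$config$classes[which.max(pred$class_probs)])
})

test_that("checkpoints round-trip through disk", {
  d <- tiny_windows(n_per_class = 2, seed = 6)
  m <- train_model(build_model(tiny_config(seed = 2)), d, epochs = 1)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m$params, m2$params, tolerance = 0)
  expect_equal(m$norm, m2$norm, tolerance = 0)
  x <- d[[1]]$values
  expect_identical(predict(m, x), predict(m2, x))
})
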