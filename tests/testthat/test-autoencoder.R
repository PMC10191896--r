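# Network construction, training, encode/decode, gradients.

test_that("default architecture has the expected weight shapes", {
  m <- build_autoencoder(ae_config(seed = 1))
  shapes <- purrr::map(m$weights, ~dim(.x$W))
  expect_equal(shapes, list(
    c(75L, 75L), c(75L, 40L), c(40L, 24L), c(24L, 3L),
    c(3L, 24L), c(24L, 40L), c(40L, 75L), c(75L, 75L)
  ))
  # decoder widths are the reverse of the encoder widths
  expect_equal(m$config$layer_sizes_decoder, rev(m$config$layer_sizes_encoder))
  expect_equal(m$activations,
               c("relu", "relu", "relu", "sigmoid",
                 "relu", "relu", "relu", "sigmoid"))
})

test_that("initialization is seed-deterministic", {
  a <- build_autoencoder(ae_config(seed = 7))
  b <- build_autoencoder(ae_config(seed = 7))
  c <- build_autoencoder(ae_config(seed = 8))
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, c$weights))
})

test_that("inconsistent layer sizes are rejected", {
  expect_error(ae_config(layer_sizes_encoder = c(75, 40, 3),
                         layer_sizes_decoder = c(2, 40, 75)), "bottleneck")
  expect_error(ae_config(layer_sizes_encoder = c(75, 40, 3),
                         layer_sizes_decoder = c(3, 40, 60)), "first encoder")
})

test_that("zero learning rate performs no update", {
  withr::with_seed(3, X <- matrix(runif(40 * 6), 40, 6))
  cfg <- ae_config(layer_sizes_encoder = c(6, 4, 3),
                   layer_sizes_decoder = c(3, 4, 6),
                   iterations_per_epoch = 10, seed = 3)
  m0 <- build_autoencoder(cfg)
  # full-batch so every iteration sees the same data: loss history constant
  m <- ae_train(m0, X, epochs = 3, learning_rate = 0, batch_size = 40)
  expect_equal(length(m$loss_history), 30L)
  expect_lt(max(m$loss_history) - min(m$loss_history), 1e-12)
  # weights untouched except the data-mean output bias set before step 1
  expect_identical(m$weights[[1]], m0$weights[[1]])
  expect_equal(reconstruction_loss(m, X), m$loss_history[1], tolerance = 1e-12)
})

test_that("rank-1 data is reconstructed nearly perfectly", {
  X <- matrix(rep(seq(0.1, 0.9, length.out = 8), each = 50), nrow = 50)
  cfg <- ae_config(layer_sizes_encoder = c(8, 5, 3),
                   layer_sizes_decoder = c(3, 5, 8),
                   iterations_per_epoch = 10, seed = 2)
  m <- ae_train(build_autoencoder(cfg), X, epochs = 40)
  expect_lt(reconstruction_loss(m, X), 1e-4)
})

test_that("training reduces the loss on a compressible synthetic cohort", {
  gen <- generate_cohort(synthetic_config(n_patients = 400, seed = 9))
  cm <- curate_cohort(gen$cohort)
  m0 <- build_autoencoder(ae_config(seed = 9))
  m <- ae_train(m0, cm, epochs = 15)
  expect_equal(length(m$loss_history), 15L * 60L)
  expect_lt(reconstruction_loss(m, cm), reconstruction_loss(m0, cm))
})

test_that("training errors when the cohort is smaller than the batch", {
  X <- matrix(runif(5 * 4), 5, 4)
  cfg <- ae_config(layer_sizes_encoder = c(4, 3), layer_sizes_decoder = c(3, 4),
                   batch_size = 10, seed = 1)
  expect_error(ae_train(build_autoencoder(cfg), X), "smaller batch")
})

test_that("encoding gives n x 3 coordinates in (0, 1), deterministically", {
  gen <- generate_cohort(synthetic_config(n_patients = 80, seed = 12))
  cm <- curate_cohort(gen$cohort)
  m <- ae_train(build_autoencoder(ae_config(seed = 12)), cm, epochs = 2)
  e1 <- ae_encode(m, cm)
  e2 <- ae_encode(m, cm)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), nrow(cm$features))
  lat <- as.matrix(e1[, c("x", "y", "z")])
  expect_true(all(lat > 0 & lat < 1))
  expect_equal(e1$patient_id, cm$patient_ids)
  expect_error(ae_encode(m, cm$features[, 1:10]), "expects")
})

test_that("decode maps back to (0,1) and the loss matches a manual recomputation", {
  gen <- generate_cohort(synthetic_config(n_patients = 60, seed = 13))
  cm <- curate_cohort(gen$cohort)
  m <- ae_train(build_autoencoder(ae_config(seed = 13)), cm, epochs = 2)
  emb <- ae_encode(m, cm)
  rec <- ae_decode(m, emb)
  expect_equal(dim(rec), dim(cm$features))
  expect_true(all(rec > 0 & rec < 1))
  # loss two ways: via the operation vs a hand-rolled loop over residuals
  manual <- 0
  for (i in seq_len(nrow(rec))) {
    manual <- manual + sum((cm$features[i, ] - rec[i, ])^2)
  }
  manual <- manual / length(rec)
  expect_equal(reconstruction_loss(m, cm), manual, tolerance = 1e-12)
  expect_gte(reconstruction_loss(m, cm), 0)
  expect_error(ae_decode(m, matrix(0.5, 2, 5)), "decoder expects")
})

test_that("a hand-built identity network reconstructs perfectly", {
  cfg <- ae_config(layer_sizes_encoder = c(3, 3), layer_sizes_decoder = c(3, 3),
                   hidden_activation = "linear", bottleneck_activation = "linear",
                   output_activation = "linear", seed = 1)
  m <- build_autoencoder(cfg)
  m$weights[[1]]$W <- diag(3); m$weights[[1]]$b <- rep(0, 3)
  m$weights[[2]]$W <- diag(3); m$weights[[2]]$b <- rep(0, 3)
  X <- matrix(runif(30), 10, 3)
  expect_equal(reconstruction_loss(m, X), 0)
})

test_that("analytic gradients match central finite differences on a small net", {
  cfg <- ae_config(layer_sizes_encoder = c(4, 3, 2),
                   layer_sizes_decoder = c(2, 3, 4), seed = 5)
  m <- build_autoencoder(cfg)
  withr::with_seed(1, X <- matrix(runif(7 * 4), 7, 4))
  bw <- nephroscape:::ae_gradients(m, X)
  h <- 1e-5
  max_rel <- 0
  for (l in seq_along(m$weights)) {
    for (p in c("W", "b")) {
      for (i in seq_along(m$weights[[l]][[p]])) {
        mp <- m; mp$weights[[l]][[p]][i] <- mp$weights[[l]][[p]][i] + h
        mm <- m; mm$weights[[l]][[p]][i] <- mm$weights[[l]][[p]][i] - h
        fd <- (reconstruction_loss(mp, X) - reconstruction_loss(mm, X)) / (2 * h)
        if (abs(fd) > 1e-8) {
          max_rel <- max(max_rel, abs(bw$grads[[l]][[p]][i] - fd) / abs(fd))
        }
      }
    }
  }
  expect_lt(max_rel, 1e-4)
})

test_that("training is bit-reproducible given (seed, data, config)", {
  gen <- generate_cohort(synthetic_config(n_patients = 100, seed = 17))
  cm <- curate_cohort(gen$cohort)
  m1 <- ae_train(build_autoencoder(ae_config(seed = 17)), cm, epochs = 3)
  m2 <- ae_train(build_autoencoder(ae_config(seed = 17)), cm, epochs = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(ae_encode(m1, cm), ae_encode(m2, cm))
})

test_that("tidy and glance summarize the fit", {
  m <- build_autoencoder(ae_config(seed = 1))
  td <- tidy(m)
  expect_equal(nrow(td), 8L)
  expect_equal(sum(td$n_parameters), glance(m)$n_parameters)
  expect_equal(td$half, rep(c("encoder", "decoder"), each = 4))
  expect_false(glance(m)$trained)
})
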