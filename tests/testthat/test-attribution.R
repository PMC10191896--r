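# Encoder Jacobian, contribution rates, plane selection, titer exclusion.

test_that("jacobian of an all-linear encoder equals the weight-matrix product", {
  m <- tiny_model(d = 6, sizes = c(6, 4, 3), hidden = "linear", bottleneck = "linear")
  closed_form <- t(m$weights[[1]]$W %*% m$weights[[2]]$W)
  withr::with_seed(2, {
    inputs <- purrr::map(1:5, ~runif(6))
    Js <- purrr::map(inputs, ~encoder_jacobian(m, .x))
    for (J in Js) expect_equal(unname(J), unname(closed_form), tolerance = 1e-12)
    # constant across inputs
    pair_diff <- max(abs(Js[[1]] - Js[[5]]))
    expect_lt(pair_diff, 1e-10)
  })
})

test_that("a dead input column yields a zero jacobian column", {
  m <- tiny_model(d = 5, sizes = c(5, 4, 3))
  m$weights[[1]]$W[2, ] <- 0
  J <- encoder_jacobian(m, runif(5))
  expect_equal(unname(J[, 2]), rep(0, 3))
})

test_that("jacobian matches central finite differences on a random network", {
  m <- tiny_model(d = 6, sizes = c(6, 5, 3), seed = 31)
  withr::with_seed(4, x <- runif(6, 0.2, 0.8))
  J <- encoder_jacobian(m, x)
  h <- 1e-5
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fd <- (as.matrix(ae_encode(m, matrix(xp, 1))[, 2:4]) -
           as.matrix(ae_encode(m, matrix(xm, 1))[, 2:4])) / (2 * h)
    rel <- abs(J[, i] - as.vector(fd)) / pmax(abs(as.vector(fd)), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
  expect_error(encoder_jacobian(m, runif(4)), "expects")
})

test_that("contribution rates are the absolute value of the mean derivative", {
  m <- tiny_model(d = 4, sizes = c(4, 3, 3))
  withr::with_seed(6, X <- matrix(runif(12, 0.2, 0.8), 3, 4,
                                  dimnames = list(NULL, paste0("it", 1:4))))
  # subset of one: rates equal that patient's |jacobian|
  one <- contribution_rates(m, X, subset = 1L)
  J1 <- abs(encoder_jacobian(m, X[1, ]))
  expect_equal(one$X, unname(J1[1, ]))
  expect_equal(one$Y, unname(J1[2, ]))
  expect_equal(one$Z, unname(J1[3, ]))
  expect_true(all(c(one$X, one$Y, one$Z) >= 0))
  expect_error(contribution_rates(m, X, subset = rep(FALSE, 3)), "non-empty")
})

test_that("two patients with opposite-sign derivatives yield rate zero for the item", {
  # hinge encoder: hidden units relu(x1 - 0.5) and relu(0.5 - x1), each
  # latent unit their sum. The derivative w.r.t. item 1 is +1 for a patient
  # with x1 > 0.5 and -1 for one with x1 < 0.5; item 2 is disconnected.
  cfg <- ae_config(layer_sizes_encoder = c(2, 2, 3),
                   layer_sizes_decoder = c(3, 2, 2),
                   hidden_activation = "relu", bottleneck_activation = "linear",
                   seed = 1)
  m <- build_autoencoder(cfg)
  m$weights[[1]]$W <- rbind(c(1, -1), c(0, 0))
  m$weights[[1]]$b <- c(-0.5, 0.5)
  m$weights[[2]]$W <- matrix(1, 2, 3)
  m$weights[[2]]$b <- rep(0, 3)
  X <- rbind(c(0.8, 0.3), c(0.2, 0.3))
  colnames(X) <- c("item1", "item2")
  JA <- encoder_jacobian(m, X[1, ])
  JB <- encoder_jacobian(m, X[2, ])
  expect_equal(unname(JA[, 1]), rep(1, 3))
  expect_equal(unname(JB[, 1]), rep(-1, 3))

  rates <- contribution_rates(m, X)
  # absolute of the mean: exact cancellation, NOT mean of absolutes (= 1)
  expect_equal(rates$X[rates$item_id == "item1"], 0)
  expect_equal(rates$Y[rates$item_id == "item1"], 0)
  expect_equal(rates$Z[rates$item_id == "item1"], 0)

  # Jensen: |mean| <= mean of absolutes, cell-wise
  mean_abs <- (abs(JA) + abs(JB)) / 2
  mean_signed <- abs((JA + JB) / 2)
  expect_true(all(mean_signed <= mean_abs + 1e-12))
})

test_that("contribution table against a per-sample finite-difference oracle", {
  m <- tiny_model(d = 5, sizes = c(5, 4, 3), seed = 77)
  withr::with_seed(8, X <- matrix(runif(30, 0.1, 0.9), 6, 5,
                                  dimnames = list(NULL, paste0("item", 1:5))))
  rates <- contribution_rates(m, X)
  h <- 1e-6
  fd_mean <- matrix(0, 3, 5)
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      xp <- X[i, ]; xp[j] <- xp[j] + h
      xm <- X[i, ]; xm[j] <- xm[j] - h
      d <- (as.matrix(ae_encode(m, matrix(xp, 1))[, 2:4]) -
            as.matrix(ae_encode(m, matrix(xm, 1))[, 2:4])) / (2 * h)
      fd_mean[, j] <- fd_mean[, j] + as.vector(d) / nrow(X)
    }
  }
  expect_equal(rates$X, abs(fd_mean[1, ]), tolerance = 1e-6)
  expect_equal(rates$Y, abs(fd_mean[2, ]), tolerance = 1e-6)
  expect_equal(rates$Z, abs(fd_mean[3, ]), tolerance = 1e-6)
  # signed means respect the X/Y/Z sign convention (X = -x, Y = -y, Z = z)
  signed <- attr(rates, "signed_means")
  expect_equal(signed$X, -fd_mean[1, ], tolerance = 1e-6)
  expect_equal(signed$Z, fd_mean[3, ], tolerance = 1e-6)
  expect_equal(rates$X, abs(signed$X))
})

test_that("axis convention is an involution on x and y", {
  s <- axis_convention()
  expect_equal(unname(s[c("x", "y")] * s[c("x", "y")]), c(1, 1))
  expect_equal(unname(s[["z"]]), 1)
})

test_that("top_contributors ranks deterministically and handles edge cases", {
  tbl <- tibble::tibble(item_id = paste0("i", 1:4),
                        X = c(0.2, 0.5, 0.5, 0.1),
                        Y = c(0, 0, 0, 0.3),
                        Z = rep(0.1, 4))
  class(tbl) <- c("contribution_table", class(tbl))
  top <- top_contributors(tbl, 2)
  # ties broken by table order: i2 before i3
  expect_equal(top$item_id[top$feature_vector == "X"], c("i2", "i3"))
  expect_equal(top$item_id[top$feature_vector == "Y"][1], "i4")
  expect_warning(all75 <- top_contributors(tbl, 10), "truncated")
  expect_equal(sort(all75$item_id[all75$feature_vector == "Z"]), paste0("i", 1:4))
  expect_error(top_contributors(tbl, 0), ">= 1")
})

test_that("an input wired with large weights dominates the contribution ranking", {
  m <- tiny_model(d = 8, sizes = c(8, 5, 3), seed = 3)
  m$weights[[1]]$W <- m$weights[[1]]$W * 0.05
  m$weights[[1]]$W[4, ] <- 5 # item 4 drives every first-layer unit
  withr::with_seed(9, X <- matrix(runif(80, 0.3, 0.7), 10, 8,
                                  dimnames = list(NULL, paste0("item", 1:8))))
  top <- top_contributors(contribution_rates(m, X), 1)
  expect_true("item4" %in% top$item_id)
})

test_that("single-item dominance in the data earns a top-3 contribution rate", {
  # a cohort where one bimodal item carries the only coherent structure:
  # the item must surface among the top contributors of some latent axis
  hits <- 0L
  n_runs <- 10L
  for (s in seq_len(n_runs)) {
    X <- withr::with_seed(500 + s, {
      n <- 250
      base <- matrix(runif(n * 75, 0.45, 0.55), n, 75)
      base[, 7] <- sample(c(0.1, 0.9), n, replace = TRUE)
      colnames(base) <- sprintf("item_%02d", 1:75)
      base
    })
    m <- ae_train(build_autoencoder(ae_config(seed = 500 + s)), X, epochs = 10)
    top <- top_contributors(contribution_rates(m, X), 3)
    if ("item_07" %in% top$item_id) hits <- hits + 1L
  }
  expect_gte(hits, n_runs - 1L)
})

test_that("high anti-dsDNA exclusion applies the >= cutoff exactly", {
  gen <- generate_cohort(synthetic_config(n_patients = 300, seed = 61))
  cm <- curate_cohort(gen$cohort)
  emb <- toy_embedding(runif(nrow(cm$cohort)), runif(nrow(cm$cohort)))
  ex <- exclude_high_dsdna(emb, cm)
  expect_equal(ex$n_excluded, sum(cm$cohort$dsdna_titer >= 500))
  expect_equal(nrow(ex$embedding), nrow(emb) - ex$n_excluded)

  # boundary: exactly 500 is excluded; ladder rung 640 is the first to bite
  co <- tiny_record("a")
  co$dsdna_titer <- 500
  co2 <- tiny_record("b")
  co2$dsdna_titer <- 499
  both <- dplyr::bind_rows(co, co2)
  e2 <- exclude_high_dsdna(toy_embedding(c(0.1, 0.2), c(0.1, 0.2)), both)
  expect_equal(e2$excluded, c(TRUE, FALSE))

  none <- dplyr::mutate(both, dsdna_titer = c(40, 80))
  e3 <- exclude_high_dsdna(toy_embedding(c(0.1, 0.2), c(0.1, 0.2)), none)
  expect_equal(e3$n_excluded, 0L)
})

test_that("feature-plane selection finds the titer-gradient axes", {
  withr::with_seed(71, {
    n <- 400
    dsdna <- 40 * 2^sample(0:5, n, replace = TRUE)
    ana <- 40 * 2^sample(0:5, n, replace = TRUE)
    cohort <- tibble::tibble(patient_id = as.character(1:n),
                             dsdna_titer = dsdna, ana_titer = ana)
    emb <- tibble::tibble(
      patient_id = cohort$patient_id,
      x = runif(n),
      y = 0.5 + 0.05 * scale(log2(dsdna))[, 1] + rnorm(n, 0, 0.01),
      z = 0.5 + 0.05 * scale(log2(ana))[, 1] + rnorm(n, 0, 0.01)
    )
    class(emb) <- c("latent_embedding", class(emb))
    sel <- select_feature_plane(emb, cohort)
    expect_equal(sel$x_axis, "y")
    expect_equal(sel$z_axis, "z")
    expect_equal(sel$plane$x, emb$y)
    expect_equal(sel$plane$z, emb$z)
  })
})
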