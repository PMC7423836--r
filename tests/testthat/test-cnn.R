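# Tiny configurations (16x16 input, minimum filters) keep these tests fast;
# the full desk-scale model is exercised in the acceptance suite.
tiny_config <- function(...) {
  suppressWarnings(cnn_config(filters = c(16, 16, 16, 16, 16), filter_size = 3,
                              input_size = 16, fc_sizes = c(16, 8), ...))
}

# Separable toy crops: positives carry a bright block in plane 3.
toy_crops <- function(n_pos, n_neg, size = 16, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    x <- array(runif(size * size * 4 * n, 0, 0.08), c(size, size, 4, n))
    for (i in seq_len(n_pos)) x[5:12, 5:12, 3, i] <- 0.95
    list(x = x, y = rep(c("CTC_POSITIVE", "CTC_NEGATIVE"), c(n_pos, n_neg)))
  })
}

test_that("the model has eight weighted layers and a deterministic weight count", {
  cfg <- cnn_config(seed = 1)
  expect_equal(cfg$n_conv_layers + cfg$n_fc_layers, 8L)
  m <- cnn_build(cfg)
  d <- ctcscope:::layer_dims(cfg)
  expect_length(d$conv, 5); expect_length(d$fc, 3)
  manual <- sum(vapply(d$conv, function(x) x[1] * x[2] + x[1], numeric(1))) +
    sum(vapply(d$fc, function(x) x[1] * x[2] + x[1], numeric(1)))
  expect_equal(m$n_params, manual)
  # weight count is a pure function of the configuration
  expect_equal(cnn_build(cnn_config(seed = 99))$n_params, m$n_params)
  # final layer is the 2-class head
  expect_equal(d$fc[[3]][1], 2)
})

test_that("configuration guards fire on out-of-range choices", {
  expect_warning(cnn_config(filters = c(8, 16, 16, 16, 16)), "16")
  expect_warning(cnn_config(filter_size = 11), "10")
  expect_error(cnn_config(filters = c(16, 16, 16)), "5 convolution")
  expect_error(cnn_config(input_size = 30), "divisible by 8")
  expect_error(cnn_config(filter_size = 4), "odd")
})

test_that("building twice with one seed gives identical weights", {
  a <- cnn_build(tiny_config(seed = 5))
  b <- cnn_build(tiny_config(seed = 5))
  expect_identical(a$weights, b$weights)
  c <- cnn_build(tiny_config(seed = 6))
  expect_false(identical(a$weights, c$weights))
})

test_that("crop extraction centers, pads and stacks channels in fixed order", {
  sim <- simulate_field(sim_params(height = 128, width = 128, n_cells = 1,
                                   ctc_fraction = 1, leukocyte_fraction = 0, noise_sigma = 0,
                                   seed = 21))
  regs <- segment_dapi(sim$stack)
  crop <- extract_crops(sim$stack, regs, size_px = 48)[[1]]
  expect_equal(dim(crop$pixels), c(48, 48, 4))
  expect_length(crop$missing_channels, 0)
  # DAPI plane peaks at the crop center (nucleus centered within +-1 px)
  dapi <- crop$pixels[, , 1]
  peak <- which(dapi == max(dapi), arr.ind = TRUE)
  expect_lt(abs(mean(peak[, 1]) - 24.5), 4)
  expect_lt(abs(mean(peak[, 2]) - 24.5), 4)
  # missing channel becomes a zero plane and is recorded
  stack3 <- sim$stack; stack3$channels$CEP17 <- NULL
  crop3 <- extract_crops(stack3, regs, size_px = 48)[[1]]
  expect_equal(crop3$missing_channels, "CEP17")
  expect_true(all(crop3$pixels[, , 4] == 0))
  # border nucleus: reflective padding still yields the exact size
  px <- matrix(0, 64, 64); px[disk_mask(64, 64, cbind(3, 3), 6)] <- 220
  bstack <- channel_stack(list(DAPI = channel_image(px, "DAPI")))
  breg <- label_nuclei(px > 0, seg_params(min_area_px = 5, max_area_px = 1e4,
                                          exclude_border = FALSE))
  bcrop <- extract_crops(bstack, breg, size_px = 32)[[1]]
  expect_equal(dim(bcrop$pixels), c(32, 32, 4))
})

test_that("training overfits a small separable set and respects zero epochs", {
  toy <- toy_crops(10, 10)
  cfg <- tiny_config(seed = 3)
  fit <- cnn_train(toy$x, toy$y, config = cfg, epochs = 25, lr = 2e-3,
                   batch_size = 5)
  expect_equal(tail(fit$history$accuracy, 1), 1)
  # loss trends down on a separable fixture
  expect_lt(mean(tail(fit$history$loss, 5)), mean(head(fit$history$loss, 5)))
  # zero epochs: the classifier equals its initialization
  f0 <- cnn_train(toy$x, toy$y, config = cfg, epochs = 0)
  expect_identical(f0$weights, cnn_build(cfg)$weights)
  expect_false(f0$trained)
  expect_error(cnn_train(toy$x, rep("CTC_POSITIVE", 20), config = cfg),
               "both classes")
})

test_that("prediction returns simplex probabilities and is input-deterministic", {
  toy <- toy_crops(6, 6)
  fit <- cnn_train(toy$x, toy$y, config = tiny_config(seed = 4), epochs = 8,
                   lr = 2e-3, batch_size = 4)
  p <- predict(fit, toy$x)
  expect_equal(dim(p), c(12, 2))
  expect_equal(unname(rowSums(p)), rep(1, 12), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicate crop, identical output
  dup <- toy$x[, , , c(1, 1), drop = FALSE]
  pd <- predict(fit, dup)
  expect_equal(pd[1, ], pd[2, ])
  cls <- predict(fit, toy$x, type = "class")
  expect_true(all(cls %in% c("CTC_POSITIVE", "CTC_NEGATIVE")))
  expect_error(predict(fit, array(0, c(8, 8, 4, 1))), "input_size")
})

test_that("seeded training is bit-for-bit reproducible", {
  toy <- toy_crops(8, 8)
  cfg <- tiny_config(seed = 11)
  f1 <- cnn_train(toy$x, toy$y, config = cfg, epochs = 4, batch_size = 4)
  f2 <- cnn_train(toy$x, toy$y, config = cfg, epochs = 4, batch_size = 4)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("grid search scores all twelve cells and finds a separating config", {
  toy <- toy_crops(12, 12)
  g <- grid_search_cv(toy$x, toy$y, k = 3, seed = 2,
                      base_config = tiny_config(), epochs = 6, lr = 2e-3,
                      batch_size = 6)
  expect_equal(nrow(g$scores), 12)   # 3 activations x 2 regularizers x 2 factors
  expect_equal(dim(g$table), c(6, 4))
  expect_setequal(unique(g$scores$activation), c("softmax", "ReLU", "tanh"))
  # the selected cell attains the table maximum, with grid-order tie-break
  best_acc <- max(g$scores$mean_accuracy)
  first_best <- which(g$scores$mean_accuracy == best_acc)[1]
  expect_equal(g$best_config$activation, g$scores$activation[first_best])
  expect_equal(g$best_config$regularizer, g$scores$regularizer[first_best])
  expect_equal(g$best_config$reg_factor, g$scores$reg_factor[first_best])
  expect_equal(best_acc, 1)          # separable toy data
  # same seed, same folds, same table
  g2 <- grid_search_cv(toy$x, toy$y, k = 3, seed = 2,
                       base_config = tiny_config(), epochs = 6, lr = 2e-3,
                       batch_size = 6)
  expect_identical(g$scores, g2$scores)
  expect_error(grid_search_cv(toy$x, rep("CTC_NEGATIVE", 24), k = 3, seed = 1,
                              base_config = tiny_config()), "both classes")
})
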