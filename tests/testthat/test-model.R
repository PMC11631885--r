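# Tiny configurations (small kernel/channel counts) keep these unit tests
# fast; the full 151-kernel architecture is exercised in test-acceptance.R.

tiny_cfg <- function() model_config(kernel_size = 15L, channels = 8L)

test_that("model configuration is validated", {
  expect_error(model_config(kernel_size = 150L), "odd")
  expect_error(loss_config(gamma = -1), "gamma")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("output is a valid per-position probability field", {
  m <- build_model(tiny_cfg(), seed = 1)
  v <- as.numeric(runif(1024) > 0.6)
  pl <- classify_vector(m, v)
  expect_length(pl$values, 1024)
  expect_identical(dim(pl$probs), c(1024L, 3L))
  expect_true(all(abs(rowSums(pl$probs) - 1) < 1e-6))
  expect_true(all(pl$values %in% 0:2))
  expect_error(classify_vector(m, v[-1]), "length")
})

test_that("constant input gives constant output; zeroed head ties to class 0", {
  m <- build_model(tiny_cfg(), seed = 2)
  pl <- classify_vector(m, rep(0, 1024))
  expect_lt(max(apply(pl$probs, 2, function(z) diff(range(z)))), 1e-5)
  m0 <- m
  m0$net$head_w[] <- 0
  m0$net$head_b[] <- 0
  pl0 <- classify_vector(m0, as.numeric(runif(1024) > 0.5))
  expect_true(all(pl0$values == 0L))
})

test_that("combined loss matches hand-evaluated values of the formula", {
  cfg <- loss_config(alpha = 0.25, gamma = 2)
  # -ln 0.5 = 0.693147; focal 0.25 * 0.25 * 0.693147 = 0.043322
  expect_equal(combined_loss(c(1, 0, 0), matrix(c(0.5, 0.25, 0.25), 1), cfg),
               0.736469, tolerance = 1e-5)
  expect_equal(combined_loss(c(1, 0, 0), matrix(c(0.9, 0.05, 0.05), 1), cfg),
               0.105624, tolerance = 1e-5)
  # perfect prediction drives the loss to zero
  expect_lt(combined_loss(c(1, 0, 0), matrix(c(1 - 1e-9, 5e-10, 5e-10), 1),
                          cfg), 1e-6)
  # loss is non-negative and collapses to plain CE for confident predictions
  # under a large focusing factor
  p <- matrix(c(0.8, 0.1, 0.1), 1)
  expect_gte(combined_loss(c(1, 0, 0), p, cfg), 0)
  big_gamma <- loss_config(alpha = 0.25, gamma = 50, clip_eps = 1e-9)
  expect_equal(combined_loss(c(1, 0, 0), matrix(c(1 - 1e-9, 5e-10, 5e-10), 1),
                             big_gamma),
               -log(1 - 1e-9), tolerance = 1e-12)
  expect_error(combined_loss(matrix(c(1, 0), 1), p), "shapes")
})

test_that("the C++ training loss agrees with the R reference formula", {
  m <- build_model(tiny_cfg(), seed = 4)
  X <- matrix(as.numeric(runif(2 * 1024) > 0.5), 2, 1024)
  Y <- matrix(sample(0:2, 2 * 1024, replace = TRUE), 2, 1024)
  cpp <- ivdquant:::cpp_nn_eval_loss(m$net, X, Y, 0.25, 2, 1e-7)
  probs <- ivdquant:::cpp_nn_forward(m$net, X)
  ref <- mean(vapply(1:2, function(i) {
    combined_loss(Y[i, ], matrix(probs[i, , ], ncol = 3), loss_config())
  }, numeric(1)))
  expect_equal(cpp, ref, tolerance = 1e-5)
})

test_that("training descends and is reproducible under a fixed seed", {
  p <- phantom_params(narrowed_fraction = 0.3, narrowing_factor = 0.5,
                      jitter_px = 0L, speck_rate = 0L, seed = 77)
  ds <- generate_vector_dataset(p, 10)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 5L, batch_size = 5L,
                       seed = 2L, validation_fraction = 0)
  m1 <- train_ivd_cnn(ds, model = build_model(tiny_cfg(), seed = 2),
                      tcfg = tcfg)
  expect_lt(m1$history$train_loss[5], m1$history$train_loss[1])
  m2 <- train_ivd_cnn(ds, model = build_model(tiny_cfg(), seed = 2),
                      tcfg = tcfg)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_error(train_ivd_cnn(list(), tcfg = tcfg), "empty")
})

test_that("validation split retains the best checkpoint", {
  p <- phantom_params(narrowed_fraction = 0.3, narrowing_factor = 0.5,
                      jitter_px = 0L, speck_rate = 0L, seed = 78)
  ds <- generate_vector_dataset(p, 10)
  m <- train_ivd_cnn(ds, model = build_model(tiny_cfg(), seed = 3),
                     tcfg = train_config(learning_rate = 1e-3, epochs = 4L,
                                         batch_size = 4L, seed = 3L,
                                         validation_fraction = 0.2))
  expect_identical(m$n_train, 8L)
  expect_identical(m$n_val, 2L)
  expect_identical(m$best_epoch, which.min(m$history$val_loss))
})

test_that("per-gap majority vote follows the stated tie rules", {
  gaps <- data.frame(gap_index = 1:3, start_row = c(100L, 200L, 300L),
                     end_row = c(110L, 210L, 310L), width_px = rep(10L, 3),
                     ratio_to_mean = rep(1, 3), label = "unassigned")
  v <- integer(1024)
  v[101:110] <- 2L                      # all narrowed votes
  v[201:205] <- 2L; v[206:210] <- 1L    # 5-5 tie -> narrowed
  v[301:304] <- 2L; v[305:310] <- 1L    # 4-6 -> normal
  out <- detect_narrowed(v, gaps)
  expect_identical(out$label, c("narrowed", "narrowed", "normal"))
  # background-only votes -> unassigned
  out0 <- detect_narrowed(integer(1024), gaps)
  expect_true(all(out0$label == "unassigned"))
})

test_that("checkpoints embed and enforce the model configuration", {
  m <- build_model(tiny_cfg(), seed = 5)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_ivd_cnn(m, tf)
  expect_s3_class(load_ivd_cnn(tf, config = tiny_cfg()), "ivd_cnn")
  expect_error(load_ivd_cnn(tf, config = model_config()), "does not match")
})
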