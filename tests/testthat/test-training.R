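# Training tests run on reduced architectures and small pixel arrays; the
# full-scale end-to-end behavior is exercised by the acceptance suite.

make_blob_data <- function(n_per_class = 8, size = 16, seed = 1) {
  # two visually trivial classes: dark-ish vs bright-ish noise images
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(0, c(size, size, 3, n))
  for (i in seq_len(n_per_class)) {
    x[, , , i] <- array(runif(size^2 * 3, 0.0, 0.4), c(size, size, 3))
    x[, , , n_per_class + i] <- array(runif(size^2 * 3, 0.6, 1.0),
                                      c(size, size, 3))
  }
  list(x = x, y = rep(c("dark", "bright"), each = n_per_class))
}

tiny_cfg <- function(epochs, seed = 1, lr = 1e-3)
  train_config(epochs = epochs, learning_rate = lr, batch_size = 8,
               seed = seed)

test_that("a reduced network separates trivial classes within a few epochs", {
  d <- make_blob_data()
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 4, reduce_cap = 4,
                           input_size = 16)
  fit <- fabnet(d$x, d$y, spec = spec, config = tiny_cfg(5, lr = 5e-3))
  expect_gt(tail(fit$history$accuracy, 1), 0.9)
  expect_equal(nrow(fit$history), 5)
})

test_that("the network overfits four patches and reproduces their labels", {
  set.seed(3)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  y <- c("a", "b", "a", "b")
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 4, reduce_cap = 4,
                           input_size = 16)
  fit <- fabnet(x, y, spec = spec, config = tiny_cfg(30, lr = 5e-3))
  # loss decreases strictly from first to final epoch
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1] - 1e-3)
  expect_equal(predict(fit, x, type = "class"), y)
})

test_that("history length equals the epoch count and loss is recorded", {
  d <- make_blob_data(4)
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 2, reduce_cap = 2,
                           input_size = 16)
  fit <- fabnet(d$x, d$y, spec = spec, config = tiny_cfg(1))
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$loss))
})

test_that("identical seeds and data give identical fits", {
  d <- make_blob_data(4)
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 2, reduce_cap = 2,
                           input_size = 16)
  f1 <- fabnet(d$x, d$y, spec = spec, config = tiny_cfg(2, seed = 7))
  f2 <- fabnet(d$x, d$y, spec = spec, config = tiny_cfg(2, seed = 7))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- fabnet(d$x, d$y, spec = spec, config = tiny_cfg(2, seed = 8))
  expect_false(identical(f1$model$params, f3$model$params))
})

test_that("every optimizer family makes progress on the overfit problem", {
  set.seed(5)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  y <- c("a", "b", "a", "b")
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 2, reduce_cap = 2,
                           input_size = 16)
  for (opt in c("adam", "sgd", "rmsprop", "adamax", "nadam", "adadelta")) {
    lr <- switch(opt, sgd = 0.05, adadelta = 1, 5e-3)
    cfg <- train_config(epochs = 10, learning_rate = lr, batch_size = 4,
                        optimizer = opt, seed = 2)
    fit <- fabnet(x, y, spec = spec, config = cfg)
    expect_lt(tail(fit$history$loss, 1), fit$history$loss[1],
              label = paste("loss decrease under", opt))
  }
})

test_that("prediction records keep provenance and simplex probabilities", {
  co <- make_tiny_cohort(patients = 2, images = 1, size = 64)
  pm <- extract_cohort_patches(co$manifest, file.path(co$dir, "p"),
                               beta = 3, size = 32, seed = 4)
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 4, reduce_cap = 4,
                           input_size = 32)
  fit <- fabnet(pm, spec = spec,
                config = train_config(epochs = 1, batch_size = 8, seed = 1))
  rec <- predict_patches(fit, pm)
  expect_equal(nrow(rec), nrow(pm))
  expect_true(all(abs(rowSums(record_probs(rec)) - 1) < 1e-6))
  expect_identical(rec$patient_id, pm$patient_id)
  expect_identical(rec$image_id, pm$source_image_id)
})

test_that("label/head mismatches and empty manifests are rejected", {
  d <- make_blob_data(2)
  spec3 <- tiny_fabnet_spec(3, n_pairs = 1, base_filters = 2, reduce_cap = 2,
                            input_size = 16)
  expect_error(fabnet(d$x, d$y, spec = spec3, config = tiny_cfg(1)),
               "label error")
  expect_error(fabnet(data.frame(), config = tiny_cfg(1)), "data error")
})

test_that("a split plan keeps test patients out of training", {
  co <- make_tiny_cohort(patients = 3, images = 1, size = 64)
  pm <- extract_cohort_patches(co$manifest, file.path(co$dir, "p"),
                               beta = 2, size = 32, seed = 4)
  plan <- make_patient_split(co$manifest, 0.7, seed = 5)
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 2, reduce_cap = 2,
                           input_size = 32)
  fit <- fabnet(pm, spec = spec,
                config = train_config(epochs = 1, batch_size = 8, seed = 1),
                split = plan)
  expect_equal(fit$audit$excluded_test_patients, plan$test_patients)
  expect_equal(fit$n_train,
               sum(pm$patient_id %in% plan$train_patients))
})

test_that("print, summary, coef and plot methods work on a fit", {
  d <- make_blob_data(2)
  spec <- tiny_fabnet_spec(2, n_pairs = 1, base_filters = 2, reduce_cap = 2,
                           input_size = 16)
  fit <- fabnet(d$x, d$y, spec = spec, config = tiny_cfg(1))
  expect_output(print(fit), "Fitted feature-agglomeration network")
  expect_output(summary(fit), "Training history")
  expect_type(coef(fit), "list")
  expect_true("head.W" %in% names(coef(fit)))
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
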