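test_that("presets reproduce the published layer stacks", {
  cnn4 <- preset_spec("CNN4")$layers
  expect_identical(vapply(cnn4, `[[`, "", "kind"),
                   c("conv1d", "conv1d", "conv1d", "maxpool1d", "flatten",
                     "dropout", "dense"))
  expect_true(all(vapply(cnn4[1:3], `[[`, 1L, "filters") == 250L))
  expect_true(all(vapply(cnn4[1:3], `[[`, 1L, "kernel") == 5L))
  expect_identical(cnn4[[4]]$pool, 3L)
  expect_identical(cnn4[[6]]$rate, 0.20)

  dnn3 <- preset_spec("DNN3")$layers
  expect_identical(vapply(dnn3, `[[`, "", "kind"),
                   c("flatten", "dense", "dense", "dense", "dense", "dropout",
                     "dense"))
  expect_identical(vapply(dnn3[2:5], `[[`, 1L, "units"),
                   c(256L, 352L, 32L, 352L))

  for (nm in preset_names()) {
    last <- rev(preset_spec(nm)$layers)[[1]]
    expect_identical(last[c("kind", "units", "activation")],
                     list(kind = "dense", units = 2L, activation = "sigmoid"))
  }
  expect_true(all(vapply(preset_spec("DNN4")$layers[2:4], `[[`, "",
                         "initializer") == "random_normal"))
  expect_error(preset_spec("CNN9"), "CNN1")
})

test_that("submodel_spec enforces structural invariants", {
  expect_error(submodel_spec("CNN_x", list(conv1d(4, 3), dense(3))),
               "dense\\(2")
  expect_error(submodel_spec("CNN5", list(flatten(), dense(2, "sigmoid"))),
               "start with a conv1d")
  expect_error(submodel_spec("DNN5", list(conv1d(4, 3), dense(2, "sigmoid"))),
               "start with a flatten")
})

test_that("inverse_time_decay matches its closed form", {
  cnn <- lr_schedule(0.001, 140, 0.1)
  dnn <- lr_schedule(0.002, 80, 1.4)
  expect_identical(inverse_time_decay(cnn, 0), 0.001)
  expect_equal(inverse_time_decay(cnn, 1400), 0.0005, tolerance = 1e-12)
  expect_equal(inverse_time_decay(dnn, 80), 0.002 / 2.4, tolerance = 1e-12)
  steps <- c(0:50, round(seq(51, 1e5, length.out = 400)))
  for (s in list(cnn, dnn)) {
    ## independent algebraic form: initial * steps / (steps + rate * step)
    ref <- s$initial_rate * s$decay_steps /
      (s$decay_steps + s$decay_rate * steps)
    expect_equal(inverse_time_decay(s, steps), ref, tolerance = 1e-12)
    expect_true(all(diff(inverse_time_decay(s, steps)) < 0))
  }
})

test_that("build_submodel: shape contract, determinism, pooling guard", {
  m <- build_submodel("CNN1", 140, seed = 5)
  X <- encode_one_hot(tiny_dataset(3, 140, cp = c(71L, 72L)))
  expect_identical(dim(predict_proba(m, X)), c(6L, 2L))
  m2 <- build_submodel("CNN1", 140, seed = 5)
  expect_identical(m$layers, m2$layers)
  m3 <- build_submodel("CNN1", 140, seed = 6)
  expect_false(identical(m$layers, m3$layers))
  expect_error(build_submodel("CNN2", 4), "incompatibility")
})

test_that("training learns separable data and respects the config", {
  L <- 24
  motif <- default_motif("donor", L, c(11, 12))
  ds <- generate_dataset(synthetic_config(150, L, "donor", 1, seed = 8), motif)
  batch <- encode_one_hot(ds)

  m0 <- train_submodel(build_submodel("CNN3", L, seed = 1), batch, ds$labels,
                       quick_config(max_epochs = 0))
  expect_false(m0$trained)
  expect_identical(nrow(m0$history), 0L)

  m <- train_submodel(build_submodel("CNN3", L, seed = 1), batch, ds$labels,
                      quick_config(max_epochs = 3, seed = 1))
  expect_true(m$trained)
  expect_true(all(c("epoch", "loss", "val_loss", "val_acc") %in%
                  names(m$history)))
  expect_gt(utils::tail(m$history$val_acc, 1), 0.9)

  ## reproducibility: same data + seeds -> identical predictions
  m2 <- train_submodel(build_submodel("CNN3", L, seed = 1), batch, ds$labels,
                       quick_config(max_epochs = 3, seed = 1))
  expect_identical(predict_proba(m, batch), predict_proba(m2, batch))

  expect_error(train_submodel(build_submodel("CNN3", L, seed = 1), batch,
                              rep(1L, length(ds)), quick_config()),
               "degenerate")
})

test_that("every preset reaches 0.95 training accuracy on separable records", {
  L <- 24
  motif <- default_motif("donor", L, c(11, 12), sharpness = 1)
  ds <- generate_dataset(synthetic_config(100, L, "donor", 1, seed = 17), motif)
  batch <- encode_one_hot(ds)
  for (nm in preset_names()) {
    m <- train_submodel(build_submodel(nm, L, seed = 2), batch, ds$labels,
                        quick_config(max_epochs = 10, seed = 2,
                                     early_stop_patience = 10))
    acc <- mean(predict_binary(m, batch) == ds$labels)
    expect_gt(acc, 0.95 - 1e-9, label = sprintf("%s training accuracy", nm))
  }
})

test_that("predict_binary: argmax with ties toward 0", {
  L <- 10
  tie <- constant_model(1, L)
  tie$layers[[2]]$b <- c(0, 0)                   # outputs (0.5, 0.5)
  X <- encode_one_hot(tiny_dataset(2, L, cp = c(5L, 6L)))
  expect_identical(predict_binary(tie, X), rep(0L, 4))
  expect_identical(predict_binary(constant_model(1, L), X), rep(1L, 4))
  expect_identical(predict_binary(constant_model(0, L), X), rep(0L, 4))
  expect_length(predict_binary(constant_model(1, L), X), dim(X)[1])
  expect_error(predict_proba(constant_model(1, 12), X), "window length")
})
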