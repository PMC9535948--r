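#' Layer specifications
#'
#' Declarative building blocks for sub-model architectures. Convolutions use
#' ReLU activation, "same" padding and stride 1; max-pooling uses stride
#' equal to the pool width.
#'
#' @param filters number of convolution filters
#' @param kernel convolution kernel width (nt)
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
conv1d <- function(filters, kernel) {
  stopifnot(filters >= 1, kernel >= 1)
  list(kind = "conv1d", filters = as.integer(filters), kernel = as.integer(kernel))
}

#' @rdname layer_spec
#' @param pool pooling window width
#' @export
maxpool1d <- function(pool) {
  stopifnot(pool >= 1)
  list(kind = "maxpool1d", pool = as.integer(pool))
}

#' @rdname layer_spec
#' @export
flatten <- function() list(kind = "flatten")

#' @rdname layer_spec
#' @param rate dropout rate in (0,1)
#' @export
dropout <- function(rate) {
  stopifnot(rate > 0, rate < 1)
  list(kind = "dropout", rate = rate)
}

#' @rdname layer_spec
#' @param units number of dense units
#' @param activation `"relu"` or `"sigmoid"`
#' @param l2 optional L2 kernel-penalty weight (default 0 = off)
#' @param initializer `"glorot_uniform"` (default) or `"random_normal"`
#' @export
dense <- function(units, activation = c("relu", "sigmoid"), l2 = 0,
                  initializer = c("glorot_uniform", "random_normal")) {
  stopifnot(units >= 1, l2 >= 0)
  list(kind = "dense", units = as.integer(units),
       activation = match.arg(activation), l2 = l2,
       initializer = match.arg(initializer))
}

#' Assemble and validate a sub-model specification
#'
#' @param name sub-model name (`"CNN1"`..`"CNN4"`, `"DNN1"`..`"DNN4"`, or a
#'   custom label)
#' @param layers ordered list of layer specs; the final layer must be
#'   `dense(2, "sigmoid")`, CNN presets must start with a convolution and
#'   DNN presets with flatten
#' @return a `submodel_spec`
#' @export
submodel_spec <- function(name, layers) {
  last <- layers[[length(layers)]]
  if (last$kind != "dense" || last$units != 2L || last$activation != "sigmoid") {
    stop("final layer must be dense(2, \"sigmoid\")", call. = FALSE)
  }
  if (grepl("^CNN", name) && layers[[1L]]$kind != "conv1d") {
    stop("CNN specs must start with a conv1d layer", call. = FALSE)
  }
  if (grepl("^DNN", name) && layers[[1L]]$kind != "flatten") {
    stop("DNN specs must start with a flatten layer", call. = FALSE)
  }
  structure(list(name = name, layers = layers), class = "submodel_spec")
}

.presets <- function() list(
  CNN1 = list(conv1d(72, 5), conv1d(144, 7), conv1d(168, 7),
              flatten(), dropout(0.20), dense(2, "sigmoid")),
  CNN2 = list(conv1d(136, 3), conv1d(72, 4), maxpool1d(7), conv1d(272, 7),
              maxpool1d(3), flatten(), dropout(0.35), dense(2, "sigmoid")),
  CNN3 = list(conv1d(208, 9), maxpool1d(6), conv1d(120, 5), maxpool1d(3),
              flatten(), dropout(0.20), dense(2, "sigmoid")),
  CNN4 = list(conv1d(250, 5), conv1d(250, 5), conv1d(250, 5), maxpool1d(3),
              flatten(), dropout(0.20), dense(2, "sigmoid")),
  DNN1 = list(flatten(), dense(704), dense(224), dropout(0.10), dense(512),
              dropout(0.15), dense(2, "sigmoid")),
  DNN2 = list(flatten(), dense(704), dense(224), dense(128), dropout(0.15),
              dense(2, "sigmoid")),
  DNN3 = list(flatten(), dense(256), dense(352), dense(32), dense(352),
              dropout(0.15), dense(2, "sigmoid")),
  DNN4 = list(flatten(), dense(250, initializer = "random_normal"),
              dense(250, initializer = "random_normal"),
              dense(250, initializer = "random_normal"), dropout(0.25),
              dense(2, "sigmoid", initializer = "random_normal"))
)

#' Retrieve one of the eight published sub-model architectures
#'
#' The four convolutional presets (CNN1-CNN4) and four dense presets
#' (DNN1-DNN4). DNN4 uses the random-normal kernel initializer; all others
#' use Glorot uniform. Presets ship without L2 penalties; `dense()` exposes
#' the knob for custom stacks.
#'
#' @param name one of `"CNN1"`..`"CNN4"`, `"DNN1"`..`"DNN4"`
#' @return a [submodel_spec()]
#' @export
preset_spec <- function(name) {
  p <- .presets()
  if (!name %in% names(p)) {
    stop(sprintf("unknown preset '%s'; valid names: %s", name,
                 paste(names(p), collapse = ", ")), call. = FALSE)
  }
  submodel_spec(name, p[[name]])
}

#' All preset names
#' @return character vector of the eight sub-model names
#' @export
preset_names <- function() names(.presets())

#' Inverse-time-decay learning-rate schedule
#'
#' `rate(step) = initial_rate / (1 + decay_rate * step / decay_steps)`;
#' steps count optimizer updates starting at 0. Convolutional sub-models
#' default to (0.001, 140, 0.1) and dense sub-models to (0.002, 80, 1.4).
#'
#' @param initial_rate starting learning rate
#' @param decay_steps decay time-scale in optimizer steps
#' @param decay_rate dimensionless decay strength
#' @return an `lr_schedule`
#' @export
lr_schedule <- function(initial_rate, decay_steps, decay_rate) {
  stopifnot(initial_rate > 0, decay_steps > 0, decay_rate > 0)
  structure(list(initial_rate = initial_rate, decay_steps = decay_steps,
                 decay_rate = decay_rate), class = "lr_schedule")
}

#' @rdname lr_schedule
#' @param schedule an `lr_schedule`
#' @param step optimizer step count (>= 0), vectorised
#' @export
inverse_time_decay <- function(schedule, step) {
  stopifnot(all(step >= 0))
  schedule$initial_rate /
    (1 + schedule$decay_rate * step / schedule$decay_steps)
}

#' Default schedules for the two sub-model families
#' @param kind `"cnn"` or `"dnn"`
#' @return an [lr_schedule()]
#' @export
default_schedule <- function(kind = c("cnn", "dnn")) {
  switch(match.arg(kind),
         cnn = lr_schedule(0.001, 140, 0.1),
         dnn = lr_schedule(0.002, 80, 1.4))
}

#' Training configuration
#'
#' @param batch_size minibatch size (default 32)
#' @param max_epochs maximum training epochs (default 30)
#' @param schedule an [lr_schedule()]; `NULL` picks the family default at
#'   training time (CNN 0.001/140/0.1, DNN 0.002/80/1.4)
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best weights restored)
#' @param validation_fraction stratified fraction held out for early
#'   stopping, in (0, 0.5)
#' @param seed RNG seed for shuffling, the validation split and dropout
#' @return a `train_config`
#' @export
train_config <- function(batch_size = 32L, max_epochs = 30L, schedule = NULL,
                         early_stop_patience = 3L, validation_fraction = 0.1,
                         seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 0,
            validation_fraction > 0, validation_fraction < 0.5)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 schedule = schedule,
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)), class = "train_config")
}

#' Published hyper-parameter search space (documentation constants)
#'
#' The ranges, steps and selected values of the original hyperband search.
#' The search itself is not re-run by this package; these constants document
#' where the preset architectures came from.
#'
#' @return a data.frame with columns family, hyperparameter, range, step,
#'   selected
#' @export
hyperparameter_search_space <- function() {
  data.frame(
    family = c("CNN", "CNN", "CNN", "CNN", "DNN", "DNN", "DNN"),
    hyperparameter = c("filters", "kernel_size", "dropout", "max_pool_size",
                       "units", "kernel_regularizer", "dropout"),
    range = c("8-400", "1-9", "0.05-0.30", "1-9", "32-704",
              "0.0025, 0.025, 0.036", "0.05-0.50"),
    step = c("8", "2", "0.05", "2", "32", NA, "0.50"),
    selected = c("72, 120, 136, 144, 168, 208, 250, 272", "3, 4, 5, 7, 9",
                 "0.20, 0.35", "3", "32, 128, 224, 250, 256, 352, 512, 704",
                 "0.0025, 0.025, 0.036", "0.1, 0.15, 0.25"),
    stringsAsFactors = FALSE)
}

#' Instantiate a trainable sub-model
#'
#' Walks the layer stack, checks shape compatibility (a pooling stack that
#' collapses the sequence length to zero is rejected) and initialises the
#' weights reproducibly from `seed`.
#'
#' @param spec a [submodel_spec()] or preset name
#' @param window_length input window length L; the model consumes
#'   N x L x 4 one-hot batches
#' @param seed weight-initialisation seed
#' @return a `splice_submodel`
#' @export
build_submodel <- function(spec, window_length, seed = 1L) {
  if (is.character(spec)) spec <- preset_spec(spec)
  stopifnot(inherits(spec, "submodel_spec"))
  window_length <- as.integer(window_length)
  layers <- with_seed(seed, {
    shape <- c(window_length, 4L)
    lapply(spec$layers, function(l) {
      st <- init_layer(l, shape)
      shape <<- st$out_shape
      st$layer
    })
  })
  structure(list(name = spec$name, layers = layers, spec = spec,
                 window_length = window_length, seed = as.integer(seed),
                 trained = FALSE,
                 kind = if (any(vapply(spec$layers, `[[`, "", "kind") == "conv1d"))
                   "cnn" else "dnn"),
            class = "splice_submodel")
}

#' @export
print.splice_submodel <- function(x, ...) {
  cat(sprintf("splice_submodel %s (%s), window length %d, %strained\n",
              x$name, toupper(x$kind), x$window_length,
              if (x$trained) "" else "un"))
  invisible(x)
}

batch_tensor <- function(batch) {
  stopifnot(length(dim(batch)) == 3L, dim(batch)[3L] == 4L)
  unclass(batch)
}

## stratified index split: validation gets ceil(frac * n) of each class
stratified_split <- function(y, frac) {
  val <- unlist(lapply(split(seq_along(y), y), function(idx) {
    idx[seq_len(max(1L, ceiling(frac * length(idx))))]
  }), use.names = FALSE)
  ## classes were ordered within split(); shuffle happened upstream
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Train a sub-model with Adam
#'
#' Minimises two-unit binary cross-entropy against one-hot (false, true)
#' targets using Adam under the config's inverse-time-decay schedule, with a
#' stratified validation split for early stopping on validation loss
#' (best-weights restoration). With `max_epochs = 0` the model is returned
#' untouched with an empty history.
#'
#' @param model a [build_submodel()] result
#' @param batch an N x L x 4 `one_hot_batch` (or plain array)
#' @param labels binary vector of length N; defaults to the batch's
#'   `"labels"` attribute
#' @param config a [train_config()]
#' @return the trained model, with a `history` data.frame (epoch, loss,
#'   val_loss, val_acc) attached as `model$history`
#' @export
train_submodel <- function(model, batch, labels = attr(batch, "labels"),
                           config = train_config()) {
  stopifnot(inherits(model, "splice_submodel"), inherits(config, "train_config"))
  X <- batch_tensor(batch)
  y <- as.integer(labels)
  if (length(y) != dim(X)[1L]) stop("labels length must match batch N", call. = FALSE)
  model$history <- data.frame(epoch = integer(0), loss = numeric(0),
                              val_loss = numeric(0), val_acc = numeric(0))
  if (config$max_epochs == 0L) return(model)
  if (length(unique(y)) < 2L) {
    stop("degenerate data: training labels contain a single class", call. = FALSE)
  }
  schedule <- config$schedule %||% default_schedule(model$kind)

  with_seed(config$seed, {
    n <- length(y)
    perm <- sample.int(n)                       # shuffle before the split
    split <- stratified_split(y[perm], config$validation_fraction)
    tr <- perm[split$train]; va <- perm[split$val]
    Xtr <- X[tr, , , drop = FALSE]; ytr <- y[tr]
    Xva <- X[va, , , drop = FALSE]; yva <- y[va]
    Ytr <- cbind(1 - ytr, ytr)                  # unit 1 = false, unit 2 = true
    Yva <- cbind(1 - yva, yva)

    adam <- adam_init(model)
    step <- 0L
    best <- list(loss = Inf, layers = model$layers, epoch = 0L)
    wait <- 0L
    ntr <- length(ytr)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(ntr)
      starts <- seq.int(1L, ntr, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
        fw <- model_forward(model, Xtr[idx, , , drop = FALSE], training = TRUE)
        P <- fw$out
        Yb <- Ytr[idx, , drop = FALSE]
        ep_loss <- ep_loss + bce_loss(P, Yb) * length(idx)
        dZ <- (P - Yb) / length(idx)            # sigmoid + BCE shortcut
        grads <- model_backward(model, dZ, fw$caches)
        lr <- inverse_time_decay(schedule, step)
        step <- step + 1L
        upd <- adam_update(model, grads, adam, lr, t = step)
        model <- upd$model; adam <- upd$state
      }
      Pva <- predict_proba(model, Xva)
      val_loss <- bce_loss(Pva, Yva)
      val_acc <- mean(as.integer(Pva[, 2L] > Pva[, 1L]) == yva)
      model$history <- rbind(model$history, data.frame(
        epoch = epoch, loss = ep_loss / ntr, val_loss = val_loss,
        val_acc = val_acc))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, layers = model$layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
    model$layers <- best$layers                 # restore best weights
    model$trained <- TRUE
    model
  })
}

#' Sub-model class probabilities
#'
#' @param model a trained `splice_submodel`
#' @param batch N x L x 4 one-hot array
#' @param chunk records per forward pass (memory control)
#' @return N x 2 matrix of per-unit sigmoid outputs (false-site, true-site)
#' @export
predict_proba <- function(model, batch, chunk = 64L) {
  X <- batch_tensor(batch)
  if (dim(X)[2L] != model$window_length) {
    stop(sprintf("input error: batch window length %d != model window length %d",
                 dim(X)[2L], model$window_length), call. = FALSE)
  }
  n <- dim(X)[1L]
  out <- matrix(0, n, 2L)
  for (s in seq.int(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx, ] <- model_forward(model, X[idx, , , drop = FALSE],
                                training = FALSE)$out
  }
  out
}

#' Binary sub-model predictions
#'
#' The predicted label is the index of the larger output unit (1 = true
#' site); ties break toward 0.
#'
#' @inheritParams predict_proba
#' @return integer vector of 0/1 predictions of length N
#' @export
predict_binary <- function(model, batch) {
  P <- predict_proba(model, batch)
  as.integer(P[, 2L] > P[, 1L])
}
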