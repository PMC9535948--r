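## Minimal BLAS-backed neural-network engine: 1-D convolution ("same"
## padding, stride 1, ReLU), max-pooling (stride = pool width, valid),
## dropout, dense layers, and Adam with an inverse-time-decay learning-rate
## schedule. Activations flow as N x L x C arrays until flatten, then as
## N x F matrices. Convolutions are im2col + dgemm; everything is driven by
## R's own RNG so runs are exactly reproducible for a fixed seed.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

## ---- conv1d ----------------------------------------------------------------

## "same" padding for stride 1: total k-1, split floor-left / ceil-right
conv_pad <- function(k) {
  pl <- (k - 1L) %/% 2L
  c(pl, k - 1L - pl)
}

## im2col as a single cached index gather: idx[(n,l), (o,c)] points into the
## flattened N x L x C input (with one appended zero as the padding
## sentinel), so patch extraction is one vectorised subset instead of k
## array slices. Indices depend only on the shape, so they are memoised.
.idx_cache <- new.env(parent = emptyenv())

get_im2col_idx <- function(N, L, C, k, pl) {
  key <- paste(N, L, C, k, pl, sep = "_")
  idx <- .idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  if (length(ls(.idx_cache)) > 64L) rm(list = ls(.idx_cache), envir = .idx_cache)
  nv <- rep(seq_len(N), times = L)
  lv <- rep(seq_len(L), each = N)
  idxk <- matrix(NA_integer_, N * L, k)
  for (o in seq_len(k)) {
    m <- lv + o - 1L - pl
    ok <- m >= 1L & m <= L
    idxk[ok, o] <- nv[ok] + (m[ok] - 1L) * N
  }
  idx <- idxk[, rep(seq_len(k), each = C), drop = FALSE] +
    matrix((rep(seq_len(C), times = k) - 1L) * (N * L), N * L, k * C,
           byrow = TRUE)
  idx[is.na(idx)] <- N * L * C + 1L            # sentinel -> appended zero
  .idx_cache[[key]] <- idx
  idx
}

im2col <- function(X, N, L, C, k, pl) {
  cols <- c(X, 0)[get_im2col_idx(N, L, C, k, pl)]
  dim(cols) <- c(N * L, k * C)
  cols
}

conv_forward <- function(layer, X, training) {
  d <- dim(X)
  k <- layer$kernel
  cols <- im2col(X, d[1L], d[2L], d[3L], k, conv_pad(k)[1L])
  Z <- add_bias(cols %*% layer$W, layer$b)
  A <- relu(Z)
  cache <- if (training) list(cols = cols, mask = Z > 0, in_dim = d) else NULL
  list(out = array(A, c(d[1L], d[2L], layer$filters)), cache = cache)
}

## The input gradient of a "same" stride-1 convolution is itself a
## convolution of dZ with the kernel flipped along its width and transposed
## in its channels, with left/right padding swapped — so the backward pass
## is another gather + dgemm rather than a scatter-add.
conv_backward <- function(layer, dOut, cache) {
  d <- cache$in_dim; N <- d[1L]; L <- d[2L]; C <- d[3L]; k <- layer$kernel
  f <- layer$filters
  dZ <- matrix(dOut, N * L, f) * cache$mask
  grads <- list(W = crossprod(cache$cols, dZ), b = colSums(dZ))
  Warr <- array(layer$W, c(C, k, f))           # [ci, o, co]
  Wflip <- matrix(aperm(Warr[, k:1, , drop = FALSE], c(3L, 2L, 1L)), k * f, C)
  colsZ <- im2col(dZ, N, L, f, k, conv_pad(k)[2L])
  list(dIn = array(colsZ %*% Wflip, c(N, L, C)), grads = grads)
}

## ---- maxpool1d -------------------------------------------------------------

pool_forward <- function(layer, X, training) {
  d <- dim(X); N <- d[1L]; L <- d[2L]; C <- d[3L]; p <- layer$pool
  Lo <- L %/% p
  Y <- array(-Inf, c(N, Lo, C))
  amax <- array(1L, c(N, Lo, C))
  for (o in seq_len(p)) {
    cand <- X[, seq.int(o, by = p, length.out = Lo), , drop = FALSE]
    better <- cand > Y
    Y[better] <- cand[better]
    amax[better] <- o
  }
  cache <- if (training) list(amax = amax, in_dim = d) else NULL
  list(out = Y, cache = cache)
}

pool_backward <- function(layer, dOut, cache) {
  d <- cache$in_dim; N <- d[1L]; L <- d[2L]; C <- d[3L]; p <- layer$pool
  Lo <- dim(dOut)[2L]
  dX <- array(0, c(N, L, C))
  for (o in seq_len(p)) {
    sel <- cache$amax == o
    slice <- array(0, c(N, Lo, C))
    slice[sel] <- dOut[sel]
    dX[, seq.int(o, by = p, length.out = Lo), ] <- slice
  }
  list(dIn = dX, grads = NULL)
}

## ---- flatten / dropout / dense --------------------------------------------

flatten_forward <- function(layer, X, training) {
  d <- dim(X)
  list(out = matrix(X, d[1L], prod(d[-1L])),
       cache = if (training) list(in_dim = d) else NULL)
}

flatten_backward <- function(layer, dOut, cache) {
  list(dIn = array(dOut, cache$in_dim), grads = NULL)
}

dropout_forward <- function(layer, X, training) {
  if (!training) return(list(out = X, cache = NULL))
  keep <- 1 - layer$rate
  mask <- array(stats::runif(length(X)) < keep, dim(X) %||% length(X)) / keep
  list(out = X * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, dOut, cache) {
  list(dIn = dOut * cache$mask, grads = NULL)
}

dense_forward <- function(layer, X, training) {
  Z <- add_bias(X %*% layer$W, layer$b)
  A <- if (layer$activation == "sigmoid") sigmoid(Z) else relu(Z)
  cache <- if (training) {
    list(X = X, mask = if (layer$activation == "sigmoid") A else (Z > 0))
  } else NULL
  list(out = A, cache = cache)
}

## For the final sigmoid layer the training loop passes dZ directly
## (cross-entropy + sigmoid collapse); `from_dz` marks that case.
dense_backward <- function(layer, dOut, cache, from_dz = FALSE) {
  dZ <- if (from_dz) dOut else dOut * cache$mask
  grads <- list(W = crossprod(cache$X, dZ), b = colSums(dZ))
  if (layer$l2 > 0) grads$W <- grads$W + 2 * layer$l2 * layer$W
  list(dIn = tcrossprod(dZ, layer$W), grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- layer dispatch --------------------------------------------------------

layer_forward <- function(layer, X, training) {
  switch(layer$kind,
         conv1d = conv_forward(layer, X, training),
         maxpool1d = pool_forward(layer, X, training),
         flatten = flatten_forward(layer, X, training),
         dropout = dropout_forward(layer, X, training),
         dense = dense_forward(layer, X, training))
}

layer_backward <- function(layer, dOut, cache, from_dz = FALSE) {
  switch(layer$kind,
         conv1d = conv_backward(layer, dOut, cache),
         maxpool1d = pool_backward(layer, dOut, cache),
         flatten = flatten_backward(layer, dOut, cache),
         dropout = dropout_backward(layer, dOut, cache),
         dense = dense_backward(layer, dOut, cache, from_dz))
}

## ---- parameter initialisation ---------------------------------------------

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_layer <- function(layer, in_shape) {
  ## in_shape: c(L, C) before flatten, F afterwards
  if (layer$kind == "conv1d") {
    C <- in_shape[2L]; k <- layer$kernel; f <- layer$filters
    layer$W <- glorot_uniform(k * C, f, k * C, k * f)
    layer$b <- numeric(f)
    out_shape <- c(in_shape[1L], f)
  } else if (layer$kind == "maxpool1d") {
    Lo <- in_shape[1L] %/% layer$pool
    if (Lo < 1L) {
      stop(sprintf(
        "architecture/input incompatibility: pool width %d collapses length %d to 0",
        layer$pool, in_shape[1L]), call. = FALSE)
    }
    out_shape <- c(Lo, in_shape[2L])
  } else if (layer$kind == "flatten") {
    out_shape <- prod(in_shape)
  } else if (layer$kind == "dropout") {
    out_shape <- in_shape
  } else if (layer$kind == "dense") {
    fi <- in_shape[1L]
    if (layer$initializer == "random_normal") {
      layer$W <- matrix(stats::rnorm(fi * layer$units, 0, 0.05), fi, layer$units)
    } else {
      layer$W <- glorot_uniform(fi, layer$units, fi, layer$units)
    }
    layer$b <- numeric(layer$units)
    out_shape <- layer$units
  }
  list(layer = layer, out_shape = out_shape)
}

## ---- forward / backward over the whole stack -------------------------------

model_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  A <- X
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], A, training)
    A <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = A, caches = caches)
}

## dZ_head: gradient of the loss w.r.t. the final pre-activation
model_backward <- function(model, dZ_head, caches) {
  grads <- vector("list", length(model$layers))
  dOut <- dZ_head
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], dOut, caches[[i]],
                         from_dz = (i == length(model$layers)))
    dOut <- bw$dIn
    grads[i] <- list(bw$grads)   # keep NULLs as placeholders
  }
  grads
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$W)) NULL else list(mW = l$W * 0, vW = l$W * 0,
                                     mb = l$b * 0, vb = l$b * 0)
  })
}

adam_update <- function(model, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

## binary cross-entropy against a two-column one-hot target, mean over
## samples and the two output units
bce_loss <- function(P, Y) {
  eps <- 1e-12
  -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
}
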