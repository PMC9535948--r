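.ensemble_presets <- list(
  ENS1 = c("DNN1", "DNN2", "DNN3", "DNN4"),
  ENS2 = c("CNN1", "CNN2", "CNN3", "CNN4"),
  ENS3 = c("DNN1", "DNN2", "DNN3", "DNN4", "CNN1", "CNN2", "CNN3", "CNN4"),
  ENS4 = c("CNN1", "CNN2", "CNN3", "DNN1", "DNN3"),
  ENS5 = c("DNN1", "DNN3", "DNN4", "CNN1", "CNN2", "CNN3"),
  ENS6 = c("DNN1", "DNN3", "DNN4", "CNN1", "CNN2")
)

#' The six candidate ensemble compositions
#'
#' ENS1 = all DNNs; ENS2 = all CNNs; ENS3 = all eight sub-models;
#' ENS4 = CNN1-3 + DNN1, DNN3; ENS5 = all but the worst CNN and DNN;
#' ENS6 = DNN1, DNN3, DNN4, CNN1, CNN2.
#'
#' @param name `"ENS1"`..`"ENS6"`
#' @return an `ensemble_preset` list with `name` and ordered `members`
#' @export
preset_members <- function(name) {
  if (!name %in% names(.ensemble_presets)) {
    stop(sprintf("unknown ensemble '%s'; valid names: %s", name,
                 paste(names(.ensemble_presets), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(name = name, members = .ensemble_presets[[name]]),
            class = "ensemble_preset")
}

#' All ensemble preset names
#' @return character vector `"ENS1"`..`"ENS6"`
#' @export
ensemble_names <- function() names(.ensemble_presets)

#' Stack member predictions into a meta-dataset
#'
#' Row i of the stacked matrix holds every member's binary prediction for
#' record i; this N x M matrix (not the raw sequences) is all the
#' meta-model ever sees.
#'
#' @param models list of >= 2 trained sub-models sharing a window length
#' @param batch N x L x 4 one-hot array
#' @return a `stacked_matrix`: N x M binary matrix with `member_order`
#'   attribute (column j = member j's predictions)
#' @export
stack_predictions <- function(models, batch) {
  stopifnot(length(models) >= 2L)
  preds <- lapply(models, predict_binary, batch = batch)
  ns <- lengths(preds)
  if (length(unique(ns)) != 1L) {
    stop("integrity error: members produced prediction vectors of unequal length",
         call. = FALSE)
  }
  M <- do.call(cbind, preds)
  colnames(M) <- vapply(models, function(m) m$name, character(1))
  structure(M, member_order = colnames(M), class = c("stacked_matrix", "matrix"))
}

## Ridge-penalised logistic regression by IRLS. The design here is at most
## eight binary columns, so a short Newton loop is exact, deterministic and
## free of external dependencies; the weak penalty keeps separable stacks
## (common: members often agree perfectly on clean data) well-posed.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L, tol = 1e-10) {
  X1 <- cbind(intercept = 1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)))       # intercept unpenalised
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    grad <- crossprod(X1, y - mu) - pen %*% beta
    H <- crossprod(X1 * W, X1) + pen
    delta <- solve(H + diag(1e-12, p), grad)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  beta
}

#' Fit the logistic-regression meta-model
#'
#' Fits a weakly ridge-penalised (`lambda = 1e-4`) logistic regression of
#' the labels on the stacked binary member predictions. The fit is exact
#' IRLS and fully deterministic; `seed` is accepted for interface symmetry
#' but unused.
#'
#' @param stacked a [stack_predictions()] result (or plain N x M 0/1 matrix)
#' @param labels binary vector of length N with both classes present
#' @param seed unused (deterministic fit)
#' @param lambda ridge penalty on the member coefficients
#' @return a `meta_model` with `coefficients` (M values), `intercept`,
#'   `member_order`
#' @export
fit_meta <- function(stacked, labels, seed = 1L, lambda = 1e-4) {
  X <- unclass(stacked)
  y <- as.integer(labels)
  if (nrow(X) < 2L || length(unique(y)) < 2L) {
    stop("degenerate data: meta-model needs >= 2 rows with both classes",
         call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("labels length must match stacked rows",
                                 call. = FALSE)
  beta <- ridge_logistic(X, y, lambda = lambda)
  structure(list(intercept = beta[1L], coefficients = beta[-1L],
                 member_order = attr(stacked, "member_order") %||% colnames(X),
                 lambda = lambda),
            class = "meta_model")
}

meta_probability <- function(meta, stacked) {
  X <- unclass(stacked)
  if (ncol(X) != length(meta$coefficients)) {
    stop(sprintf("integrity error: stacked matrix has %d columns, meta-model expects %d",
                 ncol(X), length(meta$coefficients)), call. = FALSE)
  }
  drop(1 / (1 + exp(-(meta$intercept + X %*% meta$coefficients))))
}

#' Ensemble prediction
#'
#' Stacks the members' binary predictions for the batch, applies the
#' logistic meta-model, and thresholds the resulting probability.
#'
#' @param meta a [fit_meta()] result
#' @param members list of trained sub-models in the meta-model's member
#'   order
#' @param batch N x L x 4 one-hot array
#' @param threshold decision threshold on the true-site probability
#'   (default 0.5; `label = probability >= threshold`)
#' @return list with `probability` (length-N vector), `label` (0/1 integer
#'   vector), and the `stacked` matrix
#' @export
predict_ensemble <- function(meta, members, batch, threshold = 0.5) {
  stopifnot(inherits(meta, "meta_model"))
  if (length(members) != length(meta$coefficients)) {
    stop("integrity error: member count does not match meta-model dimension",
         call. = FALSE)
  }
  stacked <- stack_predictions(members, batch)
  p <- meta_probability(meta, stacked)
  list(probability = p, label = as.integer(p >= threshold), stacked = stacked)
}
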