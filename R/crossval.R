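#' Stratified k-fold assignment
#'
#' Assigns each record a fold index in `1..k`, stratified by label: within
#' each class a seeded shuffle is dealt round-robin across folds, so
#' per-fold class counts differ by at most 1 from perfect stratification.
#'
#' @param dataset a `splice_dataset` (or any object with a `labels` field)
#' @param k number of folds (default 5)
#' @param seed fold-structure seed, independent of any training seed
#' @return integer vector of fold indices (1-based), one per record
#' @export
stratified_folds <- function(dataset, k = 5L, seed = 1L) {
  y <- dataset$labels
  k <- as.integer(k)
  tab <- table(y)
  if (any(tab < k)) {
    small <- names(tab)[tab < k][1L]
    stop(sprintf("insufficient data: class %s has %d records, fewer than k = %d",
                 small, tab[[small]], k), call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

mean_diversity <- function(reports) {
  keys <- c("correlation", "double_fault", "disagreement", "q_statistic")
  structure(as.list(colMeans(do.call(rbind, lapply(reports, function(r)
    unlist(r[keys]))))), class = "diversity_report")
}

#' Cross-validate an ensemble preset
#'
#' For each of k stratified folds: builds and trains every member on the
#' other k-1 folds, stacks the members' predictions on that same training
#' portion to fit the logistic meta-model, then evaluates members and
#' ensemble on the held-out fold. Diversity is computed from member
#' correctness on the held-out fold and averaged over all member pairs.
#' Member training seeds are fixed per (member, fold) so the same sub-model
#' gets identical weights in every ensemble that contains it.
#'
#' @param preset an [preset_members()] result or ensemble name
#' @param dataset a `splice_dataset`
#' @param k folds (default 5)
#' @param config a [train_config()]; its seed feeds weight initialisation
#'   and shuffling (per member and fold)
#' @param seed fold-structure seed
#' @param models optional pre-trained members per fold (internal reuse by
#'   [compare_ensembles()]): a list indexed `[[fold]][[member_name]]`
#' @return a `cv_result`: list with `ensemble`, per-fold metric reports for
#'   ensemble and members, `mean_accuracy`, `mean_diversity`, `folds`
#' @export
cross_validate_ensemble <- function(preset, dataset, k = 5L,
                                    config = train_config(), seed = 1L,
                                    models = NULL) {
  if (is.character(preset)) preset <- preset_members(preset)
  folds <- stratified_folds(dataset, k, seed)
  batch <- encode_one_hot(dataset)
  y <- dataset$labels
  fold_metrics <- vector("list", k)
  fold_div <- vector("list", k)
  member_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    Xtr <- batch[tr, , , drop = FALSE]; Xte <- batch[te, , , drop = FALSE]
    members <- lapply(preset$members, function(nm) {
      if (!is.null(models)) return(models[[f]][[nm]])
      train_member(nm, Xtr, y[tr], config, fold = f)
    })
    names(members) <- preset$members
    stacked_tr <- stack_predictions(members, Xtr)
    meta <- tryCatch(fit_meta(stacked_tr, y[tr]),
                     error = function(e) stop(sprintf("fold %d: %s", f,
                                                      conditionMessage(e)),
                                              call. = FALSE))
    pred <- predict_ensemble(meta, members, Xte)
    fold_metrics[[f]] <- metric_report(confusion_counts(pred$label, y[te]))
    member_preds <- lapply(members, predict_binary, batch = Xte)
    member_metrics[[f]] <- lapply(member_preds, function(p)
      metric_report(confusion_counts(p, y[te])))
    correctness <- lapply(member_preds, function(p) as.integer(p == y[te]))
    fold_div[[f]] <- ensemble_diversity(correctness)
  }
  structure(list(
    ensemble = preset$name,
    members = preset$members,
    fold_metrics = fold_metrics,
    member_metrics = member_metrics,
    fold_diversity = fold_div,
    mean_accuracy = mean(vapply(fold_metrics, `[[`, numeric(1), "accuracy")),
    mean_diversity = mean_diversity(fold_div),
    folds = folds, k = k), class = "cv_result")
}

## one member's deterministic per-(member, fold) training seed
train_member <- function(name, Xtr, ytr, config, fold) {
  seed <- config$seed + 1000L * fold + 100000L * match(name, preset_names())
  model <- build_submodel(name, dim(Xtr)[2L], seed = seed)
  cfg <- config; cfg$seed <- seed
  tryCatch(train_submodel(model, Xtr, ytr, cfg),
           error = function(e) stop(sprintf("fold %d, member %s: %s", fold, name,
                                            conditionMessage(e)), call. = FALSE))
}

#' Cross-validate several ensembles over shared trained members
#'
#' Trains each distinct sub-model once per fold and reuses it across all
#' requested ensembles, then runs [cross_validate_ensemble()] for each.
#'
#' @inheritParams cross_validate_ensemble
#' @param ensembles character vector of ensemble names
#' @return named list of `cv_result`s
#' @export
compare_ensembles <- function(ensembles, dataset, k = 5L,
                              config = train_config(), seed = 1L) {
  folds <- stratified_folds(dataset, k, seed)
  batch <- encode_one_hot(dataset)
  y <- dataset$labels
  needed <- unique(unlist(lapply(ensembles, function(e) preset_members(e)$members)))
  models <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f)
    Xtr <- batch[tr, , , drop = FALSE]
    ms <- lapply(needed, train_member, Xtr = Xtr, ytr = y[tr],
                 config = config, fold = f)
    names(ms) <- needed
    ms
  })
  out <- lapply(ensembles, cross_validate_ensemble, dataset = dataset, k = k,
                config = config, seed = seed, models = models)
  names(out) <- ensembles
  out
}

#' Select the representative ensemble from CV results
#'
#' Ranks by mean accuracy (descending), breaking ties by lower mean double
#' fault, then lower mean Q-statistic; the full ranking table is returned so
#' other criteria can be applied by the user.
#'
#' @param results list of `cv_result`s
#' @return list with `best` (ensemble name) and `ranking` (data.frame with
#'   mean accuracy and mean diversity columns, best first)
#' @export
select_best_ensemble <- function(results) {
  if (length(results) < 1L) stop("input error: no CV results", call. = FALSE)
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    ensemble = r$ensemble,
    mean_accuracy = r$mean_accuracy,
    double_fault = r$mean_diversity$double_fault,
    correlation = r$mean_diversity$correlation,
    q_statistic = r$mean_diversity$q_statistic,
    disagreement = r$mean_diversity$disagreement,
    stringsAsFactors = FALSE)))
  ord <- order(-tab$mean_accuracy, tab$double_fault, tab$q_statistic)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = tab$ensemble[1L], ranking = tab)
}
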