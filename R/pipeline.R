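#' Build a run configuration
#'
#' A single document describing an end-to-end run: where the data comes from
#' (synthetic generation or files), which ensemble to train, how to train
#' it, and where artifacts go. `load_run_config()` reads the same structure
#' from a JSON file; CLI flags override config keys.
#'
#' @param site_type `"acceptor"` or `"donor"`
#' @param out_dir output directory for artifacts
#' @param synthetic `NULL`, or a list of [synthetic_config()] arguments
#' @param data `NULL`, or list(pos_path=, neg_path=, dialect=, ...) passed to
#'   [read_dataset()]
#' @param ensemble ensemble preset name (default `"ENS2"`, the
#'   representative all-CNN ensemble)
#' @param train list of [train_config()] arguments
#' @param test_fraction stratified fraction held out for final evaluation
#' @param seed master seed: fold/split structure and, unless overridden in
#'   `train`, training
#' @return a `run_config`
#' @export
run_config <- function(site_type = "donor", out_dir = "splice_run",
                       synthetic = list(n_per_class = 500, window_length = 60),
                       data = NULL, ensemble = "ENS2",
                       train = list(max_epochs = 5), test_fraction = 0.2,
                       seed = 1L) {
  site_type <- match.arg(site_type, c("acceptor", "donor"))
  if (is.null(synthetic) && is.null(data)) {
    stop("config error: one of `synthetic` or `data` is required", call. = FALSE)
  }
  if (!is.null(data)) {
    for (p in c(data$pos_path, data$neg_path)) {
      if (!is.null(p) && !file.exists(p)) {
        stop(sprintf("config error: data path does not exist: %s", p),
             call. = FALSE)
      }
    }
  }
  preset_members(ensemble)   # fail fast on unknown names
  stopifnot(test_fraction > 0, test_fraction < 0.5)
  structure(list(site_type = site_type, out_dir = out_dir,
                 synthetic = synthetic, data = data, ensemble = ensemble,
                 train = train, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file holding the config fields
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

log_stage <- function(con, stage, ...) {
  line <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " "))
  if (!is.null(con)) writeLines(line, con)
  message(line)
}

#' Run the full pipeline
#'
#' simulate/ingest -> train members -> stack -> meta-model -> evaluate ->
#' report. Artifacts written under `config$out_dir`: `metrics.csv` (member
#' and ensemble evaluation on the held-out split), `predictions.csv`
#' (`record_id,probability,label`), class-conditional PFMs
#' (`pfm_positive.tsv`, `pfm_negative.tsv`), the fitted ensemble
#' (`ensemble.rds`), and `run.log` recording every seed and resolved
#' hyperparameter. Reruns with an identical config reproduce the metric
#' CSVs byte-for-byte.
#'
#' @param config a [run_config()]
#' @return invisibly, list with `metrics` data.frame, `ensemble` (meta +
#'   members), `paths` of written artifacts
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, "w"); on.exit(close(con))
  tcfg <- do.call(train_config, config$train %||% list())
  log_stage(con, "config", site_type = config$site_type,
            ensemble = config$ensemble, seed = config$seed,
            train_seed = tcfg$seed, batch_size = tcfg$batch_size,
            max_epochs = tcfg$max_epochs)

  if (!is.null(config$data)) {
    dataset <- do.call(read_dataset, c(config$data,
                                       list(site_type = config$site_type)))
    log_stage(con, "ingest", n = length(dataset))
  } else {
    args <- config$synthetic
    cp <- args$consensus_positions
    args$consensus_positions <- NULL
    args$site_type <- config$site_type
    if (is.null(args$seed)) args$seed <- config$seed
    scfg <- do.call(synthetic_config, args)
    cp <- cp %||% c(scfg$window_length %/% 2L, scfg$window_length %/% 2L + 1L)
    motif <- default_motif(scfg$site_type, scfg$window_length, cp)
    dataset <- generate_dataset(scfg, motif)
    log_stage(con, "simulate", n = length(dataset),
              signal = scfg$signal_strength, seed = scfg$seed)
  }

  folds <- stratified_folds(dataset, k = round(1 / config$test_fraction),
                            seed = config$seed)
  te <- which(folds == 1L); tr <- which(folds != 1L)
  batch <- encode_one_hot(dataset)
  y <- dataset$labels
  Xtr <- batch[tr, , , drop = FALSE]; Xte <- batch[te, , , drop = FALSE]
  log_stage(con, "split", train = length(tr), test = length(te),
            split_seed = config$seed)

  member_names <- preset_members(config$ensemble)$members
  members <- lapply(member_names, function(nm) {
    m <- train_member(nm, Xtr, y[tr], tcfg, fold = 0L)
    log_stage(con, "train", member = nm, epochs = nrow(m$history),
              seed = m$seed)
    m
  })
  names(members) <- member_names

  stacked <- stack_predictions(members, Xtr)
  meta <- fit_meta(stacked, y[tr])
  log_stage(con, "meta", members = paste(member_names, collapse = "+"),
            lambda = meta$lambda)

  pred <- predict_ensemble(meta, members, Xte)
  rows <- do.call(rbind, c(
    list(metric_rows(config, "ensemble", config$ensemble,
                     metric_report(confusion_counts(pred$label, y[te])))),
    lapply(member_names, function(nm) {
      metric_rows(config, "member", nm, metric_report(
        confusion_counts(predict_binary(members[[nm]], Xte), y[te])))
    })))
  log_stage(con, "evaluate",
            ensemble_accuracy = sprintf("%.4f", rows$value[rows$metric == "accuracy" &
                                                           rows$model == config$ensemble]))

  paths <- list(
    metrics = file.path(config$out_dir, "metrics.csv"),
    predictions = file.path(config$out_dir, "predictions.csv"),
    pfm_positive = file.path(config$out_dir, "pfm_positive.tsv"),
    pfm_negative = file.path(config$out_dir, "pfm_negative.tsv"),
    ensemble = file.path(config$out_dir, "ensemble.rds"),
    log = log_path)
  utils::write.csv(rows, paths$metrics, row.names = FALSE)
  utils::write.csv(data.frame(record_id = te, probability = pred$probability,
                              label = pred$label),
                   paths$predictions, row.names = FALSE)
  write_pfm(position_frequencies(dataset, "positive"), paths$pfm_positive)
  write_pfm(position_frequencies(dataset, "negative"), paths$pfm_negative)
  ensemble_model <- list(meta = meta, members = members,
                         site_type = config$site_type,
                         window_length = dataset$window_length)
  saveRDS(ensemble_model, paths$ensemble)
  for (p in paths) log_stage(con, "artifact", path = p)
  invisible(list(metrics = rows, ensemble = ensemble_model, paths = paths))
}

metric_rows <- function(config, role, model, report) {
  keys <- c("accuracy", "precision", "sensitivity", "specificity", "mcc",
            "f1", "error_rate")
  data.frame(site_type = config$site_type, role = role, model = model,
             metric = keys, value = unlist(report[keys], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Save / load a trained sub-model or ensemble
#'
#' Serialisation uses R's native RDS format; the architecture alone can be
#' exported as JSON for inspection with [export_spec_json()].
#'
#' @param model any model object from this package
#' @param path file path
#' @return `load_model` returns the object; `save_model` invisibly `path`
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Export an architecture spec as JSON
#'
#' @param spec a [submodel_spec()] or preset name
#' @param path output JSON path
#' @return invisibly, `path`
#' @export
export_spec_json <- function(spec, path) {
  if (is.character(spec)) spec <- preset_spec(spec)
  jsonlite::write_json(list(name = spec$name, layers = spec$layers), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
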