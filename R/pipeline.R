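#' Canonical eSEC of an action class
#'
#' The modal column-code sequence over a set of eSECs of one class: scenarios
#' whose event compression agrees (the expected case within thresholds) share
#' one symbol-level sequence, and the most frequent sequence is returned.
#'
#' @param esecs List of `esec_matrix` objects of one action class.
#' @return The `esec_matrix` realising the modal sequence.
#' @export
canonical_esec <- function(esecs) {
  if (!length(esecs)) stop("domain error: no eSECs given")
  keys <- vapply(esecs, function(e)
    paste(e$mat, collapse = ","), character(1))
  win <- names(sort(table(keys), decreasing = TRUE))[1L]
  esecs[[which(keys == win)[1L]]]
}

#' Canonical eSEC set of a labelled collection
#'
#' @param esecs List of labelled `esec_matrix` objects (several classes).
#' @return Named list, one canonical `esec_matrix` per class.
#' @export
canonical_set <- function(esecs) {
  labels <- esec_labels(esecs)
  if (anyNA(labels)) stop("domain error: unlabelled eSEC")
  out <- lapply(split(esecs, labels), canonical_esec)
  out[order(match(names(out), ACTIONS))]
}

#' Pipeline configuration
#'
#' Bundles everything a full run needs: relation-extraction thresholds,
#' simulator settings, classifier evaluation parameters and the synthetic
#' observer used for the response-model stage.
#'
#' @param relation A [relation_params()] object.
#' @param simulation A [simulation_config()] object.
#' @param n_per_action Scenarios per action class.
#' @param split,margin Passed to [evaluate_dataset()].
#' @param seed Root seed for all randomness.
#' @param observer_model Generating model for synthetic responses (one of
#'   [INFO_MODELS]).
#' @param observer_coefficients Named coefficients of the generating logistic
#'   observer (see [generate_responses()]).
#' @param trials_per_action Synthetic observer trials per action.
#' @param out_dir Output directory for pipeline artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(relation = relation_params(),
                       simulation = simulation_config(),
                       n_per_action = 30L,
                       split = 0.5, margin = 0, seed = 42L,
                       observer_model = "S+D",
                       observer_coefficients = c(intercept = -3.5,
                                                 cumulative = 0.35),
                       trials_per_action = 20L,
                       out_dir = NULL) {
  structure(list(relation = relation, simulation = simulation,
                 n_per_action = as.integer(n_per_action), split = split,
                 margin = margin, seed = as.integer(seed),
                 observer_model = observer_model,
                 observer_coefficients = observer_coefficients,
                 trials_per_action = as.integer(trials_per_action),
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$relation <- unclass(x$relation)
  x$simulation <- unclass(x$simulation)
  x$simulation$durations <- as.list(x$simulation$durations)
  x$observer_coefficients <- as.list(x$observer_coefficients)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    relation = do.call(relation_params, x$relation),
    simulation = do.call(simulation_config,
                         c(x$simulation[setdiff(names(x$simulation),
                                                "durations")],
                           list(durations = as.data.frame(
                             x$simulation$durations,
                             stringsAsFactors = FALSE)))),
    n_per_action = x$n_per_action, split = x$split, margin = x$margin,
    seed = x$seed, observer_model = x$observer_model,
    observer_coefficients = unlist(x$observer_coefficients),
    trials_per_action = x$trials_per_action, out_dir = x$out_dir)
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> classify -> information -> observer-model fitting:
#' generates a labelled scenario dataset, builds all eSECs, evaluates
#' progressive classification (per-action predictive power and accuracy),
#' derives the canonical action set and its information table, simulates
#' observer responses from the configured generating model, fits all eight
#' observer models per action, and ranks them by BIC.
#'
#' @param config A [run_config()]; `out_dir` must be set (artifacts are
#'   written there).
#' @return A report list: `evaluation` (see [evaluate_dataset()]),
#'   `canonical` (named eSEC list), `info` (an `info_table`),
#'   `model_comparison` (per-action BIC ranking, best model flagged),
#'   `best_models` (data.frame action/model).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.null(config$out_dir))
    stop("pipeline error [config]: out_dir is not set")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline error [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  message("simulating ", config$n_per_action, " scenarios per action")
  trajs <- stage("simulate",
                 generate_dataset(config$n_per_action, config$simulation,
                                  seed = config$seed))
  message("extracting eSEC matrices")
  esecs <- stage("extract", lapply(trajs, build_esec, params = config$relation))
  message("evaluating progressive classification")
  ev <- stage("classify",
              evaluate_dataset(esecs, split = config$split,
                               seed = config$seed, margin = config$margin))
  message("computing information tables")
  canon <- stage("info", canonical_set(esecs))
  info <- stage("info", info_table(canon))
  message("fitting observer models")
  responses <- stage("fit",
                     generate_responses(config$observer_model,
                                        config$observer_coefficients, info,
                                        config$trials_per_action,
                                        seed = config$seed + 1L))
  fits <- stage("fit", {
    acts <- names(canon)
    do.call(rbind, lapply(acts, function(act) {
      cmp <- compare_models(lapply(INFO_MODELS, function(m)
        fit_response_model(responses, info, action = act, model = m)))
      cmp$action <- act
      cmp
    }))
  })
  best <- fits[fits$winner & !duplicated(fits$action),
               c("action", "model", "BIC", "mcfadden")]
  # artifacts
  utils::write.table(ev$per_action,
                     file.path(config$out_dir, "predictive_power.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fits, file.path(config$out_dir, "model_bic.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (a in names(canon))
    write_esec(canon[[a]],
               file.path(config$out_dir, paste0("canonical_", a, ".tsv")))
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  list(evaluation = ev, canonical = canon, info = info,
       model_comparison = fits, best_models = best)
}
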