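# End-to-end experiment harness: individual models and data sources,
# source-ratio sweeps, expert fallback thresholds, statistical consensus,
# and the full three-model stack, each evaluated on the late-period
# private test set.

metric_row <- function(experiment, model, predictions, test_ms,
                       ratio = NA_character_, tau = NA_real_) {
  m <- evaluate_predictions(predictions, test_ms)
  cbind(data.frame(experiment = experiment, model = model, ratio = ratio,
                   tau = tau, stringsAsFactors = FALSE),
        as.data.frame(m)[, c("ACC", "BA", "SENS", "SPEC", "PPV", "NPV",
                             "MCC", "KAPPA")])
}

#' Run the combination-experiment suite on a benchmark
#'
#' Trains and evaluates, against the private test set: (1) the expert
#' surrogate and each statistical model on each single source; (2) RF and
#' SOHN on source-weighted public+private pools over a ratio grid; (3)
#' expert fallback below a confidence-threshold grid; (4) the
#' most-confident RF+SOHN consensus; (5) the full three-model stack.
#'
#' @param public,private_train,private_test curated \code{\link{mol_set}}s.
#' @param alerts alert set (default: the packaged surrogate).
#' @param ratios character vector of public:private ratios for the sweep.
#' @param taus numeric fallback thresholds.
#' @param best_ratio ratio used by experiments 3-5.
#' @param tau_full threshold used by the full stack.
#' @param experiments subset of \code{1:5} to run.
#' @param seed integer seed passed to every training.
#' @return data.frame of metric rows (one per evaluated model).
#' @export
run_experiment_suite <- function(public, private_train, private_test,
                                 alerts = load_alerts(),
                                 ratios = c("5:0", "5:2", "1:1", "2:5", "0:5"),
                                 taus = c(0.6, 0.7, 0.8, 0.9),
                                 best_ratio = "2:5", tau_full = 0.7,
                                 experiments = 1:5,
                                 seed = HQ_DEFAULT_SEED) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  # featurise each set once; pooled training sets inherit the caches
  if (is.null(public$cache)) public <- featurize_mol_set(public)
  if (is.null(private_train$cache)) private_train <- featurize_mol_set(private_train)
  if (is.null(private_test$cache)) private_test <- featurize_mol_set(private_test)
  expert <- expert_predict(alerts, private_test)

  train_pair <- function(ratio) {
    wts <- weighted_training_set(public, private_train, ratio, seed = seed)
    list(
      rf = train_rf(wts$data, weights = wts$weights, seed = seed),
      sohn = sohn_train(wts$data, weights = wts$weights, seed = seed)
    )
  }
  cache <- new.env(parent = emptyenv())
  models_for <- function(ratio) {
    key <- ratio
    if (is.null(cache[[key]])) cache[[key]] <- train_pair(ratio)
    cache[[key]]
  }

  if (1 %in% experiments) {
    add(metric_row("1_individual", "expert", expert, private_test))
    pub_models <- models_for("5:0")
    priv_models <- models_for("0:5")
    add(metric_row("1_individual", "rf_public",
                   predict(pub_models$rf, private_test), private_test))
    add(metric_row("1_individual", "sohn_public",
                   predict(pub_models$sohn, private_test), private_test))
    add(metric_row("1_individual", "rf_private",
                   predict(priv_models$rf, private_test), private_test))
    add(metric_row("1_individual", "sohn_private",
                   predict(priv_models$sohn, private_test), private_test))
  }
  if (2 %in% experiments) {
    for (r in ratios) {
      mods <- models_for(r)
      add(metric_row("2_data_combination", "rf",
                     predict(mods$rf, private_test), private_test, ratio = r))
      add(metric_row("2_data_combination", "sohn",
                     predict(mods$sohn, private_test), private_test,
                     ratio = r))
    }
  }
  if (any(3:5 %in% experiments)) {
    best <- models_for(best_ratio)
    rf_pred <- predict(best$rf, private_test)
    sohn_pred <- predict(best$sohn, private_test)
  }
  if (3 %in% experiments) {
    for (tau in taus) {
      add(metric_row("3_expert_fallback", "rf+expert",
                     combine_fallback(rf_pred, expert, tau), private_test,
                     ratio = best_ratio, tau = tau))
      add(metric_row("3_expert_fallback", "sohn+expert",
                     combine_fallback(sohn_pred, expert, tau), private_test,
                     ratio = best_ratio, tau = tau))
    }
  }
  if (4 %in% experiments) {
    add(metric_row("4_consensus", "rf", rf_pred, private_test,
                   ratio = best_ratio))
    add(metric_row("4_consensus", "sohn", sohn_pred, private_test,
                   ratio = best_ratio))
    add(metric_row("4_consensus", "rf+sohn",
                   combine_most_confident(list(rf_pred, sohn_pred)),
                   private_test, ratio = best_ratio))
  }
  if (5 %in% experiments) {
    consensus <- combine_most_confident(list(rf_pred, sohn_pred))
    add(metric_row("5_full_stack", "rf+sohn+expert",
                   combine_fallback(consensus, expert, tau_full),
                   private_test, ratio = best_ratio, tau = tau_full))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-seed source-combination benchmark
#'
#' Generates the synthetic benchmark for one seed, trains RF and SOHN on
#' the public source, the private source and their weighted pool, and
#' returns test-set MCCs together with the most-confident consensus of the
#' two pooled models. This is the unit the qualitative synergy analysis
#' averages over seeds.
#'
#' @param seed integer seed for generation and training.
#' @param cfg a \code{\link{simulation_config}} (its seed is overridden).
#' @param mixed_ratio public:private ratio of the pooled models.
#' @return named numeric vector of MCCs: \code{rf_public},
#'   \code{sohn_public}, \code{rf_private}, \code{sohn_private},
#'   \code{rf_mixed}, \code{sohn_mixed}, \code{consensus}.
#' @export
run_source_benchmark <- function(seed, cfg = simulation_config(),
                                 mixed_ratio = "2:5") {
  cfg$seed <- as.integer(seed)
  sim <- generate_dataset(cfg)
  pub <- featurize_mol_set(sim$public)
  priv <- featurize_mol_set(sim$private_train)
  test <- featurize_mol_set(sim$private_test)
  out <- c()
  for (r in c("5:0", mixed_ratio, "0:5")) {
    tag <- switch(r, "5:0" = "public", "0:5" = "private", "mixed")
    w <- weighted_training_set(pub, priv, r, seed = seed)
    rf <- train_rf(w$data, weights = w$weights, seed = seed)
    so <- sohn_train(w$data, weights = w$weights, seed = seed)
    prf <- predict(rf, test)
    pso <- predict(so, test)
    out[paste0("rf_", tag)] <- evaluate_predictions(prf, test)$MCC
    out[paste0("sohn_", tag)] <- evaluate_predictions(pso, test)$MCC
    if (tag == "mixed") {
      out["consensus"] <- evaluate_predictions(
        combine_most_confident(list(prf, pso)), test)$MCC
    }
  }
  out
}

#' Save a trained model as a versioned archive
#'
#' @param model a \code{sohn_model} or \code{herg_rf}.
#' @param path output path (.rds).
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("sohn_model", "herg_rf")))
  saveRDS(list(format = "hergqsar-model", format_version = 1L,
               model = model), path)
  invisible(path)
}

#' Load a model saved by \code{\link{save_model}}
#'
#' @param path archive path.
#' @return the model object.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hergqsar-model")) {
    stop_input("not a hergqsar model archive: ", path)
  }
  obj$model
}
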