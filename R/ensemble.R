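# Model/data combination strategies: source-weighted training sets,
# confidence-threshold fallback to the expert system, most-confident
# consensus, and the full three-model stack.

#' Public/private sampling ratio
#'
#' The relative total training influence of the public vs private source,
#' notated \code{a:b} (e.g. \code{"2:5"}). Within a source, records share
#' the source's total weight equally.
#'
#' @param public_weight,private_weight non-negative numbers, not both zero.
#' @return object of class \code{source_ratio}.
#' @export
source_ratio <- function(public_weight, private_weight) {
  if (public_weight < 0 || private_weight < 0 ||
      (public_weight == 0 && private_weight == 0)) {
    stop_input("ratio weights must be non-negative and not both zero")
  }
  structure(list(public = public_weight, private = private_weight),
            class = "source_ratio")
}

#' Parse a ratio string like "2:5"
#'
#' @param x string \code{"a:b"}.
#' @return a \code{\link{source_ratio}}.
#' @export
parse_ratio <- function(x) {
  parts <- suppressWarnings(as.numeric(strsplit(x, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || anyNA(parts)) {
    stop_input("ratio must have the form 'a:b': ", x)
  }
  source_ratio(parts[1], parts[2])
}

#' Source-weighted training set
#'
#' Assigns per-record weights so the total effective weight of the public
#' vs private records stands in the ratio \code{a:b}, each source's records
#' sharing its total equally; weights are normalised to mean 1. A source
#' with zero weight is dropped entirely, so the \code{5:0} and \code{0:5}
#' extremes reproduce the corresponding single-source model bit-for-bit at
#' a fixed seed. \code{mode = "resample"} instead draws a bootstrap of the
#' pooled records with probabilities proportional to those weights
#' (deterministic at fixed seed) and returns unit weights.
#'
#' @param public,private \code{\link{mol_set}} training sets.
#' @param ratio a \code{\link{source_ratio}} or \code{"a:b"} string.
#' @param mode \code{"weight"} (default, exact) or \code{"resample"}.
#' @param seed integer seed (used by \code{"resample"} only).
#' @return list with \code{data} (a \code{mol_set}) and \code{weights}
#'   (numeric, parallel to \code{data$df}).
#' @export
weighted_training_set <- function(public, private, ratio,
                                  mode = c("weight", "resample"),
                                  seed = HQ_DEFAULT_SEED) {
  mode <- match.arg(mode)
  if (is.character(ratio)) ratio <- parse_ratio(ratio)
  a <- ratio$public; b <- ratio$private
  if (a == 0) {
    return(list(data = private, weights = rep(1, nrow(private$df))))
  }
  if (b == 0) {
    return(list(data = public, weights = rep(1, nrow(public$df))))
  }
  pooled <- bind_mol_sets(public, private)
  n_pub <- nrow(public$df); n_priv <- nrow(private$df)
  w <- c(rep(a / n_pub, n_pub), rep(b / n_priv, n_priv))
  w <- w / mean(w)
  if (mode == "resample") {
    n <- n_pub + n_priv
    set.seed(derive_seed(seed, "resample"))
    idx <- sort(sample.int(n, n, replace = TRUE, prob = w))
    ms <- subset_mol_set(pooled, idx)
    ms$df$id <- make.unique(ms$df$id, sep = "_rs")
    names(ms$graphs) <- ms$df$id
    if (!is.null(ms$sdf)) ChemmineR::cid(ms$sdf) <- ms$df$id
    return(list(data = ms, weights = rep(1, n)))
  }
  list(data = pooled, weights = w)
}

#' Fallback combination of a statistical and an expert prediction
#'
#' Keeps the statistical prediction when its confidence is at least the
#' threshold; otherwise the expert's call is used and the switch is
#' recorded in the provenance. \code{tau = 0} reproduces the statistical
#' model exactly; \code{tau > 1} always defers to the expert.
#'
#' @param statistical prediction data.frame with numeric confidence.
#' @param expert expert prediction data.frame (same ids).
#' @param tau confidence threshold in \code{[0, 1]} (or beyond for the
#'   degenerate bounds).
#' @return combined prediction data.frame.
#' @export
combine_fallback <- function(statistical, expert, tau) {
  if (anyNA(statistical$confidence)) {
    stop_input("statistical predictions must carry numeric confidence")
  }
  m <- match(statistical$id, expert$id)
  if (anyNA(m)) stop_input("expert predictions missing for some ids")
  use_stat <- statistical$confidence >= tau
  new_prediction(
    id = statistical$id,
    call = ifelse(use_stat, statistical$call, expert$call[m]),
    confidence = statistical$confidence,
    model = ifelse(use_stat, statistical$model, "expert_fallback"),
    provenance = ifelse(
      use_stat, statistical$provenance,
      paste0("fallback_to_expert[", expert$provenance[m], "]")))
}

#' Most-confident consensus of several predictions
#'
#' For each id, the final call is that of the prediction with the highest
#' confidence. Confidence ties with conflicting calls are resolved
#' conservatively to active (and logged); the combination is invariant to
#' the order of the input predictions.
#'
#' @param predictions list of prediction data.frames with numeric
#'   confidence over the same ids.
#' @return combined prediction data.frame.
#' @export
combine_most_confident <- function(predictions) {
  if (length(predictions) == 0) stop_input("need at least one prediction set")
  for (p in predictions) {
    if (anyNA(p$confidence)) {
      stop_input("all predictions must carry numeric confidence")
    }
  }
  ids <- predictions[[1]]$id
  rows <- lapply(predictions, function(p) {
    m <- match(ids, p$id)
    if (anyNA(m)) stop_input("prediction sets cover different ids")
    p[m, , drop = FALSE]
  })
  calls <- vapply(rows, `[[`, character(length(ids)), "call")
  confs <- vapply(rows, `[[`, numeric(length(ids)), "confidence")
  models <- vapply(rows, `[[`, character(length(ids)), "model")
  if (length(ids) == 1L) {
    calls <- matrix(calls, nrow = 1); confs <- matrix(confs, nrow = 1)
    models <- matrix(models, nrow = 1)
  }
  out <- lapply(seq_along(ids), function(i) {
    cmax <- max(confs[i, ])
    tied <- which(confs[i, ] >= cmax - 1e-12)
    tie_calls <- unique(calls[i, tied])
    if (length(tie_calls) > 1L) {
      hq_log("debug", "confidence tie with conflicting calls at id ",
             ids[i], "; resolved to active")
      pick <- tied[calls[i, tied] == "active"]
      pick <- pick[order(models[i, pick])][1]
    } else {
      pick <- tied[order(models[i, tied])][1]
    }
    list(call = calls[i, pick], confidence = confs[i, pick],
         model = models[i, pick])
  })
  new_prediction(
    id = ids,
    call = vapply(out, `[[`, character(1), "call"),
    confidence = vapply(out, `[[`, numeric(1), "confidence"),
    model = vapply(out, `[[`, character(1), "model"),
    provenance = sprintf("most_confident(%s)",
                         paste(sort(unique(as.vector(models))),
                               collapse = "+")))
}

#' Full three-model stack prediction
#'
#' The two statistical models form a most-confident consensus; when that
#' consensus is less confident than the threshold, the expert's call is
#' used instead (the fallback rule applied on top of the consensus).
#'
#' @param sohn_model a trained \code{\link{sohn_train}} model.
#' @param rf_model a trained \code{\link{train_rf}} model.
#' @param alerts an \code{\link{load_alerts}} alert set.
#' @param ms query \code{\link{mol_set}}.
#' @param tau confidence threshold (default 0.7).
#' @return combined prediction data.frame.
#' @export
full_stack_predict <- function(sohn_model, rf_model, alerts, ms, tau = 0.7) {
  stat <- combine_most_confident(list(predict(sohn_model, ms),
                                      predict(rf_model, ms)))
  combine_fallback(stat, expert_predict(alerts, ms), tau)
}
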