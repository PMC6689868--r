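# Random-forest classifier over [physchem | Morgan | Feature-Morgan]
# feature blocks, with a similarity-aware per-prediction confidence score.

rf_feature_blocks <- function(ms, descriptors) {
  pc <- cached_pc(ms, descriptors)
  colnames(pc) <- paste0("pc_", colnames(pc))
  fpm <- cached_fp(ms, "morgan")
  fpf <- cached_fp(ms, "feature")
  M <- as.matrix(methods::as(fpm, "dMatrix"))
  Fm <- as.matrix(methods::as(fpf, "dMatrix"))
  colnames(M) <- paste0("m_", seq_len(ncol(M)))
  colnames(Fm) <- paste0("fm_", seq_len(ncol(Fm)))
  list(x = cbind(pc, M, Fm), morgan = fpm)
}

#' Train the random-forest hERG model
#'
#' Features are the concatenation of the physicochemical descriptor block,
#' the radius-4/4096-bit Morgan fingerprint and its Feature (pharmacophoric)
#' variant. Defaults: 500 trees, sqrt(p) candidate features per split,
#' unlimited depth. Training fingerprints are retained for the similarity
#' term of the confidence score. Rows are sorted by id internally so the
#' model is invariant to training-set row permutation at a fixed seed.
#'
#' @param ms curated \code{\link{mol_set}} with both classes present.
#' @param weights optional per-compound sampling weights.
#' @param num_trees,mtry forest size and per-split feature count
#'   (\code{mtry = NULL} means sqrt(p)).
#' @param descriptors physchem descriptor subset (see
#'   \code{\link{physchem_descriptors}}).
#' @param seed integer seed controlling tree construction.
#' @return object of class \code{herg_rf}.
#' @export
train_rf <- function(ms, weights = NULL, num_trees = 500L, mtry = NULL,
                     descriptors = PHYSCHEM_DESCRIPTORS,
                     seed = HQ_DEFAULT_SEED) {
  if (anyNA(ms$df$call)) stop_input("training set must be fully curated")
  if (length(unique(ms$df$call)) < 2L) {
    stop_input("random forest needs both classes in the training set")
  }
  w <- weights %||% rep(1, nrow(ms$df))
  if (length(w) != nrow(ms$df)) stop_input("weights length mismatch")
  ord <- order(ms$df$id)
  ms <- subset_mol_set(ms, ord)
  w <- w[ord]
  blocks <- rf_feature_blocks(ms, descriptors)
  y <- factor(ms$df$call, levels = c("active", "inactive"))
  fit <- ranger::ranger(
    x = blocks$x, y = y,
    num.trees = num_trees,
    mtry = mtry %||% floor(sqrt(ncol(blocks$x))),
    probability = TRUE,
    case.weights = w,
    seed = derive_seed(seed, "rf"),
    num.threads = 1L
  )
  structure(list(forest = fit, train_morgan = blocks$morgan,
                 train_ids = ms$df$id,
                 descriptors = descriptors,
                 params = list(num_trees = num_trees, seed = seed),
                 version = "rf/1"),
            class = "herg_rf")
}

#' @export
print.herg_rf <- function(x, ...) {
  cat(sprintf("<herg_rf> %d trees, %d training compounds, %d features\n",
              x$forest$num.trees, length(x$train_ids),
              x$forest$num.independent.variables))
  invisible(x)
}

#' Confidence score of a statistical prediction
#'
#' The arithmetic mean of the maximum Tanimoto similarity of the query to
#' the training data and the model's probability for the predicted class.
#' Both inputs and the result lie in \code{[0, 1]}; since the predicted
#' class has probability at least 0.5 in a binary forest, the score
#' usually lies between 0.5 and 1, reaching 1 only for an exact training
#' match predicted unanimously.
#'
#' @param max_similarity maximum similarity to the training set.
#' @param model_probability vote fraction of the predicted class.
#' @return \code{(max_similarity + model_probability) / 2}, vectorised.
#' @export
confidence_score <- function(max_similarity, model_probability) {
  if (any(!is.finite(max_similarity)) || any(!is.finite(model_probability)) ||
      any(max_similarity < 0 | max_similarity > 1) ||
      any(model_probability < 0 | model_probability > 1)) {
    stop_input("confidence_score inputs must lie in [0, 1]")
  }
  (max_similarity + model_probability) / 2
}

#' Predict hERG calls with the random-forest model
#'
#' The call is the majority forest class (probability ties resolved
#' conservatively to active); the confidence is
#' \code{\link{confidence_score}} of the maximum Tanimoto similarity to
#' the training set (plain Morgan block) and the predicted-class vote
#' fraction.
#'
#' @param object a \code{herg_rf} model.
#' @param ms query \code{\link{mol_set}}.
#' @param ... unused.
#' @return prediction data.frame: \code{id}, \code{call},
#'   \code{confidence}, \code{model}, \code{provenance}.
#' @export
predict.herg_rf <- function(object, ms, ...) {
  blocks <- rf_feature_blocks(ms, object$descriptors)
  pr <- stats::predict(object$forest, data = blocks$x,
                       num.threads = 1L)$predictions
  p_act <- pr[, "active"]
  call <- ifelse(p_act >= 0.5, "active", "inactive")
  p_pred <- pmax(p_act, 1 - p_act)
  max_sim <- apply(tanimoto_matrix(blocks$morgan, object$train_morgan), 1, max)
  conf <- confidence_score(max_sim, p_pred)
  new_prediction(
    id = ms$df$id, call = call, confidence = conf, model = "rf",
    provenance = sprintf("p=%.4f;max_sim=%.4f", p_pred, max_sim))
}
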