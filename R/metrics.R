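# Confusion-matrix evaluation metrics: ACC, BA, SENS, SPEC, PPV, NPV,
# MCC, Cohen's kappa.

#' Confusion-matrix metrics for binary calls
#'
#' Computes TP/FP/TN/FN (positive class = \code{"active"}) and the eight
#' derived statistics: accuracy, balanced accuracy \code{(SENS+SPEC)/2},
#' sensitivity, specificity, positive/negative predictive value, Matthews
#' correlation coefficient and Cohen's kappa. A metric whose denominator is
#' zero is reported as 0 and the result is flagged \code{degenerate}.
#'
#' @param predicted,observed character/factor vectors of
#'   \code{"active"}/\code{"inactive"} calls, equal length.
#' @return object of class \code{confusion_metrics}: a one-row data.frame
#'   with counts and metrics, plus a \code{degenerate} flag.
#' @export
confusion_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0) {
    stop_input("predicted and observed must be non-empty and equal length")
  }
  p <- as_call_factor(predicted)
  o <- as_call_factor(observed)
  if (anyNA(p) || anyNA(o)) {
    stop_input("calls must be 'active' or 'inactive'")
  }
  tp <- sum(p == "active" & o == "active")
  fp <- sum(p == "active" & o == "inactive")
  tn <- sum(p == "inactive" & o == "inactive")
  fn <- sum(p == "inactive" & o == "active")
  n <- tp + fp + tn + fn
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  acc <- (tp + tn) / n
  ba <- (sens + spec) / 2
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- safe_div(as.numeric(tp) * tn - as.numeric(fp) * fn, mcc_den)
  p_o <- acc
  p_e <- ((tp + fp) / n) * ((tp + fn) / n) +
    ((tn + fn) / n) * ((tn + fp) / n)
  kappa <- safe_div(p_o - p_e, 1 - p_e)
  out <- data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
                    ACC = acc, BA = ba, SENS = sens, SPEC = spec,
                    PPV = ppv, NPV = npv, MCC = mcc, KAPPA = kappa,
                    degenerate = degenerate)
  class(out) <- c("confusion_metrics", "data.frame")
  out
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sens,spec rates in \code{[0, 1]}.
#' @return \code{(sens + spec) / 2}.
#' @export
balanced_accuracy <- function(sens, spec) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  (sens + spec) / 2
}

#' Round a metric table to display precision
#'
#' Rounds the eight metric columns half-to-even to 2 decimals (the display
#' precision used throughout the reporting tables); counts are untouched.
#'
#' @param metrics data.frame with metric columns.
#' @return the rounded data.frame.
#' @export
metrics_display <- function(metrics) {
  cols <- intersect(c("ACC", "BA", "SENS", "SPEC", "PPV", "NPV",
                      "MCC", "KAPPA"), names(metrics))
  metrics[cols] <- lapply(metrics[cols], round, digits = 2)
  metrics
}

#' Evaluate a prediction table against a truth table
#'
#' @param predictions prediction data.frame (columns \code{id},
#'   \code{call}).
#' @param truth a \code{\link{mol_set}} with calls, or a data.frame with
#'   \code{id} and \code{call}.
#' @return \code{\link{confusion_metrics}} over the intersection of ids.
#' @export
evaluate_predictions <- function(predictions, truth) {
  tdf <- if (inherits(truth, "mol_set")) truth$df else truth
  m <- merge(predictions[, c("id", "call")],
             tdf[, c("id", "call")], by = "id",
             suffixes = c(".pred", ".obs"))
  if (nrow(m) == 0) stop_input("no overlapping ids between predictions and truth")
  confusion_metrics(m$call.pred, m$call.obs)
}
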