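# Bioactivity curation: binarise heterogeneous measurements into a single
# active/inactive call per compound, and temporal train/test splitting.

POTENCY_KINDS <- c("IC50", "EC50", "Ki")

#' Threshold policy for binarising bioactivities
#'
#' Potency measurements (IC50/EC50/Ki, in uM) are called active when the
#' value is strictly below the 10 uM-equivalent threshold; percent
#' inhibition at 10 uM is active strictly above 50\%. Values exactly at a
#' threshold are inactive (strict inequality, a documented boundary
#' convention). Per-kind overrides allow e.g. a different Ki cutoff.
#'
#' @param potency_threshold potency cutoff in uM (default 10).
#' @param inhibition_threshold percent-inhibition cutoff (default 50).
#' @param per_kind_overrides named numeric vector of kind-specific
#'   thresholds overriding the defaults.
#' @return an object of class \code{threshold_policy}.
#' @export
threshold_policy <- function(potency_threshold = 10,
                             inhibition_threshold = 50,
                             per_kind_overrides = NULL) {
  thr <- c(potency_threshold, inhibition_threshold,
           unname(per_kind_overrides))
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop_input("all thresholds must be positive")
  }
  if (!is.null(per_kind_overrides)) {
    bad <- setdiff(names(per_kind_overrides), ACTIVITY_KINDS)
    if (length(bad) > 0) {
      stop_input("threshold override for unknown kind(s): ",
                 paste(bad, collapse = ", "))
    }
  }
  structure(list(potency_threshold = potency_threshold,
                 inhibition_threshold = inhibition_threshold,
                 per_kind_overrides = per_kind_overrides),
            class = "threshold_policy")
}

policy_threshold_for <- function(policy, kind) {
  if (!is.null(policy$per_kind_overrides) &&
      kind %in% names(policy$per_kind_overrides)) {
    return(policy$per_kind_overrides[[kind]])
  }
  if (kind %in% POTENCY_KINDS) return(policy$potency_threshold)
  if (kind == "percent_inhibition_at_10uM") return(policy$inhibition_threshold)
  stop_input("no threshold for activity kind: ", kind)
}

#' Binarise a single activity measurement
#'
#' @param kind activity kind (IC50, EC50, Ki,
#'   percent_inhibition_at_10uM, author_call).
#' @param value measurement value (uM for potencies, \% for inhibition,
#'   0/1 for author calls).
#' @param policy a \code{\link{threshold_policy}}.
#' @return \code{"active"} or \code{"inactive"}.
#' @export
binarize_measurement <- function(kind, value, policy = threshold_policy()) {
  if (!kind %in% ACTIVITY_KINDS) stop_input("unknown activity kind: ", kind)
  if (kind == "author_call") {
    if (!value %in% c(0, 1)) stop_input("author_call value must be 0 or 1")
    return(if (value == 1) "active" else "inactive")
  }
  if (!is.finite(value) || value < 0) {
    stop_input("activity value must be a non-negative number")
  }
  if (kind == "percent_inhibition_at_10uM" && value > 100) {
    stop_input("percent inhibition must be <= 100")
  }
  thr <- policy_threshold_for(policy, kind)
  active <- if (kind %in% POTENCY_KINDS) value < thr else value > thr
  if (active) "active" else "inactive"
}

#' Conservatively merge several binary calls
#'
#' A single active is sufficient for an active overall call (a join over
#' the \code{inactive < active} lattice: commutative, associative,
#' idempotent).
#'
#' @param calls character vector of \code{"active"}/\code{"inactive"}.
#' @return merged call.
#' @export
merge_calls <- function(calls) {
  if (length(calls) == 0) stop_input("cannot merge an empty list of calls")
  bad <- setdiff(unique(calls), c("active", "inactive"))
  if (length(bad) > 0) stop_input("invalid call value(s): ",
                                  paste(bad, collapse = ", "))
  if (any(calls == "active")) "active" else "inactive"
}

#' Merge replicate measurements of one kind: mean first, then binarise
#'
#' Replicates of the same numeric assay are averaged (arithmetic mean)
#' before thresholding. Note the order matters: averaging 40\% and 70\%
#' inhibition gives 55\% (active), whereas binarising first and merging
#' conservatively would also call it active, but 40\%/45\% vs a single 60\%
#' can differ between the two orders. Mean-first is the rule for replicate
#' values of a single protocol.
#'
#' @param values numeric replicate measurements of the same kind.
#' @param kind the shared activity kind (not \code{author_call}).
#' @param policy a \code{\link{threshold_policy}}.
#' @return \code{"active"} or \code{"inactive"}.
#' @export
merge_replicates <- function(values, kind, policy = threshold_policy()) {
  if (length(values) == 0) stop_input("cannot merge an empty list of values")
  if (kind == "author_call") {
    stop_input("author_call has no replicate-mean rule; use merge_calls")
  }
  binarize_measurement(kind, mean(values), policy)
}

#' Curate a molecule set: one active/inactive call per compound
#'
#' Within each compound, replicate numeric measurements of the same kind
#' are averaged then binarised (\code{\link{merge_replicates}}); the
#' per-kind calls and any author calls are then merged conservatively
#' (\code{\link{merge_calls}}). Compounds without any measurement keep
#' their existing call if present, otherwise raise an error.
#'
#' @param ms a \code{\link{mol_set}} with raw activities.
#' @param policy a \code{\link{threshold_policy}}.
#' @param audit if \code{TRUE}, attach the per-decision audit table as
#'   \code{attr(result, "audit")}.
#' @return the \code{mol_set} with the \code{call} column filled.
#' @export
curate_dataset <- function(ms, policy = threshold_policy(), audit = FALSE) {
  acts <- ms$activities
  audit_rows <- list()
  calls <- ms$df$call
  for (i in seq_len(nrow(ms$df))) {
    id <- ms$df$id[i]
    a <- acts[acts$id == id, , drop = FALSE]
    if (nrow(a) == 0) {
      if (is.na(calls[i])) {
        stop_input("compound ", id, " has neither activities nor a call")
      }
      next
    }
    kind_calls <- character(0)
    for (k in unique(a$kind)) {
      v <- a$value[a$kind == k]
      kc <- if (k == "author_call") {
        vapply(v, function(x) binarize_measurement("author_call", x, policy),
               character(1))
      } else {
        merge_replicates(v, k, policy)
      }
      kind_calls <- c(kind_calls, kc)
      if (audit) {
        audit_rows[[length(audit_rows) + 1L]] <- data.frame(
          id = id, kind = k, n_values = length(v),
          values = paste(signif(v, 6), collapse = ";"),
          call = paste(kc, collapse = ";"), stringsAsFactors = FALSE)
      }
    }
    calls[i] <- merge_calls(kind_calls)
  }
  ms$df$call <- calls
  if (audit) attr(ms, "audit") <- do.call(rbind, audit_rows)
  ms
}

#' Temporal train/test split
#'
#' Training compounds are those dated on or before the cutoff; test
#' compounds are strictly later. Records without a date are excluded with
#' a logged warning. A canonical structure appearing on both sides of the
#' split is flagged and removed from the test side (compounds must be
#' unique to each dataset).
#'
#' @param ms a \code{\link{mol_set}} with dates.
#' @param cutoff a \code{Date} (or ISO-8601 string).
#' @return list with \code{mol_set} elements \code{train} and \code{test}.
#' @export
temporal_split <- function(ms, cutoff) {
  cutoff <- as.Date(cutoff)
  dated <- !is.na(ms$df$date)
  if (!any(dated)) stop_input("temporal split requires dated records")
  if (any(!dated)) {
    hq_log("warn", sum(!dated), " undated record(s) excluded from the split")
    warning(sum(!dated), " undated record(s) excluded from temporal split",
            call. = FALSE)
  }
  train_idx <- which(dated & ms$df$date <= cutoff)
  test_idx <- which(dated & ms$df$date > cutoff)
  dup <- ms$df$smiles[test_idx] %in% ms$df$smiles[train_idx]
  if (any(dup)) {
    hq_log("warn", sum(dup), " test structure(s) duplicated in training; removed")
    warning(sum(dup), " duplicate structure(s) removed from the test side",
            call. = FALSE)
    test_idx <- test_idx[!dup]
  }
  list(train = subset_mol_set(ms, train_idx),
       test = subset_mol_set(ms, test_idx))
}
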