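# Structural-alert expert surrogate: curated SMARTS patterns matched as
# substructures. A stand-in for a knowledge-base expert system; the shipped
# default alert set is a synthetic testing surrogate encoding the classic
# hERG pharmacophore shape, not a reproduction of any proprietary
# knowledge base.

ob_smarts_ok <- function(smarts) {
  sp <- ChemmineOB:::OBSmartsPattern()
  isTRUE(tryCatch(ChemmineOB:::OBSmartsPattern_Init(sp, smarts),
                  error = function(e) FALSE))
}

#' Load a structural-alert set from TSV
#'
#' Tab-separated file with a header and columns \code{name},
#' \code{smarts}, \code{rationale}. Every pattern must compile; failures
#' are reported with their line number. Duplicate names and empty alert
#' sets are errors.
#'
#' @param path TSV path (default: the package's synthetic surrogate set of
#'   five hERG-pharmacophore-shaped alerts).
#' @return data.frame of class \code{alert_set}.
#' @export
load_alerts <- function(path = system.file("extdata", "herg_alerts.tsv",
                                           package = "hergqsar")) {
  if (!file.exists(path)) stop_input("alert file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("name", "smarts", "rationale")
  if (!all(req %in% names(tab))) {
    stop_input("alert file must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(tab) == 0) stop_input("alert file contains no alerts")
  bad <- which(!vapply(tab$smarts, ob_smarts_ok, logical(1)))
  if (length(bad) > 0) {
    stop_input("malformed SMARTS at line(s) ",
               paste(bad + 1L, collapse = ", "), " of ", path,
               " (alert ", paste(tab$name[bad], collapse = ", "), ")")
  }
  dup <- tab$name[duplicated(tab$name)]
  if (length(dup) > 0) {
    stop_input("duplicate alert name(s): ", paste(unique(dup), collapse = ", "))
  }
  class(tab) <- c("alert_set", "data.frame")
  tab
}

#' Expert-surrogate prediction by structural-alert matching
#'
#' A compound is called active when at least one alert matches as a
#' substructure. The prediction is training-free and deterministic; its
#' confidence is categorical (\code{conf_level} \code{"matched"} /
#' \code{"no_match"}), never a number — the numeric \code{confidence}
#' column is \code{NA}. The provenance lists the matched alert names.
#'
#' @param alerts an \code{\link{load_alerts}} alert set.
#' @param ms query \code{\link{mol_set}}.
#' @return prediction data.frame with an extra \code{conf_level} column.
#' @export
expert_predict <- function(alerts, ms) {
  if (!inherits(alerts, "alert_set")) stop_input("alerts must be an alert_set")
  hits <- vapply(alerts$smarts, function(sm) {
    ChemmineR::smartsSearchOB(ms$sdf, sm, uniqueMatches = TRUE) > 0
  }, logical(length(ms$df$id)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(ms$df))
  matched <- apply(hits, 1, function(h) paste(alerts$name[h], collapse = "+"))
  any_hit <- rowSums(hits) > 0
  new_prediction(
    id = ms$df$id,
    call = ifelse(any_hit, "active", "inactive"),
    confidence = NA_real_,
    model = "expert",
    provenance = ifelse(any_hit, matched, ""),
    conf_level = ifelse(any_hit, "matched", "no_match"))
}
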