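# Table I/O: molecule tables (CSV/SDF) and prediction CSVs.

#' Read a molecule table
#'
#' CSV input requires columns \code{id} and \code{smiles}; optional columns
#' are \code{activity_kind}, \code{activity_value}, \code{source},
#' \code{date} and \code{call}. A compound may span several rows (one per
#' activity measurement); the first row of an id defines its structure and
#' metadata. SDF input takes molecule ids from the title line (falling back
#' to positional ids) and carries no activities.
#'
#' Unparseable structures are reported (warning + log) and skipped; if no
#' row parses, an input error is raised.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"sdf"}.
#' @return a \code{\link{mol_set}}.
#' @export
read_molecule_table <- function(path, format = c("csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    req <- c("id", "smiles")
    missing_cols <- setdiff(req, names(raw))
    if (length(missing_cols) > 0) {
      stop_input("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "))
    }
    first <- raw[!duplicated(raw$id), , drop = FALSE]
    df <- data.frame(id = first$id, smiles = first$smiles,
                     stringsAsFactors = FALSE)
    for (col in c("source", "date", "call")) {
      if (col %in% names(raw)) df[[col]] <- first[[col]]
    }
    acts <- NULL
    if (all(c("activity_kind", "activity_value") %in% names(raw))) {
      has <- !is.na(raw$activity_kind) & nzchar(raw$activity_kind)
      acts <- data.frame(id = raw$id[has], kind = raw$activity_kind[has],
                         value = as.numeric(raw$activity_value[has]),
                         stringsAsFactors = FALSE)
    }
    mol_set(df, activities = acts)
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    ids <- ChemmineR::sdfid(sdf)
    ids[is.na(ids) | !nzchar(trimws(ids))] <-
      paste0("MOL", which(is.na(ids) | !nzchar(trimws(ids))))
    ids <- make.unique(gsub("\\s+", "_", trimws(ids)), sep = "_")
    smi <- vapply(seq_along(sdf), function(i) {
      txt <- paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")
      out <- tryCatch(ob_convert(txt, "SDF", "CAN"), error = function(e) "")
      strsplit(out, "\t|\n")[[1]][1] %||% NA_character_
    }, character(1))
    keep <- !is.na(smi) & nzchar(smi)
    if (!any(keep)) stop_input("no parseable molecules in SDF")
    mol_set(data.frame(id = ids[keep], smiles = smi[keep],
                       stringsAsFactors = FALSE))
  }
}

#' Write predictions to CSV
#'
#' Columns: \code{id}, \code{call}, \code{confidence} (6 decimal places;
#' empty for the expert surrogate's categorical confidence), \code{model},
#' \code{provenance}, and \code{conf_level} when present. The file is
#' re-readable losslessly by \code{\link{read_predictions}} up to the
#' serialised precision.
#'
#' @param predictions prediction data.frame as returned by the model
#'   \code{predict} functions.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (is.null(predictions) || nrow(predictions) == 0) {
    stop_input("predictions must be non-empty")
  }
  out <- data.frame(
    id = predictions$id,
    call = predictions$call,
    confidence = ifelse(is.na(predictions$confidence), "",
                        sprintf("%.6f", predictions$confidence)),
    model = predictions$model,
    provenance = predictions$provenance,
    stringsAsFactors = FALSE
  )
  if ("conf_level" %in% names(predictions)) {
    out$conf_level <- predictions$conf_level
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_input("cannot write predictions to: ", path)
  invisible(path)
}

#' Read predictions written by \code{\link{write_predictions}}
#'
#' @param path CSV path.
#' @return prediction data.frame.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("id", "call", "confidence", "model", "provenance")
  if (!all(req %in% names(raw))) {
    stop_input("prediction file missing column(s): ",
               paste(setdiff(req, names(raw)), collapse = ", "))
  }
  raw$confidence <- suppressWarnings(as.numeric(raw$confidence))
  raw
}

new_prediction <- function(id, call, confidence, model, provenance,
                           conf_level = NULL) {
  df <- data.frame(id = id, call = call, confidence = confidence,
                   model = model, provenance = provenance,
                   stringsAsFactors = FALSE)
  if (!is.null(conf_level)) df$conf_level <- conf_level
  df
}
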