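# Molecule container and structure parsing.
#
# A `mol_set` bundles the per-compound table (id, canonical SMILES, source,
# date, call), the long-format raw activity measurements, the parsed
# molecular graphs (heavy atoms only) and the underlying SDFset used for
# OpenBabel-backed operations (SMARTS matching, physchem properties).

ACTIVITY_KINDS <- c("IC50", "EC50", "Ki", "percent_inhibition_at_10uM",
                    "author_call")

ob_convert <- function(text, from, to) {
  ChemmineOB::convertFormat(from, to, source = text)
}

# Canonicalise a vector of SMILES. OpenBabel aborts a batch at the first
# invalid entry, so conversion resumes after each failing row; failures are
# reported, never silently dropped.
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  start <- 1L
  while (start <= n) {
    idx <- start:n
    lines <- paste(smiles[idx], paste0("R", idx), sep = "\t")
    res <- tryCatch(ob_convert(paste(lines, collapse = "\n"), "SMI", "CAN"),
                    error = function(e) "")
    outl <- strsplit(res, "\n", fixed = TRUE)[[1]]
    outl <- outl[nzchar(trimws(outl))]
    k <- length(outl)
    if (k > 0L) {
      parts <- strsplit(outl, "\t", fixed = TRUE)
      for (j in seq_len(k)) {
        tag <- trimws(parts[[j]][2] %||% "")
        pos <- suppressWarnings(as.integer(sub("^R", "", tag)))
        if (!is.na(pos)) out[pos] <- parts[[j]][1]
      }
    }
    # row start+k (if any) is the one that aborted the stream
    start <- start + k + 1L
  }
  out
}

# Parse SMILES into an SDFset plus heavy-atom graphs. Returns indices of
# rows that failed to parse; `ids` must be unique and whitespace-free.
parse_molecules <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids))
  if (anyDuplicated(ids)) stop_input("molecule ids must be unique")
  cansmi <- canonical_smiles(smiles)
  bad <- which(is.na(cansmi))
  ok <- which(!is.na(cansmi))
  if (length(ok) == 0L) {
    return(list(cansmi = cansmi, bad = bad, sdf = NULL, graphs = list()))
  }
  lines <- paste(cansmi[ok], ids[ok], sep = "\t")
  sdftxt <- ob_convert(paste(lines, collapse = "\n"), "SMI", "SDF")
  con <- textConnection(strsplit(sdftxt, "\n", fixed = TRUE)[[1]])
  on.exit(close(con), add = TRUE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con)))
  if (length(sdf) != length(ok)) {
    stop_input("internal: SDF conversion lost molecules (",
               length(sdf), " vs ", length(ok), ")")
  }
  ChemmineR::cid(sdf) <- ids[ok]
  # single-heavy-atom structures cannot be represented by the SDF toolkit
  # layer (no bond block); they are outside the package's scope and skipped
  natoms <- vapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    if (is.null(dim(ab))) 1L else nrow(ab)
  }, integer(1))
  tiny <- which(natoms < 2L)
  if (length(tiny) > 0L) {
    bad <- sort(c(bad, ok[tiny]))
    cansmi[ok[tiny]] <- NA_character_
    ok <- ok[-tiny]
    sdf <- sdf[ids[ok]]
    if (length(ok) == 0L) {
      return(list(cansmi = cansmi, bad = bad, sdf = NULL, graphs = list()))
    }
  }
  graphs <- build_graphs(sdf)
  names(graphs) <- ids[ok]
  list(cansmi = cansmi, bad = bad, sdf = sdf, graphs = graphs)
}

# Aromatic atom indices for every molecule of an SDFset, via a single
# SMARTS pattern over the OpenBabel molecule refs.
aromatic_atom_indices <- function(sdf) {
  mols <- ChemmineR::obmol(sdf)
  sp <- ChemmineOB:::OBSmartsPattern()
  if (!ChemmineOB:::OBSmartsPattern_Init(sp, "[a]")) {
    stop("internal: failed to compile aromatic SMARTS")
  }
  lapply(mols, function(m) {
    ChemmineOB:::OBSmartsPattern_Match(sp, m)
    sort(unique(unlist(ChemmineOB:::OBSmartsPattern_GetUMapList(sp))))
  })
}

# Heavy-atom graph: elements, aromatic flags, hybridisation (derived from
# kekulised bond orders), bond list and adjacency.
build_graphs <- function(sdf) {
  arom_idx <- aromatic_atom_indices(sdf)
  lapply(seq_along(sdf), function(i) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    elem <- sub("_.*$", "", rownames(ab))
    n <- length(elem)
    bb <- ChemmineR::bondblock(mol)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
    bonds <- if (nrow(bb) > 0) {
      cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
            order = as.integer(bb[, 3]))
    } else {
      matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
    }
    arom <- rep(FALSE, n)
    arom[arom_idx[[i]][arom_idx[[i]] <= n]] <- TRUE
    nbr <- vector("list", n)
    nbr_bo <- vector("list", n)
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds[b, 1]; a2 <- bonds[b, 2]; o <- bonds[b, 3]
      nbr[[a1]] <- c(nbr[[a1]], a2); nbr_bo[[a1]] <- c(nbr_bo[[a1]], o)
      nbr[[a2]] <- c(nbr[[a2]], a1); nbr_bo[[a2]] <- c(nbr_bo[[a2]], o)
    }
    nbr <- lapply(nbr, function(x) x %||% integer(0))
    nbr_bo <- lapply(nbr_bo, function(x) x %||% integer(0))
    n_double <- vapply(nbr_bo, function(o) sum(o == 2L), integer(1))
    n_triple <- vapply(nbr_bo, function(o) sum(o == 3L), integer(1))
    hyb <- ifelse(n_triple > 0L | n_double >= 2L, "sp",
                  ifelse(n_double > 0L | arom, "sp2", "sp3"))
    list(n = n, elem = elem, arom = arom, hyb = hyb, bonds = bonds,
         nbr = nbr, nbr_bo = nbr_bo)
  })
}

#' Construct a molecule set from SMILES
#'
#' Parses and canonicalises SMILES (via OpenBabel), builds heavy-atom
#' graphs, and assembles the package's central container. Rows whose SMILES
#' fail to parse — or that contain a single heavy atom, which the SDF
#' toolkit layer cannot represent — are reported through a warning and
#' skipped, never silently dropped; their ids are kept in
#' \code{attr(x, "skipped")}.
#'
#' @param df data.frame with columns \code{id}, \code{smiles}; optional
#'   \code{source} (\code{"public"}/\code{"private"}), \code{date}
#'   (ISO-8601), \code{call} (\code{"active"}/\code{"inactive"}).
#' @param activities optional data.frame with columns \code{id},
#'   \code{kind} (one of IC50, EC50, Ki, percent_inhibition_at_10uM,
#'   author_call) and \code{value}.
#' @return an object of class \code{mol_set}.
#' @export
mol_set <- function(df, activities = NULL) {
  req <- c("id", "smiles")
  if (!all(req %in% names(df))) {
    stop_input("molecule table must have columns: ", paste(req, collapse = ", "))
  }
  df$id <- as.character(df$id)
  if (any(grepl("\\s", df$id))) {
    hq_log("warn", "whitespace in molecule ids replaced by '_'")
    df$id <- gsub("\\s+", "_", df$id)
  }
  if (anyDuplicated(df$id)) stop_input("molecule ids must be unique")
  parsed <- parse_molecules(as.character(df$smiles), df$id)
  skipped <- df$id[parsed$bad]
  if (length(skipped) > 0) {
    hq_log("warn", length(skipped),
           " unparseable or unsupported SMILES skipped: ",
           paste(utils::head(skipped, 5), collapse = ", "),
           if (length(skipped) > 5) ", ..." else "")
    warning(length(skipped), " unparseable SMILES row(s) skipped",
            call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(df)), parsed$bad)
  if (length(keep) == 0L) stop_input("no parseable molecules in input")
  out <- data.frame(
    id = df$id[keep],
    smiles = parsed$cansmi[keep],
    source = if ("source" %in% names(df)) as.character(df$source[keep])
             else NA_character_,
    date = if ("date" %in% names(df)) as.Date(as.character(df$date[keep]))
           else as.Date(rep(NA, length(keep))),
    call = if ("call" %in% names(df)) as.character(df$call[keep])
           else NA_character_,
    stringsAsFactors = FALSE
  )
  acts <- if (is.null(activities)) {
    data.frame(id = character(0), kind = character(0), value = numeric(0))
  } else {
    a <- activities[activities$id %in% out$id, , drop = FALSE]
    bad_kind <- setdiff(unique(a$kind), ACTIVITY_KINDS)
    if (length(bad_kind) > 0) {
      stop_input("unknown activity kind(s): ", paste(bad_kind, collapse = ", "))
    }
    data.frame(id = as.character(a$id), kind = as.character(a$kind),
               value = as.numeric(a$value), stringsAsFactors = FALSE)
  }
  structure(
    list(df = out, activities = acts, graphs = parsed$graphs, sdf = parsed$sdf),
    skipped = skipped,
    class = "mol_set"
  )
}

#' @export
print.mol_set <- function(x, ...) {
  calls <- table(factor(x$df$call, levels = c("active", "inactive")))
  cat(sprintf(
    "<mol_set> %d molecules (%d active / %d inactive / %d uncalled), %d raw activities\n",
    nrow(x$df), calls[["active"]], calls[["inactive"]],
    sum(is.na(x$df$call)), nrow(x$activities)))
  invisible(x)
}

#' @export
length.mol_set <- function(x) nrow(x$df)

#' Subset a molecule set by position or id
#'
#' @param ms a \code{mol_set}.
#' @param i integer positions or character ids.
#' @return a \code{mol_set} restricted to the selected molecules.
#' @export
subset_mol_set <- function(ms, i) {
  if (is.character(i)) i <- match(i, ms$df$id)
  if (anyNA(i)) stop_input("unknown molecule id in subset")
  ids <- ms$df$id[i]
  cache <- if (is.null(ms$cache)) NULL else {
    list(morgan = ms$cache$morgan[i, , drop = FALSE],
         feature = ms$cache$feature[i, , drop = FALSE],
         pc = ms$cache$pc[i, , drop = FALSE],
         apfs = ms$cache$apfs[i],
         d_min = ms$cache$d_min, d_max = ms$cache$d_max)
  }
  # positional indexing throughout: graph/sdf order mirrors df order, and
  # it keeps bootstrap subsets (duplicated positions) well-defined
  structure(
    list(df = ms$df[i, , drop = FALSE],
         activities = ms$activities[ms$activities$id %in% ids, , drop = FALSE],
         graphs = ms$graphs[i],
         sdf = if (is.null(ms$sdf)) NULL else suppressWarnings(ms$sdf[i]),
         cache = cache),
    class = "mol_set"
  )
}

#' Concatenate molecule sets
#'
#' Used by the ensemble layer to pool public and private training data.
#' Duplicate ids are disambiguated by prefixing the source set index.
#'
#' @param ... \code{mol_set} objects.
#' @return a single \code{mol_set}.
#' @export
bind_mol_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  ids <- unlist(lapply(sets, function(s) s$df$id))
  if (anyDuplicated(ids)) {
    for (k in seq_along(sets)) {
      pre <- paste0("s", k, ".")
      old <- sets[[k]]$df$id
      sets[[k]]$df$id <- paste0(pre, old)
      sets[[k]]$activities$id <- paste0(pre, sets[[k]]$activities$id)
      names(sets[[k]]$graphs) <- paste0(pre, old)
      if (!is.null(sets[[k]]$sdf)) ChemmineR::cid(sets[[k]]$sdf) <- paste0(pre, old)
      if (!is.null(sets[[k]]$cache)) {
        rownames(sets[[k]]$cache$morgan) <- paste0(pre, old)
        rownames(sets[[k]]$cache$feature) <- paste0(pre, old)
        rownames(sets[[k]]$cache$pc) <- paste0(pre, old)
        names(sets[[k]]$cache$apfs) <- paste0(pre, old)
      }
    }
  }
  df <- do.call(rbind, lapply(sets, `[[`, "df"))
  acts <- do.call(rbind, lapply(sets, `[[`, "activities"))
  graphs <- do.call(c, lapply(sets, `[[`, "graphs"))
  sdfs <- lapply(sets, `[[`, "sdf")
  sdfs <- sdfs[!vapply(sdfs, is.null, logical(1))]
  sdf <- if (length(sdfs) == 0) NULL else {
    out <- sdfs[[1]]
    for (k in seq_along(sdfs)[-1]) out <- c(out, sdfs[[k]])
    out
  }
  caches <- lapply(sets, `[[`, "cache")
  cache <- if (!any(vapply(caches, is.null, logical(1))) &&
               length(unique(vapply(caches, `[[`, 1, "d_min"))) == 1 &&
               length(unique(vapply(caches, `[[`, 1, "d_max"))) == 1) {
    list(morgan = do.call(rbind, lapply(caches, `[[`, "morgan")),
         feature = do.call(rbind, lapply(caches, `[[`, "feature")),
         pc = do.call(rbind, lapply(caches, `[[`, "pc")),
         apfs = do.call(c, lapply(caches, `[[`, "apfs")),
         d_min = caches[[1]]$d_min, d_max = caches[[1]]$d_max)
  } else NULL
  structure(list(df = df, activities = acts, graphs = graphs, sdf = sdf,
                 cache = cache),
            class = "mol_set")
}
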