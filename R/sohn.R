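# Self-organising hypothesis network (SOHN) classifier.
#
# Each typed atom-pair feature present in the training set is a candidate
# toxicophoric hypothesis. The most relevant hypotheses are selected by
# recursive partitioning (Shannon information gain on present/absent
# splits), organised into a generality hierarchy by strict support-set
# inclusion (Hasse diagram), and each hypothesis acts as a local kNN model
# over its supporting compounds. A query is answered by the most specific
# applicable hypotheses; their local predictions are combined into a final
# call (most-confident by default).

#' Build the molecule-by-feature incidence matrix
#'
#' @param ms a \code{\link{mol_set}}.
#' @param d_min,d_max atom-pair distance bounds (bonds).
#' @return sparse logical matrix, molecules in rows (ids as rownames),
#'   atom-pair feature codes in lexicographically sorted columns.
#' @export
atom_pair_incidence <- function(ms, d_min = 2L, d_max = 20L) {
  fsets <- cached_apfs(ms, d_min, d_max)
  codes <- sort(unique(unlist(fsets, use.names = FALSE)))
  i <- rep(seq_along(fsets), lengths(fsets))
  j <- match(unlist(fsets, use.names = FALSE), codes)
  m <- Matrix::sparseMatrix(i = i, j = j,
                            dims = c(length(fsets), length(codes)),
                            dimnames = list(names(fsets), codes))
  methods::as(m, "nMatrix")
}

shannon_entropy <- function(p) {
  q <- 1 - p
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
  h
}

# Recursive-partitioning hypothesis selection over the incidence matrix.
# Returns a data.frame of selected features with their selection score —
# the node-weighted information gain (node weight fraction x local gain),
# the feature's contribution to the total impurity decrease, comparable
# across nodes of different sizes — plus the node depth.
select_features_rp <- function(X, y01, w, min_support, max_depth) {
  selected <- new.env(parent = emptyenv())
  codes <- colnames(X)
  w_total <- sum(w)
  recurse <- function(idx, depth) {
    if (length(idx) < 2L || depth >= max_depth) return(invisible(NULL))
    wn <- w[idx]
    tot <- sum(wn)
    p_node <- sum(wn[y01[idx] == 1L]) / tot
    if (p_node <= 0 || p_node >= 1) return(invisible(NULL))  # pure node
    sub <- X[idx, , drop = FALSE]
    npres <- Matrix::colSums(sub)
    eligible <- npres >= min_support & npres <= length(idx) - 1L
    if (!any(eligible)) return(invisible(NULL))
    wpres <- as.numeric(Matrix::crossprod(sub, wn))
    wpos <- as.numeric(Matrix::crossprod(sub, wn * (y01[idx] == 1L)))
    h_node <- shannon_entropy(p_node)
    wabs <- tot - wpres
    wpos_abs <- sum(wn * (y01[idx] == 1L)) - wpos
    gain <- rep(-Inf, ncol(X))
    e <- which(eligible)
    gain[e] <- h_node -
      (wpres[e] / tot) * shannon_entropy(wpos[e] / wpres[e]) -
      (wabs[e] / tot) * shannon_entropy(wpos_abs[e] / wabs[e])
    if (max(gain) <= 1e-12) return(invisible(NULL))
    # deterministic tie-break: gain desc, node support desc, code asc
    best <- e[order(-gain[e], -npres[e], codes[e])][1]
    code <- codes[best]
    weighted_gain <- gain[best] * tot / w_total
    prev <- selected[[code]]
    if (is.null(prev) || prev$gain < weighted_gain) {
      selected[[code]] <- list(gain = weighted_gain, depth = depth)
    }
    has <- as.logical(sub[, best])
    recurse(idx[has], depth + 1L)
    recurse(idx[!has], depth + 1L)
    invisible(NULL)
  }
  recurse(seq_along(y01), 0L)
  feats <- ls(selected)
  if (length(feats) == 0L) {
    return(data.frame(feature = character(0), gain = numeric(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    feature = feats,
    gain = vapply(feats, function(f) selected[[f]]$gain, numeric(1)),
    depth = vapply(feats, function(f) selected[[f]]$depth, integer(1)),
    stringsAsFactors = FALSE)
  sup <- Matrix::colSums(X[, out$feature, drop = FALSE])
  out <- out[order(-out$gain, -sup, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the hypothesis network (Hasse diagram of support inclusion)
#'
#' Hypotheses with identical support sets are merged into one node keeping
#' all their features. Edges run from parent (more general, larger
#' support) to child (support strictly contained in the parent's), with
#' transitive shortcuts removed.
#'
#' @param features character vector of hypothesis feature codes.
#' @param supports list of integer support index vectors, parallel to
#'   \code{features}.
#' @return list with \code{node_features} (list), \code{node_support}
#'   (list), \code{edges} (two-column matrix parent, child) and
#'   \code{strict_subset} (logical matrix; \code{[i, j]} true when node i's
#'   support is strictly contained in node j's).
#' @export
build_network <- function(features, supports) {
  stopifnot(length(features) == length(supports))
  if (length(features) == 0L) {
    return(list(node_features = list(), node_support = list(),
                edges = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("parent", "child"))),
                strict_subset = matrix(logical(0), 0, 0)))
  }
  keys <- vapply(supports, function(s) paste(sort(s), collapse = ","),
                 character(1))
  uk <- unique(keys)
  node_features <- lapply(uk, function(k) sort(features[keys == k]))
  node_support <- lapply(uk, function(k) sort(supports[[match(k, keys)]]))
  h <- length(uk)
  sizes <- lengths(node_support)
  strict <- matrix(FALSE, h, h)
  for (i in seq_len(h)) {
    for (j in seq_len(h)) {
      if (i != j && sizes[i] < sizes[j]) {
        strict[i, j] <- all(node_support[[i]] %in% node_support[[j]])
      }
    }
  }
  # transitive reduction: drop i->j if an intermediate k exists
  shortcut <- (strict %*% strict) > 0
  reduced <- strict & !shortcut
  ij <- which(reduced, arr.ind = TRUE)
  edges <- cbind(parent = ij[, 2], child = ij[, 1])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  list(node_features = node_features, node_support = node_support,
       edges = edges, strict_subset = strict)
}

#' Train a SOHN classifier
#'
#' @param ms curated \code{\link{mol_set}} (every compound has a call).
#' @param weights optional per-compound training weights (see
#'   \code{\link{weighted_training_set}}); default all 1.
#' @param k neighbours per local kNN model (default 5).
#' @param min_support minimum number of supporting compounds for a
#'   hypothesis at its selection node (default 5).
#' @param max_depth recursion depth limit of the partitioning (default 10).
#' @param d_min,d_max atom-pair topological distance bounds (default 2-20).
#' @param combine \code{"max_confidence"} (default): the final call is the
#'   most confident local prediction; \code{"vote"}: confidence-weighted
#'   vote across applicable hypotheses.
#' @param seed integer seed (the procedure is deterministic; the seed is
#'   recorded for provenance).
#' @return object of class \code{sohn_model}. If no feature has positive
#'   gain (e.g. a single-class training set) the hypothesis list is empty
#'   and prediction falls back to global kNN.
#' @export
sohn_train <- function(ms, weights = NULL, k = 5L, min_support = 5L,
                       max_depth = 10L, d_min = 2L, d_max = 20L,
                       combine = c("max_confidence", "vote"),
                       seed = HQ_DEFAULT_SEED) {
  combine <- match.arg(combine)
  if (anyNA(ms$df$call)) stop_input("training set must be fully curated")
  y <- ms$df$call
  w <- weights %||% rep(1, nrow(ms$df))
  if (length(w) != nrow(ms$df)) stop_input("weights length mismatch")
  # canonical internal order by id so row permutation cannot change the model
  ord <- order(ms$df$id)
  ms <- subset_mol_set(ms, ord)
  y <- y[ord]; w <- w[ord]
  X <- atom_pair_incidence(ms, d_min = d_min, d_max = d_max)
  y01 <- as.integer(y == "active")
  hyps <- select_features_rp(X, y01, w, min_support, max_depth)
  supports <- lapply(hyps$feature, function(f) which(X[, f]))
  hyps$support_size <- lengths(supports)
  net <- build_network(hyps$feature, supports)
  # map node -> max gain of its features (for reporting)
  node_gain <- vapply(net$node_features, function(fs) {
    max(hyps$gain[match(fs, hyps$feature)])
  }, numeric(1))
  structure(list(
    hypotheses = hyps,
    network = net,
    node_gain = node_gain,
    fp = cached_fp(ms, "morgan"),
    y = y, ids = ms$df$id, weights = w,
    params = list(k = as.integer(k), min_support = as.integer(min_support),
                  max_depth = as.integer(max_depth), d_min = d_min,
                  d_max = d_max, combine = combine, seed = seed),
    version = "sohn/1"
  ), class = "sohn_model")
}

#' @export
print.sohn_model <- function(x, ...) {
  cat(sprintf(
    "<sohn_model> %d hypotheses in %d network nodes, %d training compounds (k=%d)\n",
    nrow(x$hypotheses), length(x$network$node_support), length(x$y),
    x$params$k))
  invisible(x)
}

#' Most specific applicable hypotheses for a query
#'
#' A network node is applicable when one of its features occurs in the
#' query; nodes with an applicable strict descendant (more specific
#' applicable hypothesis) are dropped.
#'
#' @param model a \code{\link{sohn_train}} model.
#' @param query_features character vector of the query's atom-pair codes
#'   (\code{\link{enumerate_atom_pairs}}).
#' @return integer vector of applicable node indices (possibly empty).
#' @export
applicable_hypotheses <- function(model, query_features) {
  net <- model$network
  if (length(net$node_support) == 0L) return(integer(0))
  app <- which(vapply(net$node_features,
                      function(fs) any(fs %in% query_features), logical(1)))
  if (length(app) <= 1L) return(app)
  # keep node i only if no other applicable node has support strictly inside i's
  keep <- vapply(app, function(i) {
    !any(net$strict_subset[setdiff(app, i), i])
  }, logical(1))
  app[keep]
}

#' Local k-nearest-neighbour prediction under one hypothesis
#'
#' Given similarities of the query to a hypothesis' supporting compounds
#' and their labels, takes the \code{min(k, n)} nearest, calls the
#' majority label (ties conservatively active) and scores confidence with
#' \code{\link{sohn_confidence}}.
#'
#' @param similarities numeric similarities in \code{[0, 1]}.
#' @param labels parallel \code{"active"}/\code{"inactive"} labels.
#' @param k neighbourhood size.
#' @param tie_ids optional parallel ids used to break similarity ties
#'   deterministically.
#' @return list with \code{call} and \code{confidence}.
#' @export
local_knn_predict <- function(similarities, labels, k,
                              tie_ids = seq_along(similarities)) {
  stopifnot(length(similarities) == length(labels), length(similarities) > 0,
            k >= 1)
  ord <- order(-similarities, tie_ids)
  take <- ord[seq_len(min(k, length(ord)))]
  s <- similarities[take]; l <- labels[take]
  n_act <- sum(l == "active")
  call <- if (n_act >= length(l) - n_act) "active" else "inactive"
  list(call = call, confidence = sohn_confidence(s, l, call))
}

#' SOHN confidence of a local kNN prediction
#'
#' Interpolates between the two anchor conditions under which confidence
#' is exactly 1 — an exact training-set match (max similarity 1) or full
#' label agreement among the neighbours — as the product of the mean
#' neighbour similarity and the fraction of neighbours agreeing with the
#' call. The value is monotonically non-decreasing in each similarity and
#' in the agreement fraction, and lies in \code{[0, 1]}.
#'
#' @param similarities neighbour similarities in \code{[0, 1]}.
#' @param labels neighbour labels.
#' @param call the emitted call.
#' @return confidence in \code{[0, 1]}.
#' @export
sohn_confidence <- function(similarities, labels, call) {
  stopifnot(length(similarities) == length(labels),
            length(similarities) > 0)
  agree <- mean(labels == call)
  if (max(similarities) >= 1 - 1e-9 || agree >= 1) return(1)
  mean(similarities) * agree
}

#' Predict hERG calls with a SOHN model
#'
#' For each query, the most specific applicable hypotheses each produce a
#' local kNN prediction; these are combined by the model's configured rule
#' (most-confident by default, confidence ties resolved conservatively to
#' active). Queries matching no hypothesis fall back to a global kNN over
#' the whole training set and are flagged out-of-domain in the provenance.
#'
#' @param object a \code{sohn_model}.
#' @param ms a \code{\link{mol_set}} of query molecules.
#' @param ... unused.
#' @return prediction data.frame: \code{id}, \code{call}, \code{confidence},
#'   \code{model}, \code{provenance}.
#' @export
predict.sohn_model <- function(object, ms, ...) {
  qfp <- cached_fp(ms, "morgan")
  sims <- tanimoto_matrix(qfp, object$fp)
  net <- object$network
  k <- object$params$k
  qfeats <- cached_apfs(ms, object$params$d_min, object$params$d_max)
  res <- lapply(seq_len(nrow(ms$df)), function(qi) {
    feats <- qfeats[[qi]]
    app <- applicable_hypotheses(object, feats)
    if (length(app) == 0L) {
      loc <- local_knn_predict(sims[qi, ], object$y, k, object$ids)
      return(list(call = loc$call, confidence = loc$confidence,
                  provenance = "global_knn;out_of_domain"))
    }
    locals <- lapply(app, function(node) {
      sup <- net$node_support[[node]]
      loc <- local_knn_predict(sims[qi, sup], object$y[sup], k,
                               object$ids[sup])
      c(loc, list(node = node))
    })
    calls <- vapply(locals, `[[`, character(1), "call")
    confs <- vapply(locals, `[[`, numeric(1), "confidence")
    if (object$params$combine == "vote") {
      s_act <- sum(confs[calls == "active"])
      s_inact <- sum(confs[calls == "inactive"])
      call <- if (s_act >= s_inact) "active" else "inactive"
      conf <- if (s_act + s_inact > 0) max(s_act, s_inact) / (s_act + s_inact)
              else 0
      prov <- sprintf("vote;nodes=%s", paste(app, collapse = "+"))
    } else {
      best_conf <- max(confs)
      cand <- which(confs >= best_conf - 1e-12)
      # conservative tie policy: an active call wins a confidence tie
      pick <- if (any(calls[cand] == "active")) {
        cand[calls[cand] == "active"][1]
      } else cand[1]
      call <- calls[pick]; conf <- confs[pick]
      prov <- sprintf("hypothesis=%s",
                      net$node_features[[locals[[pick]]$node]][1])
    }
    list(call = call, confidence = conf, provenance = prov)
  })
  new_prediction(
    id = ms$df$id,
    call = vapply(res, `[[`, character(1), "call"),
    confidence = vapply(res, `[[`, numeric(1), "confidence"),
    model = "sohn",
    provenance = vapply(res, `[[`, character(1), "provenance"))
}
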