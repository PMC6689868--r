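# Shared fixtures and independent oracles. Fixtures are parsed once per
# test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A small labelled set where a tertiary-amine side chain perfectly
# separates actives from inactives.
toy_labelled_molset <- function() {
  fixture("toy_labelled", function() {
    df <- data.frame(
      id = sprintf("m%02d", 1:12),
      smiles = c(
        "c1ccccc1CCCN(C)C", "c1ccncc1CCCN(C)C", "Cc1ccccc1CCCN(C)C",
        "Oc1ccccc1CCCN(C)C", "c1ccc(F)cc1CCCN(C)C", "CC(=O)c1ccccc1CCCN(C)C",
        "c1ccccc1CCO", "c1ccncc1OC", "Cc1ccccc1C#N",
        "Oc1ccccc1CC", "c1ccc(F)cc1C(=O)N", "CC(=O)c1ccccc1"
      ),
      call = rep(c("active", "inactive"), each = 6),
      stringsAsFactors = FALSE
    )
    mol_set(df)
  })
}

single_mol_graph <- function(smiles) {
  ms <- mol_set(data.frame(id = "x", smiles = smiles,
                           stringsAsFactors = FALSE))
  ms$graphs[["x"]]
}

# Independent oracle: all-pairs shortest-path BFS over the bond list,
# written without igraph, paired with the package's atom typing.
oracle_atom_pairs <- function(graph, d_min = 2L, d_max = 20L) {
  n <- graph$n
  if (n < 2) return(character(0))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (b in seq_len(nrow(graph$bonds))) {
    a1 <- graph$bonds[b, 1]; a2 <- graph$bonds[b, 2]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  bfs <- function(start) {
    dist <- rep(NA_integer_, n)
    dist[start] <- 0L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    dist
  }
  types <- type_atoms(graph)
  feats <- character(0)
  for (i in seq_len(n - 1)) {
    d <- bfs(i)
    for (j in (i + 1):n) {
      if (!is.na(d[j]) && d[j] >= d_min && d[j] <= d_max) {
        lo <- min(types[i], types[j]); hi <- max(types[i], types[j])
        feats <- c(feats, paste(lo, hi, d[j], sep = "|"))
      }
    }
  }
  sort(unique(feats))
}

# Random small molecules (<= 12 heavy atoms) from a fragment grammar.
random_small_smiles <- function(n, seed) {
  set.seed(seed)
  cores <- c("c1ccccc1", "c1ccncc1", "C1CCCC1", "c1ccsc1", "C1CCNC1",
             "CCCC", "CC(C)C", "c1ccoc1")
  tails <- c("", "C", "CC", "O", "OC", "N", "F", "Cl", "C#N", "C=O")
  vapply(seq_len(n), function(i) {
    core <- sample(cores, 1)
    tail <- sample(tails, 1)
    paste0(core, tail)
  }, character(1))
}

# Independent oracle: exhaustive weighted information-gain scan over every
# feature column, plain loops and base R only.
oracle_best_root_feature <- function(X, y01, w, min_support) {
  ent <- function(p) {
    if (p <= 0 || p >= 1) return(0)
    -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  tot <- sum(w)
  h_root <- ent(sum(w[y01 == 1]) / tot)
  best <- NULL; best_gain <- 1e-12; best_sup <- -1
  for (f in colnames(X)) {
    has <- as.logical(X[, f])
    sup <- sum(has)
    if (sup < min_support || sup > length(y01) - 1) next
    wp <- sum(w[has]); wa <- tot - wp
    g <- h_root - (wp / tot) * ent(sum(w[has & y01 == 1]) / wp) -
      (wa / tot) * ent(sum(w[!has & y01 == 1]) / wa)
    better <- g > best_gain + 1e-12 ||
      (abs(g - best_gain) <= 1e-12 &&
         (sup > best_sup || (sup == best_sup && !is.null(best) && f < best)))
    if (better) { best <- f; best_gain <- g; best_sup <- sup }
  }
  best
}

expect_prediction_frame <- function(p, n) {
  expect_s3_class(p, "data.frame")
  expect_equal(nrow(p), n)
  expect_true(all(c("id", "call", "confidence", "model", "provenance")
                  %in% names(p)))
  expect_true(all(p$call %in% c("active", "inactive")))
}
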