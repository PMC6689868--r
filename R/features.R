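# Molecular features: typed atom pairs, circular fingerprints,
# physicochemical descriptors, Tanimoto similarity.

FP_WIDTH <- 4096L
FP_RADIUS <- 4L
HALOGENS <- c("F", "Cl", "Br", "I")

#' Type the heavy atoms of a molecule
#'
#' Assigns each heavy atom a refined type code combining its element, an
#' aromaticity flag, its hybridisation (derived from bond orders) and the
#' sorted multiset of directly bonded heavy-element symbols, e.g.
#' \code{"C.ar.sp2[C,C,N]"}. This is an approximation of extended
#' Ghose–Crippen typing: two atoms with identical element, hybridisation and
#' neighbour multiset always receive the same code, and typing is invariant
#' to atom-index permutation. Formal charge is ignored.
#'
#' @param graph a molecule graph from a \code{\link{mol_set}}
#'   (\code{ms$graphs[[id]]}).
#' @return character vector, one code per heavy atom.
#' @export
type_atoms <- function(graph) {
  vapply(seq_len(graph$n), function(i) {
    nb <- sort(graph$elem[graph$nbr[[i]]])
    paste0(graph$elem[i],
           if (graph$arom[i]) ".ar" else "",
           ".", graph$hyb[i],
           "[", paste(nb, collapse = ","), "]")
  }, character(1))
}

# Shortest-path bond distances between all heavy-atom pairs.
topo_distances <- function(graph) {
  if (nrow(graph$bonds) == 0) {
    d <- matrix(Inf, graph$n, graph$n); diag(d) <- 0
    return(d)
  }
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  g <- igraph::add_edges(g, t(graph$bonds[, 1:2, drop = FALSE]))
  igraph::distances(g)
}

#' Enumerate typed atom-pair features
#'
#' A feature is an unordered pair of atom type codes together with their
#' shortest topological (bond-count) distance, encoded as
#' \code{"typeA|typeB|d"} with \code{typeA <= typeB} lexicographically.
#' Only distances in \code{[d_min, d_max]} are kept (default 2–20 bonds).
#'
#' @param graph molecule graph.
#' @param d_min,d_max inclusive topological distance bounds.
#' @return sorted character vector of distinct feature codes.
#' @export
enumerate_atom_pairs <- function(graph, d_min = 2L, d_max = 20L) {
  stopifnot(d_min >= 1L, d_min <= d_max)
  n <- graph$n
  if (n < 2L) return(character(0))
  types <- type_atoms(graph)
  d <- topo_distances(graph)
  ut <- upper.tri(d)
  sel <- which(ut & is.finite(d) & d >= d_min & d <= d_max, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(character(0))
  t1 <- types[sel[, 1]]; t2 <- types[sel[, 2]]
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  sort(unique(paste(lo, hi, d[sel], sep = "|")))
}

# Initial atom invariants for the two circular-fingerprint variants.
# "morgan": element/degree/hybridisation/aromaticity (connectivity-like).
# "feature": pharmacophoric role flags (aromatic, H-bond donor/acceptor
# proxies, basic nitrogen, halogen), the FCFP-style variant.
fp_init_invariants <- function(graph, variant) {
  deg <- lengths(graph$nbr)
  if (variant == "morgan") {
    paste0(graph$elem, ";", deg, ";", graph$hyb, ";",
           as.integer(graph$arom))
  } else {
    acceptor <- graph$elem %in% c("N", "O")
    # donor proxy: N/O with spare valence for an implicit hydrogen
    donor <- (graph$elem == "N" & deg < 3L & !graph$arom) |
             (graph$elem == "O" & deg < 2L)
    basic_n <- graph$elem == "N" & graph$hyb == "sp3" & !graph$arom &
      !vapply(seq_len(graph$n), function(i) {
        any(graph$elem[graph$nbr[[i]]] == "C" &
              vapply(graph$nbr[[i]], function(j) {
                any(graph$nbr_bo[[j]] == 2L & graph$elem[graph$nbr[[j]]] == "O")
              }, logical(1)))
      }, logical(1))  # exclude amide-like N
    halogen <- graph$elem %in% HALOGENS
    paste0("F", as.integer(graph$arom), as.integer(acceptor),
           as.integer(donor), as.integer(basic_n), as.integer(halogen))
  }
}

#' Circular (Morgan-style) fingerprint
#'
#' Iterative neighbourhood hashing over the heavy-atom graph: atom
#' identifiers start from the variant's initial invariants and are updated
#' for \code{radius} rounds from the sorted (bond order, neighbour
#' identifier) list; every identifier from every round is folded into a
#' fixed-width bit vector. \code{variant = "feature"} seeds the iteration
#' with pharmacophoric role flags instead of connectivity invariants
#' (the Feature-Morgan analogue).
#'
#' @param graph molecule graph.
#' @param radius neighbourhood radius in bonds (default 4).
#' @param width bit-vector width (default 4096).
#' @param variant \code{"morgan"} or \code{"feature"}.
#' @return sorted integer vector of on-bit positions in \code{1:width}.
#' @export
morgan_fingerprint <- function(graph, radius = FP_RADIUS, width = FP_WIDTH,
                               variant = c("morgan", "feature")) {
  variant <- match.arg(variant)
  ids <- vapply(fp_init_invariants(graph, variant), hq_hash, integer(1),
                USE.NAMES = FALSE)
  bits <- ids
  if (graph$n > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(graph$n), function(i) {
        nb <- graph$nbr[[i]]
        if (length(nb) == 0L) return(hq_hash(paste0(r, "|", ids[i])))
        env <- sort(paste0(graph$nbr_bo[[i]], ":", ids[nb]))
        hq_hash(paste0(r, "|", ids[i], "|", paste(env, collapse = ",")))
      }, integer(1))
      ids <- new_ids
      bits <- c(bits, ids)
    }
  }
  sort(unique(bits %% width + 1L))
}

#' Precompute and cache the feature blocks of a molecule set
#'
#' Computes Morgan and Feature-Morgan fingerprint matrices, the
#' physicochemical descriptor block and the per-molecule atom-pair feature
#' sets, and stores them in the set's \code{cache} slot. Training and
#' prediction functions use the cache when present and compute on the fly
#' otherwise; \code{\link{subset_mol_set}} and \code{\link{bind_mol_sets}}
#' propagate it, so featurising each source once is enough for a whole
#' experiment sweep.
#'
#' @param ms a \code{\link{mol_set}}.
#' @param d_min,d_max atom-pair distance bounds for the cached sets.
#' @return the \code{mol_set} with a filled \code{cache} slot.
#' @export
featurize_mol_set <- function(ms, d_min = 2L, d_max = 20L) {
  ms$cache <- list(
    morgan = fingerprint_matrix(ms, "morgan"),
    feature = fingerprint_matrix(ms, "feature"),
    pc = physchem_descriptors(ms),
    apfs = lapply(ms$graphs, enumerate_atom_pairs, d_min = d_min,
                  d_max = d_max),
    d_min = d_min, d_max = d_max
  )
  ms
}

cached_fp <- function(ms, variant) {
  if (!is.null(ms$cache) && !is.null(ms$cache[[variant]])) {
    return(ms$cache[[variant]])
  }
  fingerprint_matrix(ms, variant)
}

cached_pc <- function(ms, descriptors) {
  if (!is.null(ms$cache) && !is.null(ms$cache$pc) &&
      all(descriptors %in% colnames(ms$cache$pc))) {
    return(ms$cache$pc[, descriptors, drop = FALSE])
  }
  physchem_descriptors(ms, descriptors)
}

cached_apfs <- function(ms, d_min, d_max) {
  if (!is.null(ms$cache) && !is.null(ms$cache$apfs) &&
      identical(ms$cache$d_min, d_min) && identical(ms$cache$d_max, d_max)) {
    return(ms$cache$apfs)
  }
  lapply(ms$graphs, enumerate_atom_pairs, d_min = d_min, d_max = d_max)
}

#' Fingerprint matrix for a molecule set
#'
#' @param ms a \code{\link{mol_set}}.
#' @param variant fingerprint variant, see \code{\link{morgan_fingerprint}}.
#' @param radius,width fingerprint parameters.
#' @return sparse logical matrix (\code{Matrix::ngCMatrix}), molecules in
#'   rows (named by id), bits in columns.
#' @export
fingerprint_matrix <- function(ms, variant = c("morgan", "feature"),
                               radius = FP_RADIUS, width = FP_WIDTH) {
  variant <- match.arg(variant)
  onbits <- lapply(ms$graphs, morgan_fingerprint, radius = radius,
                   width = width, variant = variant)
  i <- rep(seq_along(onbits), lengths(onbits))
  j <- unlist(onbits, use.names = FALSE)
  m <- Matrix::sparseMatrix(i = i, j = j, dims = c(length(onbits), width),
                            dimnames = list(names(ms$graphs), NULL))
  methods::as(m, "nMatrix")
}

#' Tanimoto similarity between two fingerprints
#'
#' \code{|A and B| / |A or B|}. Two empty fingerprints have similarity 0
#' (with a warning); identical non-empty fingerprints have similarity 1.
#'
#' @param a,b fingerprints as on-bit integer vectors
#'   (\code{\link{morgan_fingerprint}}) or logical/0-1 vectors of equal
#'   width.
#' @return similarity in \code{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  if (is.logical(a) || all(a %in% c(0, 1))) {
    if (length(a) != length(b)) stop_input("fingerprint width mismatch")
    a <- which(as.logical(a)); b <- which(as.logical(b))
  }
  inter <- length(intersect(a, b))
  uni <- length(a) + length(b) - inter
  if (uni == 0L) {
    warning("Tanimoto of two empty fingerprints defined as 0", call. = FALSE)
    return(0)
  }
  inter / uni
}

#' Tanimoto similarity matrix between two fingerprint matrices
#'
#' @param A,B sparse logical matrices with equal widths
#'   (\code{\link{fingerprint_matrix}}).
#' @return dense numeric matrix of pairwise similarities,
#'   \code{nrow(A) x nrow(B)}.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop_input("fingerprint width mismatch")
  inter <- as.matrix(Matrix::tcrossprod(
    methods::as(A, "dMatrix"), methods::as(B, "dMatrix")))
  na <- Matrix::rowSums(A); nb <- Matrix::rowSums(B)
  uni <- outer(na, nb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' Default physicochemical descriptor names
#'
#' OpenBabel-computed molecular properties plus graph-derived counts; the
#' \code{descriptors} argument of \code{\link{physchem_descriptors}}
#' selects a subset of these names.
#'
#' @format character vector of descriptor names.
#' @export
PHYSCHEM_DESCRIPTORS <- c(
  "MW", "logP", "TPSA", "MR", "HBD", "HBA1", "HBA2", "nF",
  "heavy_atoms", "n_bonds", "n_rings", "n_aromatic_atoms", "frac_aromatic",
  "n_C", "n_N", "n_O", "n_S", "n_halogen",
  "n_sp3_C", "frac_sp3_C", "n_rotatable", "n_double_bonds", "n_triple_bonds",
  "n_basic_N", "n_amide", "max_degree"
)

#' Physicochemical descriptor block
#'
#' Computes the default descriptor list (OpenBabel molecular properties:
#' MW, logP, TPSA, molar refractivity, H-bond donor/acceptor counts,
#' fluorine count; plus graph-derived counts: atoms, bonds, rings, aromatic
#' fraction, element counts, sp3-carbon fraction, rotatable bonds, basic
#' nitrogens, amides, degree). Non-finite values are imputed to 0 with a
#' logged warning.
#'
#' @param ms a \code{\link{mol_set}}.
#' @param descriptors character vector naming the descriptors to keep
#'   (default: all of \code{PHYSCHEM_DESCRIPTORS}).
#' @return numeric matrix, molecules in rows (named by id); constant column
#'   set across molecules.
#' @export
physchem_descriptors <- function(ms, descriptors = PHYSCHEM_DESCRIPTORS) {
  unknown <- setdiff(descriptors, PHYSCHEM_DESCRIPTORS)
  if (length(unknown) > 0) {
    stop_input("unknown descriptor(s): ", paste(unknown, collapse = ", "))
  }
  pb <- ChemmineR::propOB(ms$sdf)
  gstats <- t(vapply(ms$graphs, function(g) {
    deg <- lengths(g$nbr)
    nb <- nrow(g$bonds)
    in_ring <- ring_membership(g)
    rot <- if (nb == 0) 0L else sum(
      g$bonds[, 3] == 1L & !in_ring &
        deg[g$bonds[, 1]] > 1L & deg[g$bonds[, 2]] > 1L)
    amide_n <- vapply(seq_len(g$n), function(i) {
      g$elem[i] == "N" && any(vapply(g$nbr[[i]], function(j) {
        g$elem[j] == "C" && any(g$nbr_bo[[j]] == 2L &
                                  g$elem[g$nbr[[j]]] == "O")
      }, logical(1)))
    }, logical(1))
    basic_n <- g$elem == "N" & g$hyb == "sp3" & !g$arom & !amide_n
    n_c <- sum(g$elem == "C")
    c(heavy_atoms = g$n,
      n_bonds = nb,
      n_rings = nb - g$n + components_count(g),
      n_aromatic_atoms = sum(g$arom),
      frac_aromatic = if (g$n > 0) sum(g$arom) / g$n else 0,
      n_C = n_c, n_N = sum(g$elem == "N"), n_O = sum(g$elem == "O"),
      n_S = sum(g$elem == "S"), n_halogen = sum(g$elem %in% HALOGENS),
      n_sp3_C = sum(g$elem == "C" & g$hyb == "sp3"),
      frac_sp3_C = if (n_c > 0) sum(g$elem == "C" & g$hyb == "sp3") / n_c else 0,
      n_rotatable = rot,
      n_double_bonds = if (nb == 0) 0L else sum(g$bonds[, 3] == 2L),
      n_triple_bonds = if (nb == 0) 0L else sum(g$bonds[, 3] == 3L),
      n_basic_N = sum(basic_n),
      n_amide = sum(amide_n),
      max_degree = if (g$n > 0) max(deg, 0L) else 0L)
  }, numeric(18)))
  ob <- as.matrix(pb[, c("MW", "logP", "TPSA", "MR", "HBD", "HBA1", "HBA2",
                         "nF")])
  mode(ob) <- "numeric"
  out <- cbind(ob, gstats)[, descriptors, drop = FALSE]
  rownames(out) <- ms$df$id
  if (any(!is.finite(out))) {
    hq_log("warn", sum(!is.finite(out)),
           " non-finite descriptor value(s) imputed to 0")
    out[!is.finite(out)] <- 0
  }
  out
}

# number of connected components of the heavy-atom graph
components_count <- function(g) {
  if (g$n == 0L) return(0L)
  if (nrow(g$bonds) == 0L) return(g$n)
  gr <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  gr <- igraph::add_edges(gr, t(g$bonds[, 1:2, drop = FALSE]))
  igraph::components(gr)$no
}

# per-bond ring membership flags
ring_membership <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  gr <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  gr <- igraph::add_edges(gr, t(g$bonds[, 1:2, drop = FALSE]))
  # a bond is in a ring iff removing it leaves its endpoints connected
  vapply(seq_len(nb), function(b) {
    g2 <- igraph::delete_edges(gr, b)
    igraph::distances(g2, v = g$bonds[b, 1], to = g$bonds[b, 2])[1, 1] < Inf
  }, logical(1))
}
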