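#' Build a co-occurrence network from fruitbody samples
#'
#' Pairwise correlations over relative abundances; node pairs with
#' `|r| >= r_min` become undirected edges (no self-loops). Each node also
#' records its correlation with the TM phylotype when present.
#'
#' @param rel samples x phylotypes relative-abundance matrix (>= 5 samples;
#'   pass a prefiltered fruitbody sub-table).
#' @param r_min absolute correlation threshold for edges (default 0.35).
#' @param method correlation type.
#' @param tm_id column name of the TM phylotype; when present, per-node
#'   correlations with TM are recorded for cluster labeling.
#' @return object of class `cooccurrence_network`: `nodes`, `edges`
#'   (`source`, `target`, `r`), `adjacency` (|r| weights), `tm_correlation`.
#' @export
build_network <- function(rel, r_min = 0.35, method = c("pearson", "spearman"),
                          tm_id = NULL) {
  method <- match.arg(method)
  if (nrow(rel) < 5) stop("need >= 5 samples for stable correlations")
  keep <- apply(rel, 2, stats::sd) > 0
  rel <- rel[, keep, drop = FALSE]
  cm <- stats::cor(rel, method = method)
  diag(cm) <- 0
  adj <- abs(cm) * (abs(cm) >= r_min)
  idx <- which(upper.tri(cm) & abs(cm) >= r_min, arr.ind = TRUE)
  edges <- data.frame(source = colnames(cm)[idx[, 1]],
                      target = colnames(cm)[idx[, 2]],
                      r = cm[idx], stringsAsFactors = FALSE)
  tm_cor <- if (!is.null(tm_id) && tm_id %in% colnames(cm)) {
    v <- cm[, tm_id]
    v[tm_id] <- 1
    v
  } else NULL
  structure(list(nodes = colnames(cm), edges = edges, adjacency = adj,
                 signed = cm, tm_correlation = tm_cor),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Markov clustering (MCL) of a weighted network
#'
#' Standard MCL over edge weights `|r|`: self-loops are added (weight = the
#' node's maximum incident `|r|`, at least 1e-3), columns are normalized to
#' sum 1, then expansion (matrix squaring) and inflation (elementwise power
#' followed by column renormalization) iterate until the maximum column
#' change falls below `tol`. Clusters are the connected components of the
#' attractor graph. Deterministic and invariant to node input order.
#'
#' @param network a `cooccurrence_network` or a non-negative weight matrix.
#' @param inflation inflation exponent (default 2.0).
#' @param max_iter iteration cap (default 200); non-convergence returns the
#'   current clustering with a warning.
#' @param tol convergence tolerance on the transition matrix (default 1e-6).
#' @return list with `membership` (named integer vector, cluster ids in
#'   order of first appearance), `n_clusters`, `iterations`, `converged`.
#' @export
mcl <- function(network, inflation = 2.0, max_iter = 200, tol = 1e-6) {
  A <- if (inherits(network, "cooccurrence_network")) network$adjacency
       else as.matrix(network)
  if (nrow(A) == 0) stop("empty network")
  if (any(A < 0)) stop("MCL requires non-negative weights")
  loops <- pmax(apply(A, 1, max), 1e-3)
  diag(A) <- loops
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  it <- 0
  colsum_dev <- 0
  while (it < max_iter) {
    it <- it + 1
    M_new <- normalize((M %*% M)^inflation)
    colsum_dev <- max(colsum_dev, abs(colSums(M_new) - 1))
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")
  # attractor graph: nonzero entries of the limit matrix, symmetrized
  g <- igraph::graph_from_adjacency_matrix((M > 1e-6) | t(M > 1e-6),
                                           mode = "undirected")
  memb <- igraph::components(g)$membership
  # renumber clusters by first node appearance for order invariance
  first_seen <- unique(memb)
  memb <- match(memb, first_seen)
  names(memb) <- rownames(A)
  list(membership = memb, n_clusters = max(memb), iterations = it,
       converged = converged, max_colsum_dev = colsum_dev)
}

#' Label MCL clusters by their relationship with TM
#'
#' Each cluster is labeled `TM-positive` or `TM-negative` by the majority
#' sign among member nodes whose `|r|` with TM reaches `r_min`; clusters
#' with no such member (or a tie) are `neutral`. Node degrees are reported
#' and the maximum-degree node flagged as the hub.
#'
#' @param network a `cooccurrence_network` built with `tm_id`.
#' @param clustering result of [mcl()].
#' @param r_min correlation threshold used for membership sign (default 0.35).
#' @return list with `clusters` (data.frame: `cluster`, `label`, `n_nodes`)
#'   and `nodes` (data.frame: `node`, `cluster`, `tm_r`, `degree`, `is_hub`).
#' @export
group_by_tm <- function(network, clustering, r_min = 0.35) {
  memb <- clustering$membership
  deg <- stats::setNames(rowSums(network$adjacency > 0), network$nodes)
  tm <- network$tm_correlation
  nodes <- data.frame(node = network$nodes,
                      cluster = unname(memb[network$nodes]),
                      tm_r = if (is.null(tm)) NA_real_ else unname(tm[network$nodes]),
                      degree = unname(deg[network$nodes]),
                      stringsAsFactors = FALSE)
  nodes$is_hub <- nodes$degree == max(nodes$degree) & nodes$degree > 0
  labels <- vapply(sort(unique(nodes$cluster)), function(cl) {
    if (is.null(tm)) return("unlabeled")
    r <- nodes$tm_r[nodes$cluster == cl]
    strong <- r[!is.na(r) & abs(r) >= r_min]
    if (length(strong) == 0) return("neutral")
    n_pos <- sum(strong > 0)
    n_neg <- sum(strong < 0)
    if (n_pos > n_neg) "TM-positive" else if (n_neg > n_pos) "TM-negative"
    else "neutral"
  }, character(1))
  clusters <- data.frame(cluster = sort(unique(nodes$cluster)), label = labels,
                         n_nodes = as.integer(table(nodes$cluster)),
                         stringsAsFactors = FALSE)
  list(clusters = clusters, nodes = nodes)
}
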