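#' Maximum spanning tree of a weighted adjacency matrix
#'
#' Kruskal's algorithm on descending edge weights: edges are added in
#' order of decreasing weight, skipping any edge that would close a
#' loop, until all nodes are connected. Weight ties are broken by
#' lexicographic `(i, j)` order for determinism. Zero-weight edges are
#' admitted, so any symmetric nonnegative matrix over >= 2 nodes yields
#' a spanning tree.
#'
#' @param adjacency symmetric nonnegative `n x n` matrix (e.g. a PLI
#'   adjacency); the diagonal is ignored.
#' @param node_labels optional node labels (defaults to the matrix
#'   dimnames, then to `1..n`).
#' @return an object of class `spanning_tree`: list with `n_nodes`,
#'   `edges` (data.frame `i`, `j`, `weight` with `i < j`), and
#'   `node_labels`.
#' @export
max_spanning_tree <- function(adjacency, node_labels = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 2) stop("need at least 2 nodes")
  if (ncol(adjacency) != n ||
      max(abs(adjacency - t(adjacency))) > 1e-9)
    stop("adjacency must be square and symmetric")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  if (is.null(node_labels)) node_labels <- rownames(adjacency)
  if (is.null(node_labels)) node_labels <- as.character(seq_len(n))
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  ww <- adjacency[cbind(ii, jj)]
  ord <- order(-ww, ii, jj)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  keep <- integer(n - 1)
  got <- 0L
  for (k in ord) {
    ri <- find(ii[k]); rj <- find(jj[k])
    if (ri != rj) {
      parent[ri] <- rj
      got <- got + 1L
      keep[got] <- k
      if (got == n - 1L) break
    }
  }
  edges <- data.frame(i = ii[keep], j = jj[keep], weight = ww[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_nodes = n, edges = edges,
                 node_labels = as.character(node_labels)),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, total weight %.4f\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Binarize a spanning tree
#'
#' Sets all edge weights to 1 while preserving the topology. The
#' original PLI weights are retained in the `pli_weights` attribute so
#' the mean-edge-PLI measure is still computed from the pre-binarization
#' weights.
#'
#' @param tree a `spanning_tree`.
#' @return a `spanning_tree` with unit weights.
#' @export
binarize <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  original <- attr(tree, "pli_weights")
  if (is.null(original)) original <- tree$edges$weight
  tree$edges$weight <- rep(1, nrow(tree$edges))
  attr(tree, "pli_weights") <- original
  tree
}

#' Topological measure suite of a spanning tree
#'
#' Computes the global tree measures and the per-node degree and
#' betweenness vectors. With `N` nodes and `m = N - 1` links, the
#' normalization conventions are: degree, leaf fraction, diameter and
#' eccentricity are divided by `m`; betweenness centrality is divided by
#' the undirected pair count `(N - 1)(N - 2) / 2`; tree hierarchy is
#' `Th = L / (2 m MaxBC)` with `L` the raw leaf count. The mean edge PLI
#' (`mst_pli`) is the mean of the `m` edge weights (pre-binarization
#' weights if the tree was binarized).
#'
#' @param tree a `spanning_tree`.
#' @return an object of class `mst_measures`: list with the normalized
#'   scalars `diameter`, `leaf_fraction`, `max_bc`, `max_degree`,
#'   `tree_hierarchy`, `mst_pli`, the raw counts `raw_max_degree`,
#'   `raw_leaf_count`, `raw_diameter`, and per-node vectors
#'   `eccentricity`, `node_bc`, `node_degree` (named by node label).
#' @export
mst_measures <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n_nodes
  m <- n - 1
  deg <- tabulate(c(tree$edges$i, tree$edges$j), nbins = n)
  leaves <- sum(deg == 1)
  g <- igraph::graph_from_edgelist(
    cbind(tree$edges$i, tree$edges$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  hops <- igraph::distances(g)
  ecc <- apply(hops, 1, max)
  diam <- max(ecc)
  pairs <- m * (n - 2) / 2  # (N-1)(N-2)/2 undirected pairs
  bc_raw <- igraph::betweenness(g, directed = FALSE)
  bc <- if (pairs > 0) bc_raw / pairs else rep(0, n)
  max_bc <- max(bc)
  wts <- attr(tree, "pli_weights")
  if (is.null(wts)) wts <- tree$edges$weight
  labels <- tree$node_labels
  names(bc) <- labels
  ecc_n <- ecc / m
  names(ecc_n) <- labels
  deg_n <- deg / m
  names(deg_n) <- labels
  structure(
    list(diameter = diam / m,
         leaf_fraction = leaves / m,
         max_bc = max_bc,
         max_degree = max(deg) / m,
         tree_hierarchy = if (max_bc > 0) leaves / (2 * m * max_bc)
                          else NA_real_,
         mst_pli = mean(wts),
         raw_max_degree = max(deg),
         raw_leaf_count = leaves,
         raw_diameter = diam,
         eccentricity = ecc_n,
         node_bc = bc,
         node_degree = deg_n),
    class = "mst_measures")
}

#' Maximum spanning trees of every network in a PLI stack
#'
#' @param stack a `pli_stack` from [connectivity_stack()].
#' @return an object of class `mst_stack`: list with `trees` (list of
#'   `spanning_tree`s) and `index` (data.frame `trial`, `condition`,
#'   `subject`, `band`, `window` aligned with `trees`).
#' @export
mst_stack <- function(stack) {
  stopifnot(inherits(stack, "pli_stack"))
  d <- dim(stack$pli)
  combos <- expand.grid(trial = seq_len(d[3]),
                        band = stack$bands,
                        window = seq_len(d[5]),
                        stringsAsFactors = FALSE)
  trees <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    b <- match(combos$band[k], stack$bands)
    trees[[k]] <- max_spanning_tree(
      stack$pli[, , combos$trial[k], b, combos$window[k]],
      stack$channel_labels)
  }
  index <- data.frame(
    trial = combos$trial,
    condition = stack$meta$condition[combos$trial],
    subject = stack$meta$subject[combos$trial],
    band = combos$band, window = combos$window,
    stringsAsFactors = FALSE)
  structure(list(trees = trees, index = index), class = "mst_stack")
}

#' Per-trial MST measure tables
#'
#' @param msts an `mst_stack` from [mst_stack()].
#' @return list with `global` (one row per tree: trial, condition,
#'   subject, band, window, the six global measures and the raw
#'   line/star diagnostics) and `nodal` (long format: one row per tree
#'   and node with normalized degree and betweenness).
#' @export
mst_measure_table <- function(msts) {
  stopifnot(inherits(msts, "mst_stack"))
  nk <- length(msts$trees)
  n_nodes <- msts$trees[[1]]$n_nodes
  gl <- vector("list", nk)
  nodal_deg <- matrix(0, nk, n_nodes)
  nodal_bc <- matrix(0, nk, n_nodes)
  for (k in seq_len(nk)) {
    mm <- mst_measures(msts$trees[[k]])
    gl[[k]] <- c(diameter = mm$diameter,
                 leaf_fraction = mm$leaf_fraction,
                 max_bc = mm$max_bc, max_degree = mm$max_degree,
                 tree_hierarchy = mm$tree_hierarchy,
                 mst_pli = mm$mst_pli,
                 raw_max_degree = mm$raw_max_degree,
                 raw_leaf_count = mm$raw_leaf_count,
                 raw_diameter = mm$raw_diameter)
    nodal_deg[k, ] <- mm$node_degree
    nodal_bc[k, ] <- mm$node_bc
  }
  global <- cbind(msts$index, as.data.frame(do.call(rbind, gl)))
  labels <- msts$trees[[1]]$node_labels
  nodal <- data.frame(
    msts$index[rep(seq_len(nk), each = n_nodes), ],
    node = rep(labels, times = nk),
    node_degree = as.vector(t(nodal_deg)),
    node_bc = as.vector(t(nodal_bc)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(global = global, nodal = nodal)
}
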