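# Independent oracles used across the suite.

# Decode a Pruefer sequence into the edge list of its labeled tree.
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 0L
  for (v in seq) {
    leaf <- which(degree == 1L)[1]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(min(leaf, v), max(leaf, v))
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- c(min(last), max(last))
  edges
}

# Exhaustive maximum spanning-tree weight over all n^(n-2) labeled trees.
best_tree_weight <- function(adj) {
  n <- nrow(adj)
  if (n == 2) return(adj[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(seqs[r, ], n)
    w <- sum(adj[e])
    if (w > best) best <- w
  }
  best
}

# Concatenate 3-d arrays along the third dimension.
abind_3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], total))
  at <- 0
  for (p in parts) {
    out[, , at + seq_len(dim(p)[3])] <- p
    at <- at + dim(p)[3]
  }
  out
}

# Random symmetric nonnegative weight matrix.
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Direct Benjamini-Hochberg step-up computation.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force pairwise AUC (probability a positive outscores a negative,
# ties counted half).
auc_pairwise <- function(dec, labels, positive) {
  pos <- dec[labels == positive]
  neg <- dec[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Weighted graph on n nodes whose dominant edges form a simple chain
# 1-2-...-n (background weights below 0.5, chain edges above 0.8).
chain_dominant_adjacency <- function(n) {
  a <- random_adjacency(n) * 0.5
  for (i in seq_len(n - 1)) {
    w <- runif(1, 0.8, 1)
    a[i, i + 1] <- w
    a[i + 1, i] <- w
  }
  a
}

# Weighted graph whose dominant edges form a star around `hub`.
hub_dominant_adjacency <- function(n, hub = 1) {
  a <- random_adjacency(n) * 0.5
  for (j in setdiff(seq_len(n), hub)) {
    w <- runif(1, 0.8, 1)
    a[hub, j] <- w
    a[j, hub] <- w
  }
  a
}

# Hand-built spanning trees.
path_tree <- function(n, weight = 1) {
  max_spanning_tree(chain_adjacency_exact(n, weight))
}

chain_adjacency_exact <- function(n, weight = 1) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    a[i, i + 1] <- weight
    a[i + 1, i] <- weight
  }
  a
}

star_adjacency_exact <- function(n, weight = 1, hub = 1) {
  a <- matrix(0, n, n)
  for (j in setdiff(seq_len(n), hub)) {
    a[hub, j] <- weight
    a[j, hub] <- weight
  }
  a
}

star_tree <- function(n, weight = 1, hub = 1) {
  max_spanning_tree(star_adjacency_exact(n, weight, hub))
}

# Small two-band plan used by the pipeline-level fixtures: the two bands
# are spectrally well separated so cross-band leakage is negligible.
test_band_plan <- function() list(theta = c(4, 8), gamma = c(31, 46))

# Planted star-vs-chain configuration over `nch` channels with coupling
# in the gamma band, analysis window 2 (and optionally 3).
planted_config <- function(n_per, nch = 12, seed = 1, windows = "2",
                           conditions = c("face", "ketch", "scrambled")) {
  star <- star_coupling(nch)
  chain <- chain_coupling(nch)
  sw <- stats::setNames(rep(list(star), length(windows)), windows)
  cw <- stats::setNames(rep(list(chain), length(windows)), windows)
  synth_config(
    n_subjects = 1, trials_per_condition = n_per, n_channels = nch,
    band_plan = test_band_plan(), conditions = conditions,
    coupling_plan = list(face = list(gamma = sw),
                         ketch = list(gamma = cw)),
    noise_sd = 0.3, seed = seed)
}

# Generator output -> PLI stack, without re-referencing (the synthetic
# signals are reference-free; see the methods vignette).
planted_stack <- function(cfg) {
  ep <- baseline_correct(generate_dataset(cfg))
  connectivity_stack(ep, cfg$band_plan, cfg$n_windows, cfg$window_ms)
}
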