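#' Two-sided Wilcoxon rank-sum test with direction
#'
#' Exact enumeration when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. If every value in both samples is identical
#' the test is degenerate and p = 1 is returned with a flag.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list with `p_value`, `statistic` (rank-sum W of `sample_a`),
#'   `direction` (sign of `median(a) - median(b)`), and `degenerate`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty")
  combined <- c(sample_a, sample_b)
  if (max(combined) == min(combined)) {
    return(list(p_value = 1, statistic = NA_real_, direction = 0,
                degenerate = TRUE))
  }
  exact <- length(combined) <= 20 && !anyDuplicated(combined)
  ht <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       direction = sign(median(sample_a) - median(sample_b)),
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values. The family size may exceed the number of
#' p-values supplied, which is used when only a gated subset of a full
#' (band x window) grid is actually tested but the correction family is
#' the whole grid.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param n_family family size for the correction (default
#'   `length(p_values)`).
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values, n_family = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH",
           n = max(n_family, length(p_values)))
}

#' Dissimilarity gate over the (band, window) grid
#'
#' Runs a rank-sum test of the reference-tree dissimilarity scores of
#' the two contrast conditions in every (band, window) cell, adjusts
#' across the full grid by FDR, and flags the cells whose adjusted
#' p-value is at most `alpha`. Downstream measure testing is restricted
#' to the passing cells.
#'
#' @param diss data.frame from [dissimilarity_table()].
#' @param contrast character vector of the two contrast condition
#'   labels.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (band, window) cell: `band`,
#'   `window`, `p_raw`, `p_adj`, `direction`, `pass`.
#' @export
gate_by_dissimilarity <- function(diss, contrast, alpha = 0.05) {
  stopifnot(length(contrast) == 2)
  bands <- unique(diss$band)
  windows <- sort(unique(diss$window))
  grid <- expand.grid(band = bands, window = windows,
                      stringsAsFactors = FALSE)
  grid$p_raw <- NA_real_
  grid$direction <- NA_real_
  keep <- rep(TRUE, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sel <- diss$band == grid$band[k] & diss$window == grid$window[k]
    a <- diss$score[sel & diss$condition == contrast[1]]
    b <- diss$score[sel & diss$condition == contrast[2]]
    if (length(a) == 0 || length(b) == 0) {
      warning("cell (", grid$band[k], ", T", grid$window[k],
              ") is missing a contrast condition; skipped")
      keep[k] <- FALSE
      next
    }
    ht <- rank_sum_test(a, b)
    grid$p_raw[k] <- ht$p_value
    grid$direction[k] <- ht$direction
  }
  grid <- grid[keep, , drop = FALSE]
  grid$p_adj <- fdr_adjust(grid$p_raw, n_family = nrow(grid))
  grid$pass <- grid$p_adj <= alpha
  rownames(grid) <- NULL
  grid[, c("band", "window", "p_raw", "p_adj", "direction", "pass")]
}

# One measure family: rank-sum per gated cell (and node, for nodal
# measures), BH-adjusted with the full grid(-by-node) family size.
test_measure_family <- function(df, value_col, gate, contrast,
                                n_family, by_node = FALSE) {
  cells <- gate[gate$pass, c("band", "window"), drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    sel <- df$band == cells$band[k] & df$window == cells$window[k]
    nodes <- if (by_node) unique(df$node[sel]) else NA_character_
    for (nd in nodes) {
      sub <- sel
      if (by_node) sub <- sel & df$node == nd
      a <- df[[value_col]][sub & df$condition == contrast[1]]
      b <- df[[value_col]][sub & df$condition == contrast[2]]
      ht <- rank_sum_test(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        band = cells$band[k], window = cells$window[k], node = nd,
        p_raw = ht$p_value, direction = ht$direction,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_adjust(out$p_raw, n_family = n_family)
  out
}

#' Significant-feature selection table
#'
#' Tests each global MST measure (diameter, leaf fraction, maximum
#' betweenness, maximum degree, tree hierarchy, mean edge PLI) between
#' the two contrast conditions in every cell that passed the
#' dissimilarity gate, and likewise each node's degree and betweenness.
#' Correction families are per measure: the full band-by-window grid
#' for global measures, and the grid times the node count for nodal
#' measures, even when the gate restricts which cells are actually
#' tested.
#'
#' @param measures list with `global` and `nodal` data.frames from
#'   [mst_measure_table()] (the `nodal` element may be `NULL` to skip
#'   nodal testing).
#' @param gate data.frame from [gate_by_dissimilarity()].
#' @param contrast the two contrast condition labels.
#' @param alpha significance level (default 0.05).
#' @param grid_size correction family size for global measures;
#'   defaults to bands x windows as observed in `measures$global`.
#' @return an object of class `selection_table`: data.frame with
#'   `measure`, `band`, `window`, `node` (`NA` for global measures),
#'   `p_raw`, `p_adj`, `direction`, `significant`, plus a
#'   `correction_scope` attribute describing the families.
#' @export
select_features <- function(measures, gate, contrast, alpha = 0.05,
                            grid_size = NULL) {
  global <- measures$global
  nodal <- measures$nodal
  if (is.null(grid_size))
    grid_size <- length(unique(global$band)) *
      length(unique(global$window))
  global_measures <- c("diameter", "leaf_fraction", "max_bc",
                       "max_degree", "tree_hierarchy", "mst_pli")
  out <- list()
  for (msr in global_measures) {
    fam <- test_measure_family(global, msr, gate, contrast,
                               n_family = grid_size)
    if (!is.null(fam)) {
      fam$measure <- msr
      out[[length(out) + 1]] <- fam
    }
  }
  if (!is.null(nodal) && nrow(nodal) > 0) {
    n_nodes <- length(unique(nodal$node))
    for (msr in c("node_degree", "node_bc")) {
      fam <- test_measure_family(nodal, msr, gate, contrast,
                                 n_family = grid_size * n_nodes,
                                 by_node = TRUE)
      if (!is.null(fam)) {
        fam$measure <- msr
        out[[length(out) + 1]] <- fam
      }
    }
  }
  if (length(out) == 0) {
    tab <- data.frame(measure = character(0), band = character(0),
                      window = integer(0), node = character(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      direction = numeric(0),
                      significant = logical(0))
  } else {
    tab <- do.call(rbind, out)
    tab$significant <- tab$p_adj <= alpha
    tab <- tab[, c("measure", "band", "window", "node", "p_raw",
                   "p_adj", "direction", "significant")]
    rownames(tab) <- NULL
  }
  attr(tab, "alpha") <- alpha
  attr(tab, "correction_scope") <- paste0(
    "BH per measure; family = full band x window grid (m = ",
    grid_size, "), times node count for nodal measures")
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Feature manifest from a selection table
#'
#' The significant rows of a [select_features()] table, ordered
#' deterministically by band, window, measure and node: the list of
#' (measure, band, window\[, node\]) tuples assembled into the
#' classifier's feature matrix.
#'
#' @param selection a `selection_table`.
#' @return data.frame with `measure`, `band`, `window`, `node`.
#' @export
feature_manifest <- function(selection) {
  sig <- selection[selection$significant, , drop = FALSE]
  sig <- sig[order(sig$band, sig$window, sig$measure, sig$node,
                   na.last = TRUE), , drop = FALSE]
  rownames(sig) <- NULL
  as.data.frame(sig[, c("measure", "band", "window", "node")])
}
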