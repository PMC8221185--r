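#' Reference maximum spanning tree from averaged adjacencies
#'
#' Element-wise mean of a stack of connectivity matrices (typically all
#' trials of the reference/"scrambled" condition in one band and
#' window), followed by maximum-spanning-tree extraction of the mean.
#'
#' @param matrices list of equal-shape symmetric matrices, or a 3-d array
#'   with the stacking dimension last. If matrices carry `band_label` /
#'   `window_index` attributes they must all agree.
#' @param node_labels optional node labels for the resulting tree.
#' @return a `spanning_tree` of the averaged adjacency.
#' @export
reference_mst <- function(matrices, node_labels = NULL) {
  if (is.array(matrices) && length(dim(matrices)) == 3) {
    matrices <- lapply(seq_len(dim(matrices)[3]),
                       function(k) matrices[, , k])
  }
  stopifnot(length(matrices) >= 1)
  meta <- lapply(matrices, function(m)
    c(attr(m, "band_label"), attr(m, "window_index")))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta) > 1 &&
      length(unique(vapply(meta, paste, character(1),
                           collapse = "/"))) > 1)
    stop("matrices mix band/window metadata")
  mean_adj <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  if (is.null(node_labels)) node_labels <- rownames(matrices[[1]])
  max_spanning_tree(mean_adj, node_labels)
}

# Per-node sums of distances to direct tree neighbours.
neighbour_distance_sums <- function(tree, distance) {
  w <- tree$edges$weight
  d <- switch(distance,
              reciprocal = {
                if (any(w <= 0))
                  stop("zero-PLI tree edge: reciprocal distance ",
                       "undefined")
                1 / w
              },
              one_minus = 1 - w,
              stop("unknown distance convention '", distance, "'"))
  s <- numeric(tree$n_nodes)
  for (k in seq_along(d)) {
    s[tree$edges$i[k]] <- s[tree$edges$i[k]] + d[k]
    s[tree$edges$j[k]] <- s[tree$edges$j[k]] + d[k]
  }
  if (any(s <= 0))
    stop("a node has zero total neighbour distance; dissimilarity ",
         "undefined")
  s
}

#' Information-based dissimilarity between two spanning trees
#'
#' For each node `i`, let `S(i)` be the sum of edge distances from `i`
#' to its direct tree neighbours (distance `1/PLI` by default, or
#' `1 - PLI` behind the `distance` switch). The dissimilarity of tree n
#' given tree m is the average over nodes of `log10 |S_n(i) / S_m(i)|`.
#' It is zero for identical trees, antisymmetric under argument swap,
#' and (for the reciprocal convention) invariant to a common rescaling
#' of all PLI weights.
#'
#' @param tree_n,tree_m `spanning_tree`s over the same node set.
#' @param distance edge distance convention, `"reciprocal"` (default)
#'   or `"one_minus"`.
#' @return a single numeric dissimilarity score (may be negative).
#' @export
dissimilarity <- function(tree_n, tree_m,
                          distance = c("reciprocal", "one_minus")) {
  distance <- match.arg(distance)
  stopifnot(inherits(tree_n, "spanning_tree"),
            inherits(tree_m, "spanning_tree"))
  if (tree_n$n_nodes != tree_m$n_nodes)
    stop("trees have different node counts")
  sn <- neighbour_distance_sums(tree_n, distance)
  sm <- neighbour_distance_sums(tree_m, distance)
  mean(log10(abs(sn / sm)))
}

#' Dissimilarity of each trial tree against a reference tree
#'
#' @param trial_trees list of `spanning_tree`s (one per trial).
#' @param ref reference `spanning_tree`.
#' @param distance edge distance convention, see [dissimilarity()].
#' @return numeric vector of per-trial scores.
#' @export
condition_dissimilarity <- function(trial_trees, ref,
                                    distance = c("reciprocal",
                                                 "one_minus")) {
  distance <- match.arg(distance)
  vapply(trial_trees, dissimilarity, numeric(1), tree_m = ref,
         distance = distance)
}

#' Per-trial dissimilarity scores against per-cell reference trees
#'
#' For every (band, window) cell, the reference tree is the maximum
#' spanning tree of the trial-averaged adjacency of the reference
#' condition; every trial's tree (all conditions) is then scored
#' against it.
#'
#' @param stack a `pli_stack` from [connectivity_stack()].
#' @param msts the matching `mst_stack` (computed if omitted).
#' @param reference_condition label of the reference condition.
#' @param distance edge distance convention, see [dissimilarity()].
#' @return data.frame with `trial`, `condition`, `subject`, `band`,
#'   `window`, `score`.
#' @export
dissimilarity_table <- function(stack, msts = NULL,
                                reference_condition = "scrambled",
                                distance = c("reciprocal",
                                             "one_minus")) {
  distance <- match.arg(distance)
  stopifnot(inherits(stack, "pli_stack"))
  if (is.null(msts)) msts <- mst_stack(stack)
  ref_idx <- which(stack$meta$condition == reference_condition)
  if (length(ref_idx) == 0)
    stop("no trials with reference condition '", reference_condition,
         "'")
  d <- dim(stack$pli)
  out <- msts$index
  out$score <- NA_real_
  for (b in seq_along(stack$bands)) {
    for (w in seq_len(stack$n_windows)) {
      mean_adj <- apply(stack$pli[, , ref_idx, b, w, drop = FALSE],
                        c(1, 2), mean)
      ref <- max_spanning_tree(mean_adj, stack$channel_labels)
      sel <- which(out$band == stack$bands[b] & out$window == w)
      out$score[sel] <- condition_dissimilarity(msts$trees[sel], ref,
                                                distance)
    }
  }
  out
}
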