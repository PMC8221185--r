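#' Assemble the per-trial feature matrix from a manifest
#'
#' One row per trial of the supplied measure tables, one column per
#' manifest entry, in the manifest's deterministic (band, window,
#' measure, node) order.
#'
#' @param measures list with `global` and `nodal` data.frames from
#'   [mst_measure_table()].
#' @param manifest data.frame from [feature_manifest()].
#' @return an object of class `feature_matrix`: list with `x` (numeric
#'   matrix, trials x features), `y` (per-trial condition labels),
#'   `trial` (trial ids) and `manifest`.
#' @export
build_feature_matrix <- function(measures, manifest) {
  if (nrow(manifest) == 0) stop("empty feature manifest")
  global <- measures$global
  nodal <- measures$nodal
  trials <- sort(unique(global$trial))
  x <- matrix(NA_real_, length(trials), nrow(manifest))
  colnames(x) <- paste0(manifest$measure, "_", manifest$band, "_T",
                        manifest$window,
                        ifelse(is.na(manifest$node), "",
                               paste0("_", manifest$node)))
  for (k in seq_len(nrow(manifest))) {
    nodal_feat <- manifest$measure[k] %in% c("node_degree", "node_bc")
    src <- if (nodal_feat) nodal else global
    sel <- src$band == manifest$band[k] &
      src$window == manifest$window[k]
    if (nodal_feat) sel <- sel & src$node == manifest$node[k]
    sub <- src[sel, , drop = FALSE]
    pos <- match(trials, sub$trial)
    if (anyNA(pos)) {
      missing <- trials[which(is.na(pos))[1]]
      stop("trial ", missing, " has no (", manifest$band[k], ", T",
           manifest$window[k], ") computation for feature '",
           manifest$measure[k], "'")
    }
    x[, k] <- sub[[manifest$measure[k]]][pos]
  }
  y <- global$condition[match(trials, global$trial)]
  structure(list(x = x, y = y, trial = trials, manifest = manifest),
            class = "feature_matrix")
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into folds.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of an RBF-kernel SVM
#'
#' Five-fold stratified cross-validation, repeated `n_repeats` times.
#' Features are z-scored with means and standard deviations fitted on
#' the training folds only. Decision values are pooled across the folds
#' of one repetition for the ROC; accuracy, sensitivity, specificity and
#' AUC are averaged over repetitions. The first level of `positive`
#' defines sensitivity.
#'
#' @param features a `feature_matrix` from [build_feature_matrix()], or
#'   a plain numeric matrix (then `labels` is required).
#' @param labels per-trial class labels (two classes), only for matrix
#'   input.
#' @param n_folds number of folds (default 5).
#' @param n_repeats number of repetitions (default 5).
#' @param seed integer seed controlling every fold assignment.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; defaults to 1 / n_features on the
#'   z-scored features (the scale convention).
#' @param positive label treated as the positive class (default: first
#'   sorted level).
#' @return an object of class `classification_report`: list with mean
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, the pooled
#'   `roc_points` (data.frame `fpr`, `tpr`), a `per_repetition`
#'   data.frame, and the `seed`.
#' @export
crossval_svm <- function(features, labels = NULL, n_folds = 5,
                         n_repeats = 5, seed = 1, cost = 1,
                         gamma = NULL, positive = NULL) {
  if (inherits(features, "feature_matrix")) {
    x <- features$x
    y <- features$y
  } else {
    x <- as.matrix(features)
    y <- labels
  }
  if (is.null(y) || length(unique(y)) != 2)
    stop("need exactly two classes")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (is.null(positive)) positive <- classes[1]
  negative <- setdiff(classes, positive)
  if (min(table(y)) < n_folds)
    stop("need at least n_folds trials per class")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  set.seed(seed)
  reps <- vector("list", n_repeats)
  all_dec <- numeric(0)
  all_lab <- character(0)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds)
    dec <- numeric(length(y))
    pred <- character(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      mu <- colMeans(x[tr, , drop = FALSE])
      sdev <- apply(x[tr, , drop = FALSE], 2, sd)
      sdev[sdev == 0 | !is.finite(sdev)] <- 1
      xs_tr <- scale(x[tr, , drop = FALSE], mu, sdev)
      xs_te <- scale(x[!tr, , drop = FALSE], mu, sdev)
      fit <- e1071::svm(xs_tr, factor(y[tr], levels = classes),
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      pr <- predict(fit, xs_te, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient decision values so larger means the positive class
      dv_name <- colnames(attr(pr, "decision.values"))[1]
      first_lab <- strsplit(dv_name, "/")[[1]][1]
      if (first_lab != positive) dv <- -dv
      dec[!tr] <- dv
      pred[!tr] <- as.character(pr)
    }
    roc <- pROC::roc(response = y, predictor = dec,
                     levels = c(negative, positive), direction = "<",
                     quiet = TRUE)
    reps[[r]] <- data.frame(
      repetition = r,
      accuracy = mean(pred == y),
      sensitivity = mean(pred[y == positive] == positive),
      specificity = mean(pred[y == negative] == negative),
      auc = as.numeric(pROC::auc(roc)))
    all_dec <- c(all_dec, dec)
    all_lab <- c(all_lab, y)
  }
  per_rep <- do.call(rbind, reps)
  roc_all <- pROC::roc(response = all_lab, predictor = all_dec,
                       levels = c(negative, positive), direction = "<",
                       quiet = TRUE)
  roc_points <- data.frame(fpr = rev(1 - roc_all$specificities),
                           tpr = rev(roc_all$sensitivities))
  structure(
    list(accuracy = mean(per_rep$accuracy),
         sensitivity = mean(per_rep$sensitivity),
         specificity = mean(per_rep$specificity),
         auc = mean(per_rep$auc),
         roc_points = roc_points, per_repetition = per_rep,
         decision_values = all_dec, labels = all_lab,
         positive = positive, seed = seed),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<classification_report> accuracy %.4f | sensitivity %.4f | ",
    "specificity %.4f | AUC %.4f\n"),
    x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  positive class '%s', %d repetitions, seed %d\n",
              x$positive, nrow(x$per_repetition), x$seed))
  invisible(x)
}

#' Time-segment baseline features
#'
#' The comparison baseline to the MST features: raw amplitude samples
#' from a named channel subset (occipito-temporal by default) over a
#' post-stimulus span, concatenated per trial, optionally decimated.
#'
#' @param epochs an [epoch_set()].
#' @param channels channel labels to include; defaults to
#'   [occipito_temporal_channels()] intersected with the available
#'   labels.
#' @param span `c(start, end)` in ms relative to stimulus onset
#'   (`start <= t < end`).
#' @param decimate keep every `decimate`-th sample (default 1, no
#'   decimation).
#' @return a `feature_matrix` whose manifest describes the
#'   channel/sample layout.
#' @export
timesegment_features <- function(epochs,
                                 channels = NULL,
                                 span = c(0, 500), decimate = 1) {
  if (is.null(channels)) {
    channels <- intersect(occipito_temporal_channels(),
                          epochs$channel_labels)
    if (length(channels) == 0) channels <- epochs$channel_labels
  }
  missing <- setdiff(channels, epochs$channel_labels)
  if (length(missing) > 0)
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  t_ms <- epoch_times(epochs)
  sel <- which(t_ms >= span[1] & t_ms < span[2])
  sel <- sel[seq(1, length(sel), by = decimate)]
  ch_idx <- match(channels, epochs$channel_labels)
  nt <- n_trials(epochs)
  x <- matrix(NA_real_, nt, length(channels) * length(sel))
  for (i in seq_len(nt)) {
    x[i, ] <- as.vector(t(matrix(epochs$data[i, ch_idx, sel],
                                 nrow = length(ch_idx))))
  }
  colnames(x) <- as.vector(vapply(channels, function(ch)
    paste0("ts_", ch, "_", seq_along(sel)), character(length(sel))))
  manifest <- data.frame(measure = "time_segment",
                         band = NA_character_, window = NA_integer_,
                         node = rep(channels, each = length(sel)))
  structure(list(x = x, y = epochs$condition, trial = seq_len(nt),
                 manifest = manifest),
            class = "feature_matrix")
}
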