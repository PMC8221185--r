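#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Either a
#' [synth_config()] (signals are generated) or the path of an epoch
#' archive (signals are loaded) must be supplied.
#'
#' @param synth a [synth_config()], or `NULL` when loading from disk.
#' @param archive_dir epoch-archive directory, or `NULL` when
#'   generating.
#' @param band_plan named list of band edges in Hz.
#' @param n_windows,window_ms analysis-window plan.
#' @param baseline_span baseline span in ms.
#' @param split_fraction fraction of trials in the analysis subset.
#' @param split_seed seed of the stratified split.
#' @param reference_condition label of the reference condition used for
#'   the reference trees.
#' @param contrast the two contrast condition labels.
#' @param alpha significance level for gate and selection.
#' @param distance tree edge-distance convention (`"reciprocal"` or
#'   `"one_minus"`).
#' @param svm_cost,svm_gamma,svm_folds,svm_repeats,svm_seed SVM
#'   cross-validation settings (`svm_gamma = NULL` uses the scale
#'   convention 1 / n_features).
#' @param stages named logical list toggling `dissimilarity`, `stats`
#'   and `classify`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, archive_dir = NULL,
                            band_plan = default_band_plan(),
                            n_windows = 5, window_ms = 100,
                            baseline_span = c(-200, 0),
                            split_fraction = 0.7, split_seed = 1,
                            reference_condition = "scrambled",
                            contrast = c("face", "ketch"),
                            alpha = 0.05,
                            distance = c("reciprocal", "one_minus"),
                            svm_cost = 1, svm_gamma = NULL,
                            svm_folds = 5, svm_repeats = 5,
                            svm_seed = 1,
                            stages = list(dissimilarity = TRUE,
                                          stats = TRUE,
                                          classify = TRUE)) {
  distance <- match.arg(distance)
  if (is.null(synth) && is.null(archive_dir))
    stop("supply either `synth` or `archive_dir`")
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop("`contrast` must be two distinct condition labels")
  if (reference_condition %in% contrast)
    stop("`reference_condition` must differ from the contrast labels")
  structure(
    list(synth = synth, archive_dir = archive_dir,
         band_plan = band_plan, n_windows = n_windows,
         window_ms = window_ms, baseline_span = baseline_span,
         split_fraction = split_fraction, split_seed = split_seed,
         reference_condition = reference_condition,
         contrast = contrast, alpha = alpha, distance = distance,
         svm_cost = svm_cost, svm_gamma = svm_gamma,
         svm_folds = svm_folds, svm_repeats = svm_repeats,
         svm_seed = svm_seed, stages = stages),
    class = "pipeline_config")
}

# Serializable view of a config (drops function-free recursion issues,
# renders coupling graphs as edge tables).
config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synth)) {
    sc <- unclass(out$synth)
    sc$coupling_plan <- lapply(sc$coupling_plan, function(bands)
      lapply(bands, function(wins)
        lapply(wins, function(g) unclass(g)$edges)))
    out$synth <- sc
  }
  out
}

#' Run the end-to-end dynamic-network pipeline
#'
#' Executes: generate-or-load epochs, preprocessing (common average
#' reference, per-band zero-phase filtering, baseline correction),
#' per-trial PLI networks, maximum spanning trees and their measures,
#' reference-tree dissimilarity, the gated Wilcoxon/FDR selection on the
#' analysis subset, and cross-validated SVM classification on the
#' held-out subset. Writes flat CSV/JSON artifacts per stage plus a
#' machine-readable run manifest; an unforced re-run with identical
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the stage artifacts.
#' @param force recompute and overwrite existing stage outputs.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory stage results:
#'   `epochs`, `split`, `stack`, `measures`, `dissimilarity`, `gate`,
#'   `selection`, `manifest`, `report`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage_names <- c("epochs", "preprocess", "connectivity", "mst",
                   "dissimilarity", "stats", "classify")

  # 1. epochs -------------------------------------------------------
  say("stage 1/7: epochs")
  epochs <- if (!is.null(config$synth)) generate_dataset(config$synth)
            else read_epoch_archive(config$archive_dir)
  f_trials <- file.path(out_dir, "01_trials.csv")
  if (force || !file.exists(f_trials))
    write.csv(data.frame(trial = seq_len(n_trials(epochs)),
                         condition = epochs$condition,
                         subject = epochs$subject),
              f_trials, row.names = FALSE)

  # 2. preprocess ---------------------------------------------------
  say("stage 2/7: preprocess")
  epochs <- common_average_reference(epochs)
  epochs <- baseline_correct(epochs, config$baseline_span)
  split <- split_dataset(epochs, config$split_fraction,
                         config$split_seed)
  f_split <- file.path(out_dir, "02_split.csv")
  if (force || !file.exists(f_split))
    write.csv(data.frame(
      subset = c(rep("analysis", n_trials(split$analysis)),
                 rep("holdout", n_trials(split$holdout))),
      condition = c(split$analysis$condition,
                    split$holdout$condition)),
      f_split, row.names = FALSE)

  # 3. connectivity (band filtering happens inside, on full epochs) --
  say("stage 3/7: connectivity")
  stack_a <- connectivity_stack(split$analysis, config$band_plan,
                                config$n_windows, config$window_ms)
  f_conn <- file.path(out_dir, "03_mean_pli.csv")
  if (force || !file.exists(f_conn)) {
    rows <- list()
    d <- dim(stack_a$pli)
    off <- upper.tri(matrix(0, d[1], d[1]))
    for (b in seq_along(stack_a$bands))
      for (w in seq_len(stack_a$n_windows))
        for (cond in unique(stack_a$meta$condition)) {
          sel <- which(stack_a$meta$condition == cond)
          mean_adj <- rowMeans(stack_a$pli[, , sel, b, w,
                                           drop = FALSE], dims = 2)
          rows[[length(rows) + 1]] <- data.frame(
            band = stack_a$bands[b], window = w, condition = cond,
            mean_pli = mean(mean_adj[off]))
        }
    write.csv(do.call(rbind, rows), f_conn, row.names = FALSE)
  }

  # 4. spanning trees and measures ----------------------------------
  say("stage 4/7: spanning trees")
  msts_a <- mst_stack(stack_a)
  measures_a <- mst_measure_table(msts_a)
  f_glob <- file.path(out_dir, "04_mst_measures.csv")
  if (force || !file.exists(f_glob))
    write.csv(measures_a$global, f_glob, row.names = FALSE)
  f_nodal <- file.path(out_dir, "04_mst_nodal.csv")
  if (force || !file.exists(f_nodal))
    write.csv(measures_a$nodal, f_nodal, row.names = FALSE)

  diss <- gate <- selection <- manifest <- report <- NULL

  # 5. dissimilarity -------------------------------------------------
  if (isTRUE(config$stages$dissimilarity)) {
    say("stage 5/7: dissimilarity")
    diss <- dissimilarity_table(stack_a, msts_a,
                                config$reference_condition,
                                config$distance)
    f_diss <- file.path(out_dir, "05_dissimilarity.csv")
    if (force || !file.exists(f_diss))
      write.csv(diss, f_diss, row.names = FALSE)
  }

  # 6. gated statistics ----------------------------------------------
  if (isTRUE(config$stages$stats) && !is.null(diss)) {
    say("stage 6/7: statistics")
    gate <- gate_by_dissimilarity(diss, config$contrast, config$alpha)
    f_gate <- file.path(out_dir, "06_gate.csv")
    if (force || !file.exists(f_gate))
      write.csv(gate, f_gate, row.names = FALSE)
    selection <- select_features(measures_a, gate, config$contrast,
                                 config$alpha)
    f_sel <- file.path(out_dir, "06_selection.csv")
    if (force || !file.exists(f_sel))
      write.csv(as.data.frame(selection), f_sel, row.names = FALSE)
    manifest <- feature_manifest(selection)
    f_man <- file.path(out_dir, "06_feature_manifest.json")
    if (force || !file.exists(f_man))
      jsonlite::write_json(manifest, f_man, auto_unbox = TRUE,
                           digits = NA)
  }

  # 7. classification on the held-out subset -------------------------
  if (isTRUE(config$stages$classify) && !is.null(manifest) &&
      nrow(manifest) > 0) {
    say("stage 7/7: classification")
    keep <- split$holdout$condition %in% config$contrast
    holdout <- subset_epochs(split$holdout, keep)
    stack_h <- connectivity_stack(holdout, config$band_plan,
                                  config$n_windows, config$window_ms)
    measures_h <- mst_measure_table(mst_stack(stack_h))
    feats <- build_feature_matrix(measures_h, manifest)
    report <- crossval_svm(feats, n_folds = config$svm_folds,
                           n_repeats = config$svm_repeats,
                           seed = config$svm_seed,
                           cost = config$svm_cost,
                           gamma = config$svm_gamma,
                           positive = config$contrast[1])
    f_rep <- file.path(out_dir, "07_classification.json")
    if (force || !file.exists(f_rep))
      jsonlite::write_json(
        list(accuracy = report$accuracy,
             sensitivity = report$sensitivity,
             specificity = report$specificity, auc = report$auc,
             positive = report$positive, seed = report$seed,
             per_repetition = report$per_repetition),
        f_rep, auto_unbox = TRUE, digits = NA)
    f_roc <- file.path(out_dir, "07_roc.csv")
    if (force || !file.exists(f_roc))
      write.csv(report$roc_points, f_roc, row.names = FALSE)
  }

  f_manifest <- file.path(out_dir, "run_manifest.json")
  if (force || !file.exists(f_manifest))
    jsonlite::write_json(
      list(package = "mstnet",
           version = as.character(utils::packageVersion("mstnet")),
           stages = stage_names,
           config = config_as_list(config)),
      f_manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(epochs = epochs, split = split, stack = stack_a,
                 measures = measures_a, dissimilarity = diss,
                 gate = gate, selection = selection,
                 manifest = manifest, report = report))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()] and
#' [synth_config()]; planted couplings are described as templated
#' entries with `condition`, `band`, `window`, `type`
#' (`"star"`/`"chain"`), and optional `hub`, `lag`, `weight`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  band_plan <- if (!is.null(y$band_plan))
    lapply(y$band_plan, unlist) else default_band_plan()
  synth <- NULL
  if (!is.null(y$synth)) {
    s <- y$synth
    plan <- list()
    for (cp in s$coupling_plan) {
      g <- switch(cp$type,
                  star = star_coupling(s$n_channels,
                                       hub = cp$hub %||% 1,
                                       lag = cp$lag %||% (pi / 2),
                                       weight = cp$weight %||% 1),
                  chain = chain_coupling(s$n_channels,
                                         lag = cp$lag %||% (pi / 2),
                                         weight = cp$weight %||% 1),
                  stop("unknown coupling type '", cp$type, "'"))
      plan[[cp$condition]][[cp$band]][[as.character(cp$window)]] <- g
    }
    synth <- synth_config(
      n_subjects = s$n_subjects %||% 1,
      trials_per_condition = s$trials_per_condition %||% 10,
      n_channels = s$n_channels %||% 63,
      sample_rate = s$sample_rate %||% 1000,
      epoch_span = unlist(s$epoch_span %||% c(-200, 800)),
      band_plan = band_plan,
      conditions = unlist(s$conditions %||%
                            c("face", "ketch", "scrambled")),
      coupling_plan = plan,
      coupling_strength = s$coupling_strength %||% 0.9,
      noise_sd = s$noise_sd %||% 1,
      seed = s$seed %||% 1)
  }
  pipeline_config(
    synth = synth, archive_dir = y$archive_dir,
    band_plan = band_plan,
    n_windows = y$n_windows %||% 5,
    window_ms = y$window_ms %||% 100,
    split_fraction = y$split_fraction %||% 0.7,
    split_seed = y$split_seed %||% 1,
    reference_condition = y$reference_condition %||% "scrambled",
    contrast = unlist(y$contrast %||% c("face", "ketch")),
    alpha = y$alpha %||% 0.05,
    distance = y$distance %||% "reciprocal",
    svm_cost = y$svm_cost %||% 1,
    svm_gamma = y$svm_gamma,
    svm_folds = y$svm_folds %||% 5,
    svm_repeats = y$svm_repeats %||% 5,
    svm_seed = y$svm_seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
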