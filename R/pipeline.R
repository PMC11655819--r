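#' Configuration of a full desk-scale experiment
#'
#' Bundles everything a reproducible end-to-end run needs: the simulation (or
#' an epochs container path), the decomposition windows, the reference
#' electrode, the classifier choice and the analysis modes. A run is fully
#' determined by this object plus its seed.
#'
#' @param sim a `sim_config`, or `NULL` when `input` is given.
#' @param input path to an epochs container (see [read_epoch_set()]).
#' @param windows a `ride_windows`.
#' @param reference_electrode synchronization electrode.
#' @param analysis_window half-open crop window in ms.
#' @param classifier "logistic" (default, fast) or "eegnet".
#' @param classifier_cfg optional `classifier_config` for the network.
#' @param modes subset of `c("overall", "temporal", "generalization",
#'   "saliency")`.
#' @param k cross-validation folds.
#' @param window_ms,stride_ms sliding-window geometry for the temporal modes.
#' @param stages pipeline stages to materialize and assess.
#' @param seed global seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input = NULL,
                       windows = ride_windows(),
                       reference_electrode = "Pz",
                       analysis_window = c(100, 1100),
                       classifier = c("logistic", "eegnet"),
                       classifier_cfg = NULL,
                       modes = "overall", k = 10,
                       window_ms = 120, stride_ms = 40,
                       stages = c("original", "step1", "step2", "step3",
                                  "step4"),
                       seed = 1L) {
  classifier <- match.arg(classifier)
  modes <- match.arg(modes, c("overall", "temporal", "generalization",
                              "saliency"), several.ok = TRUE)
  structure(list(sim = sim, input = input, windows = windows,
                 reference_electrode = reference_electrode,
                 analysis_window = analysis_window, classifier = classifier,
                 classifier_cfg = classifier_cfg, modes = modes, k = k,
                 window_ms = window_ms, stride_ms = stride_ms,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full experiment: simulate/load, decompose, correct, assess
#'
#' Executes the pipeline end to end: obtain epochs (simulator or container),
#' run the stepwise latency correction, then assess every materialized stage
#' with the requested modes — overall cross-validated accuracy, sliding-window
#' temporal decoding, temporal generalization, and saliency maps. Deterministic
#' given the config.
#'
#' @param cfg a `run_config`.
#' @param verbose log stage progress.
#' @return a report bundle (class `latstep_report`): `stages` (the
#'   `correction_result`s), `overall` (tidy accuracy table), `temporal`,
#'   `generalization`, `saliency` (per-stage lists, when requested),
#'   `provenance` (per-trial shift log) and `truth` (when simulated).
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3L]
  if (!is.null(cfg$input)) {
    epochs <- read_epoch_set(cfg$input)
    truth <- NULL
  } else {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    gen <- simulate_epochs(sim)
    epochs <- gen$epochs
    truth <- gen$truth
    say("simulated %d trials (%.1f s)", dim(epochs)[1L], proc.time()[3L] - t0)
  }
  stages <- run_stepwise_pipeline(epochs, cfg$windows,
                                  reference_electrode = cfg$reference_electrode,
                                  analysis_window = cfg$analysis_window,
                                  stages = cfg$stages)
  say("correction pipeline done (%.1f s)", proc.time()[3L] - t0)
  report <- list(config = cfg, stages = stages,
                 provenance = attr(stages, "provenance"), truth = truth)
  if ("overall" %in% cfg$modes) {
    rows <- lapply(names(stages), function(nm) {
      res <- crossval_accuracy(stages[[nm]]$epochs, k = cfg$k,
                               classifier = cfg$classifier,
                               cfg = cfg$classifier_cfg, seed = cfg$seed,
                               stage = stages[[nm]]$stage)
      data.frame(stage = stages[[nm]]$stage, fold = seq_len(res$k),
                 accuracy = res$accuracies, mean = res$mean, sd = res$sd,
                 p_vs_chance = res$p)
    })
    report$overall <- do.call(rbind, rows)
    say("overall decoding done (%.1f s)", proc.time()[3L] - t0)
  }
  if ("temporal" %in% cfg$modes) {
    report$temporal <- do.call(rbind, lapply(names(stages), function(nm)
      temporal_decoding(stages[[nm]]$epochs, window_ms = cfg$window_ms,
                        stride_ms = cfg$stride_ms, k = cfg$k,
                        classifier = cfg$classifier, cfg = cfg$classifier_cfg,
                        seed = cfg$seed, stage = stages[[nm]]$stage)))
    say("temporal decoding done (%.1f s)", proc.time()[3L] - t0)
  }
  if ("generalization" %in% cfg$modes) {
    report$generalization <- lapply(stages, function(st)
      temporal_generalization(st$epochs, window_ms = cfg$window_ms,
                              stride_ms = cfg$stride_ms, k = cfg$k,
                              classifier = cfg$classifier,
                              cfg = cfg$classifier_cfg, seed = cfg$seed,
                              stage = st$stage))
    say("temporal generalization done (%.1f s)", proc.time()[3L] - t0)
  }
  if ("saliency" %in% cfg$modes) {
    report$saliency <- lapply(stages, function(st) {
      folds <- make_folds(st$epochs$labels, cfg$k, cfg$seed)
      tr <- folds != 1L
      model <- fit_fold(st$epochs$data[tr, , , drop = FALSE],
                        st$epochs$labels[tr], cfg$classifier,
                        cfg$classifier_cfg, fold_seed = cfg$seed + 1L,
                        lambda = 1)
      condition_saliency_map(model, subset_trials(st$epochs, which(!tr)),
                             stage = st$stage)
    })
    say("saliency maps done (%.1f s)", proc.time()[3L] - t0)
  }
  class(report) <- "latstep_report"
  report
}

#' @export
print.latstep_report <- function(x, ...) {
  cat("<latstep_report> stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$overall)) {
    agg <- unique(x$overall[, c("stage", "mean", "sd")])
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-9s accuracy %.3f +/- %.3f\n",
                  agg$stage[i], agg$mean[i], agg$sd[i]))
  }
  invisible(x)
}

#' Write the tidy tables of a report bundle to a directory
#'
#' @param report a `latstep_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "latstep_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, nm) utils::write.table(
    df, file.path(dir, nm), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$provenance, "provenance.tsv")
  if (!is.null(report$overall)) wt(report$overall, "overall_accuracy.tsv")
  if (!is.null(report$temporal)) wt(report$temporal, "temporal_decoding.tsv")
  if (!is.null(report$generalization)) {
    for (nm in names(report$generalization)) {
      gm <- report$generalization[[nm]]
      m <- gm$accuracy
      dimnames(m) <- list(train_end_ms = gm$end_ms, gen_end_ms = gm$end_ms)
      wt(as.data.frame(as.table(m), responseName = "accuracy"),
         paste0("generalization_", nm, ".tsv"))
    }
  }
  if (!is.null(report$saliency)) {
    for (nm in names(report$saliency)) {
      sm <- report$saliency[[nm]]
      df <- data.frame(channel = rep(sm$channel_names, ncol(sm$importance)),
                       time_ms = rep(sm$times, each = nrow(sm$importance)),
                       importance = as.numeric(sm$importance))
      wt(df, paste0("saliency_", nm, ".tsv"))
    }
  }
  invisible(dir)
}
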