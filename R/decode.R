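#' Ridge-penalized logistic baseline classifier
#'
#' Flattens each trial (channels x samples) into one feature vector and fits a
#' binomial ridge model (glmnet, alpha = 0) at a single fixed penalty —
#' deterministic, fast, and a linear reference against which the convolutional
#' network's behavior can be compared.
#'
#' @param epochs an `epoch_set`, or an N x C x T array plus `labels`.
#' @param labels required when `epochs` is a bare array.
#' @param lambda ridge penalty (default 1).
#' @return an object of class `logistic_model` with the coefficient map
#'   reshaped back to channels x samples.
#' @export
train_logistic <- function(epochs, labels = NULL, lambda = 1) {
  if (inherits(epochs, "epoch_set")) {
    X <- epochs$data; labels <- epochs$labels
  } else X <- epochs
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly two classes")
  d <- dim(X)
  Xf <- matrix(X, nrow = d[1L])
  y <- as.numeric(labels == classes[2L])
  fit <- glmnet::glmnet(Xf, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  structure(list(coef = matrix(beta, d[2L], d[3L]),
                 intercept = as.numeric(fit$a0),
                 classes = classes, dims = d[2:3]),
            class = "logistic_model")
}

#' @export
predict.logistic_model <- function(object, newdata,
                                   type = c("prob", "logit", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "epoch_set")) newdata$data else newdata
  if (length(dim(X)) == 2L) X <- array(X, dim = c(1L, dim(X)))
  logits <- as.numeric(matrix(X, nrow = dim(X)[1L]) %*% as.numeric(object$coef) +
                         object$intercept)
  switch(type,
         logit = logits,
         prob = stats::plogis(logits),
         class = object$classes[1L + (stats::plogis(logits) > 0.5)])
}

#' Stratified k-fold assignment
#'
#' Trials are pooled over subjects and stratified by condition: within each
#' class, trials are shuffled (deterministically under `seed`) and dealt
#' round-robin into `k` folds, so every fold contains both classes whenever
#' each class has at least `k` trials.
#'
#' @param labels per-trial class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param group optional grouping factor (e.g. subject); when given, whole
#'   groups are assigned to folds instead of single trials.
#' @return integer fold id per trial.
#' @export
make_folds <- function(labels, k = 10, seed = 1, group = NULL) {
  n <- length(labels)
  fold <- integer(n)
  with_local_seed(seed, {
    if (is.null(group)) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stop("class '", cl, "' has fewer trials (", length(idx),
               ") than folds (", k, ")")
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      groups <- unique(group)
      if (length(groups) < k) stop("fewer groups than folds")
      gf <- sample(rep_len(seq_len(k), length(groups)))
      fold <- gf[match(group, groups)]
    }
  })
  fold
}

fit_fold <- function(X, labels, classifier, cfg, fold_seed, lambda) {
  if (classifier == "logistic") {
    train_logistic(X, labels = labels, lambda = lambda)
  } else {
    if (is.null(cfg))
      cfg <- classifier_config(channels = dim(X)[2L], samples = dim(X)[3L])
    cfg$seed <- as.integer(fold_seed)
    train_eegnet(X, cfg = cfg, labels = labels)
  }
}

accuracy_of <- function(model, X, labels) {
  mean(predict(model, X, type = "class") == labels)
}

#' Cross-validated decoding accuracy
#'
#' Trains the chosen classifier on a stratified trial-level k-fold split
#' pooled across subjects and conditions (90%/10% at k = 10) and reports the
#' per-fold test accuracy, its mean and SD, and a two-sided one-sample t-test
#' against the binary chance level 0.5.
#'
#' @param epochs an `epoch_set` with two conditions.
#' @param k number of folds (default 10).
#' @param classifier "logistic" (default) or "eegnet".
#' @param cfg optional `classifier_config` for the network.
#' @param seed seed for fold assignment and per-fold network training.
#' @param lambda ridge penalty of the logistic baseline.
#' @param folds optional precomputed fold vector (overrides `k`/`seed`).
#' @param group_by_subject assign whole subjects to folds instead of trials.
#' @param stage optional stage label carried into the result.
#' @return an object of class `decoding_result`.
#' @export
crossval_accuracy <- function(epochs, k = 10, classifier = c("logistic",
                                                             "eegnet"),
                              cfg = NULL, seed = 1, lambda = 1, folds = NULL,
                              group_by_subject = FALSE, stage = NA_character_) {
  stopifnot(inherits(epochs, "epoch_set"))
  classifier <- match.arg(classifier)
  labels <- epochs$labels
  if (length(unique(labels)) != 2L) stop("need exactly two conditions")
  if (is.null(folds))
    folds <- make_folds(labels, k, seed,
                        group = if (group_by_subject) epochs$subjects)
  k <- max(folds)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[!tr])) < 2L)
      warning("fold ", f, " is missing a class in its test set")
    model <- fit_fold(epochs$data[tr, , , drop = FALSE], labels[tr],
                      classifier, cfg, fold_seed = seed + f, lambda = lambda)
    acc[f] <- accuracy_of(model, epochs$data[!tr, , , drop = FALSE],
                          labels[!tr])
  }
  tt <- if (stats::sd(acc) > 0)
    stats::t.test(acc, mu = 0.5) else list(statistic = NA_real_,
                                           p.value = NA_real_)
  structure(list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 t = unname(tt$statistic), p = tt$p.value, k = k,
                 classifier = classifier, stage = stage,
                 window = range(epochs$times), folds = folds, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result>%s %s, %d-fold CV: %.3f +/- %.3f (t=%.2f, p=%.2g)\n",
              if (is.na(x$stage)) "" else paste0(" [", x$stage, "]"),
              x$classifier, x$k, x$mean, x$sd,
              ifelse(is.na(x$t), NA, x$t), x$p))
  invisible(x)
}

sliding_windows <- function(times, srate, window_ms, stride_ms) {
  step <- 1000 / srate
  wlen <- round_half_away(window_ms / step)
  stride_samp <- stride_ms / step
  if (abs(stride_samp - round(stride_samp)) > 1e-9) {
    stride_samp <- max(1, round(stride_samp))
    warning("stride snapped to ", stride_samp * step, " ms (sample grid)")
  }
  stride_samp <- as.integer(round(stride_samp))
  n <- length(times)
  if (n < wlen) stop("epoch shorter than the sliding window")
  starts <- seq(1L, n - wlen + 1L, by = stride_samp)
  list(starts = starts, wlen = wlen, stride = stride_samp)
}

#' Sliding-window temporal decoding
#'
#' Cross-validated accuracy inside a short window slid across the epoch
#' (defaults: 120 ms windows moved 4 ms at a time). All windows share the same
#' fold assignment so curves are comparable point by point. Each point is
#' indexed by the endpoint of its segment.
#'
#' @inheritParams crossval_accuracy
#' @param window_ms window length in ms (default 120).
#' @param stride_ms window step in ms (default 4; snapped to the sample grid
#'   with a warning if needed).
#' @return data.frame with `start_ms`, `end_ms`, `mean_accuracy`, `sd`, `p`;
#'   the per-fold accuracy matrix (windows x folds) is attached as attribute
#'   `"fold_accuracies"`.
#' @export
temporal_decoding <- function(epochs, window_ms = 120, stride_ms = 4,
                              k = 10, classifier = c("logistic", "eegnet"),
                              cfg = NULL, seed = 1, lambda = 1,
                              stage = NA_character_) {
  stopifnot(inherits(epochs, "epoch_set"))
  classifier <- match.arg(classifier)
  sw <- sliding_windows(epochs$times, epochs$srate, window_ms, stride_ms)
  folds <- make_folds(epochs$labels, k, seed)
  step <- 1000 / epochs$srate
  out <- vector("list", length(sw$starts))
  fold_acc <- matrix(NA_real_, length(sw$starts), max(folds))
  for (i in seq_along(sw$starts)) {
    s0 <- sw$starts[i]
    win <- crop_epochs(epochs, epochs$times[s0],
                       epochs$times[s0 + sw$wlen - 1L] + step / 2)
    res <- crossval_accuracy(win, classifier = classifier, cfg = cfg,
                             seed = seed, lambda = lambda, folds = folds,
                             stage = stage)
    fold_acc[i, ] <- res$accuracies
    out[[i]] <- data.frame(start_ms = epochs$times[s0],
                           end_ms = epochs$times[s0 + sw$wlen - 1L] + step,
                           mean_accuracy = res$mean, sd = res$sd, p = res$p)
  }
  df <- do.call(rbind, out)
  df$stage <- stage
  attr(df, "fold_accuracies") <- fold_acc
  attr(df, "folds") <- folds
  df
}

#' Temporal generalization matrix
#'
#' For every training window, the classifier fitted on each training fold is
#' evaluated on the corresponding held-out trials cropped to every
#' generalization window; accuracies are averaged over folds. The diagonal
#' reproduces the temporal-decoding curve computed with the same folds and
#' seeds. Below-chance off-diagonal cells diagnose time-shifted,
#' pattern-reversed structure between conditions.
#'
#' @inheritParams temporal_decoding
#' @return an object of class `generalization_matrix`: `accuracy` (train
#'   windows x generalization windows), `end_ms` window endpoints, `folds`,
#'   and the per-fold array in `fold_accuracy`.
#' @export
temporal_generalization <- function(epochs, window_ms = 120, stride_ms = 4,
                                    k = 10, classifier = c("logistic",
                                                           "eegnet"),
                                    cfg = NULL, seed = 1, lambda = 1,
                                    stage = NA_character_) {
  stopifnot(inherits(epochs, "epoch_set"))
  classifier <- match.arg(classifier)
  sw <- sliding_windows(epochs$times, epochs$srate, window_ms, stride_ms)
  folds <- make_folds(epochs$labels, k, seed)
  nw <- length(sw$starts)
  nf <- max(folds)
  labels <- epochs$labels
  segs <- lapply(sw$starts, function(s0)
    epochs$data[, , s0:(s0 + sw$wlen - 1L), drop = FALSE])
  acc <- array(NA_real_, dim = c(nw, nw, nf))
  for (f in seq_len(nf)) {
    tr <- folds != f
    for (i in seq_len(nw)) {
      model <- fit_fold(segs[[i]][tr, , , drop = FALSE], labels[tr],
                        classifier, cfg, fold_seed = seed + f,
                        lambda = lambda)
      for (j in seq_len(nw))
        acc[i, j, f] <- accuracy_of(model, segs[[j]][!tr, , , drop = FALSE],
                                    labels[!tr])
    }
  }
  step <- 1000 / epochs$srate
  end_ms <- epochs$times[sw$starts + sw$wlen - 1L] + step
  structure(list(accuracy = apply(acc, c(1L, 2L), mean),
                 fold_accuracy = acc, end_ms = end_ms,
                 window_ms = window_ms, stride_ms = stride_ms,
                 folds = folds, classifier = classifier, stage = stage),
            class = "generalization_matrix")
}

#' @export
print.generalization_matrix <- function(x, ...) {
  cat(sprintf("<generalization_matrix>%s %d x %d windows (%g ms / %g ms), %s\n",
              if (is.na(x$stage)) "" else paste0(" [", x$stage, "]"),
              nrow(x$accuracy), ncol(x$accuracy), x$window_ms, x$stride_ms,
              x$classifier))
  cat(sprintf("  accuracy range [%.3f, %.3f], diagonal mean %.3f\n",
              min(x$accuracy), max(x$accuracy), mean(diag(x$accuracy))))
  invisible(x)
}

#' Two-sided binomial chance band for a single accuracy estimate
#'
#' The 95% acceptance band for an accuracy computed from `n` test trials under
#' the null of chance-level (0.5) performance.
#'
#' @param n number of test trials.
#' @param level confidence level (default 0.95).
#' @return length-2 numeric `[lower, upper]` on the accuracy scale.
#' @export
chance_band <- function(n, level = 0.95) {
  a <- (1 - level) / 2
  c(stats::qbinom(a, n, 0.5), stats::qbinom(1 - a, n, 0.5)) / n
}
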