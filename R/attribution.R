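#' Signed per-feature attribution of one trial
#'
#' Computes channels x samples contribution scores toward the classifier's
#' logit. `"deeplift_rescale"` propagates the activation difference between the
#' trial and a reference input through every layer, using exact linear rules
#' for convolutions, batch norm (inference mode), pooling and the dense head,
#' and the rescale rule (delta-output over delta-input) at the ELU
#' nonlinearities; the attributions then satisfy the completeness identity
#' sum(attribution) = logit(trial) - logit(baseline). `"gradient_x_input"` is
#' the plain saliency fallback, gradient of the logit times the input. For a
#' linear model with a zero baseline the two coincide exactly.
#'
#' @param model a trained `eegnet_model` or `logistic_model`.
#' @param trial channels x samples matrix.
#' @param method "deeplift_rescale" (default) or "gradient_x_input".
#' @param baseline reference input; default an all-zero trial (the
#'   average-referenced resting value).
#' @return channels x samples matrix of signed scores; positive = evidence for
#'   the model's positive (second) class.
#' @export
attribute_trial <- function(model, trial,
                            method = c("deeplift_rescale", "gradient_x_input"),
                            baseline = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(trial))
  if (is.null(baseline)) baseline <- matrix(0, nrow(trial), ncol(trial))
  stopifnot(identical(dim(baseline), dim(trial)))
  if (inherits(model, "logistic_model")) {
    out <- switch(method,
                  gradient_x_input = model$coef * trial,
                  deeplift_rescale = model$coef * (trial - baseline))
    return(out)
  }
  if (!inherits(model, "eegnet_model"))
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  X <- array(trial, dim = c(1L, dim(trial)))
  fx <- eegnet_forward(model, X, training = FALSE, keep_cache = TRUE)
  if (method == "gradient_x_input") {
    bw <- eegnet_backward(model, fx$cache, dlogits = 1)
    return(bw$dX[1L, , , drop = TRUE] * trial)
  }
  B <- array(baseline, dim = c(1L, dim(baseline)))
  fb <- eegnet_forward(model, B, training = FALSE, keep_cache = TRUE)
  rescale <- function(px, pb) {
    d <- px - pb
    m <- elu_grad(px)
    big <- abs(d) > 1e-7
    m[big] <- (elu(px[big]) - elu(pb[big])) / d[big]
    m
  }
  elu_mult <- list(
    e2 = lapply(seq_len(model$F), function(f)
      rescale(fx$cache$pre_elu2[[f]], fb$cache$pre_elu2[[f]])),
    e3 = lapply(seq_len(model$F), function(f)
      rescale(fx$cache$pre_elu3[[f]], fb$cache$pre_elu3[[f]])))
  bw <- eegnet_backward(model, fx$cache, dlogits = 1, elu_mult = elu_mult)
  bw$dX[1L, , , drop = TRUE] * (trial - baseline)
}

#' Condition-wise saliency map over confidently classified trials
#'
#' Selects the trials the model classifies correctly with predicted-class
#' probability above `p_threshold`, attributes each of them, and averages the
#' signed attributions: per condition, and combined into one signed map whose
#' positive values mark features that drive decisions toward the positive
#' (second) condition and negative values features favoring the first — the
#' red/blue convention of bipolar saliency displays.
#'
#' @param model a trained `eegnet_model` or `logistic_model`.
#' @param epochs held-out `epoch_set` to attribute.
#' @param p_threshold minimum predicted-class probability (default 0.9).
#' @param method attribution method, see [attribute_trial()].
#' @param baseline reference input passed through.
#' @param stage optional stage label.
#' @return an object of class `saliency_map`: `importance` (channels x
#'   samples, signed), `per_condition` maps, `n_trials_used`, `times`,
#'   `channel_names`, `stage`, and the selection rule used.
#' @export
condition_saliency_map <- function(model, epochs, p_threshold = 0.9,
                                   method = "deeplift_rescale",
                                   baseline = NULL, stage = NA_character_) {
  stopifnot(inherits(epochs, "epoch_set"))
  classes <- model$classes
  prob <- predict(model, epochs, type = "prob")
  pred <- classes[1L + (prob > 0.5)]
  pred_prob <- ifelse(prob > 0.5, prob, 1 - prob)
  selected <- pred == epochs$labels & pred_prob > p_threshold
  nch <- n_channels(epochs); nsm <- n_samples(epochs)
  per_condition <- list()
  n_used <- stats::setNames(integer(2L), classes)
  total <- matrix(0, nch, nsm)
  n_total <- 0L
  for (cl in classes) {
    idx <- which(selected & epochs$labels == cl)
    n_used[cl] <- length(idx)
    if (length(idx) == 0L) {
      warning("no trial of condition '", cl, "' passes the p > ",
              p_threshold, " selection; side left empty")
      per_condition[[cl]] <- matrix(0, nch, nsm)
      next
    }
    acc <- matrix(0, nch, nsm)
    for (i in idx)
      acc <- acc + attribute_trial(model, epochs$data[i, , , drop = TRUE],
                                   method = method, baseline = baseline)
    per_condition[[cl]] <- acc / length(idx)
    total <- total + acc
    n_total <- n_total + length(idx)
  }
  importance <- if (n_total > 0L) total / n_total else total
  dimnames(importance) <- list(epochs$channel_names, NULL)
  structure(list(importance = importance, per_condition = per_condition,
                 n_trials_used = n_used, p_threshold = p_threshold,
                 method = method, stage = stage, times = epochs$times,
                 channel_names = epochs$channel_names,
                 positive_class = classes[2L]),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map>%s %s, %s trials used (%s), positive class '%s'\n",
              if (is.na(x$stage)) "" else paste0(" [", x$stage, "]"),
              x$method, paste(x$n_trials_used, collapse = "+"),
              paste(names(x$n_trials_used), collapse = "/"),
              x$positive_class))
  invisible(x)
}

#' Temporal centroid of one side of a saliency map
#'
#' The importance-weighted mean latency of the positive (or negative) mass,
#' used to compare when each condition's discriminative features occur.
#'
#' @param map a `saliency_map` or channels x samples matrix.
#' @param sign_of "positive" or "negative" mass.
#' @param times required when `map` is a bare matrix.
#' @return centroid latency in ms.
#' @export
saliency_centroid <- function(map, sign_of = c("positive", "negative"),
                              times = NULL) {
  sign_of <- match.arg(sign_of)
  if (inherits(map, "saliency_map")) {
    times <- map$times
    m <- map$importance
  } else m <- map
  v <- colSums(if (sign_of == "positive") pmax(m, 0) else pmax(-m, 0))
  if (sum(v) == 0) return(NA_real_)
  sum(times * v) / sum(v)
}
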