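# Compact convolutional network for two-class single-trial EEG decoding.
#
# Three blocks: (1) K1 temporal convolutions (1, L1) shared across electrodes,
# batch-normalized; (2) K2 spatial convolutions (C, 1) per temporal map, batch
# norm, ELU, average pooling, dropout; (3) a depthwise temporal convolution of
# length L2 = floor(L1/2) per feature map, a 1x1 merge across all K1*K2 maps,
# batch norm, ELU, average pooling, dropout, then a flatten and a single-logit
# sigmoid head. Trained with Adam on binary cross-entropy with L2 weight decay.
# Implemented self-contained (dense matrix ops only) so that the same forward/
# backward machinery can also propagate DeepLIFT multipliers.

#' Classifier configuration
#'
#' @param channels electrode count C.
#' @param samples input length T in samples; must be >= `l1`.
#' @param k1 number of temporal kernels (default 4).
#' @param k2 spatial kernels per temporal kernel (default 2).
#' @param l1 temporal kernel length in samples; default half the input length,
#'   rounded down to an odd number (>= 3).
#' @param l2 separable kernel length; default `floor(l1/2)`.
#' @param dropout dropout rate in blocks 2-3 (default 0.2).
#' @param weight_decay L2 penalty on convolution/dense weights (default 1e-3).
#' @param lr Adam learning rate (default 0.05).
#' @param n_epochs training epochs (default 100).
#' @param batch_size minibatch size (default 64).
#' @param pool1,pool2 average-pooling lengths of blocks 2 and 3 (defaults 4
#'   and 8, each clipped to the available length).
#' @param seed RNG seed governing initialization, shuffling and dropout.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(channels, samples, k1 = 4, k2 = 2,
                              l1 = NULL, l2 = NULL, dropout = 0.2,
                              weight_decay = 1e-3, lr = 0.05,
                              n_epochs = 100, batch_size = 64,
                              pool1 = 4, pool2 = 8, seed = 1L) {
  if (is.null(l1)) {
    l1 <- samples %/% 2L
    if (l1 %% 2L == 0L) l1 <- l1 - 1L
    l1 <- max(l1, 3L)
  }
  if (is.null(l2)) l2 <- max(l1 %/% 2L, 1L)
  if (samples < l1) stop("input length (", samples,
                         ") is shorter than the temporal kernel (", l1, ")")
  stopifnot(k1 >= 1, k2 >= 1, dropout >= 0, dropout < 1, lr > 0,
            n_epochs >= 1, batch_size >= 1)
  structure(list(channels = as.integer(channels), samples = as.integer(samples),
                 k1 = as.integer(k1), k2 = as.integer(k2),
                 l1 = as.integer(l1), l2 = as.integer(l2),
                 dropout = dropout, weight_decay = weight_decay, lr = lr,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# ---- primitive layers -------------------------------------------------------

# 'same'-padded 1-D convolution along columns of an R x T matrix
conv_same_fwd <- function(X, w, p_left) {
  Tn <- ncol(X)
  out <- matrix(0, nrow(X), Tn)
  for (l in seq_along(w)) {
    off <- l - 1L - p_left
    t1 <- max(1L, 1L - off); t2 <- min(Tn, Tn - off)
    if (t1 > t2) next
    out[, t1:t2] <- out[, t1:t2] + w[l] * X[, (t1 + off):(t2 + off)]
  }
  out
}

conv_same_bwd <- function(dY, X, w, p_left) {
  Tn <- ncol(X)
  dX <- matrix(0, nrow(X), Tn)
  dw <- numeric(length(w))
  for (l in seq_along(w)) {
    off <- l - 1L - p_left
    t1 <- max(1L, 1L - off); t2 <- min(Tn, Tn - off)
    if (t1 > t2) next
    dX[, (t1 + off):(t2 + off)] <- dX[, (t1 + off):(t2 + off)] +
      w[l] * dY[, t1:t2]
    dw[l] <- sum(X[, (t1 + off):(t2 + off)] * dY[, t1:t2])
  }
  list(dX = dX, dw = dw)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training, eps = 1e-5) {
  if (training) {
    mu <- mean(x); v <- mean((x - mu)^2)
  } else {
    mu <- run_mean; v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  list(y = gamma * xhat + beta, xhat = xhat, mu = mu, v = v, inv = inv,
       training = training)
}

bn_bwd <- function(dy, cache, gamma) {
  dgamma <- sum(dy * cache$xhat)
  dbeta <- sum(dy)
  dxhat <- dy * gamma
  if (!cache$training) {  # eval mode: affine, no stats gradient
    return(list(dx = dxhat * cache$inv, dgamma = dgamma, dbeta = dbeta))
  }
  m <- length(dy)
  x_mu <- cache$xhat / cache$inv
  dvar <- sum(dxhat * x_mu) * (-0.5) * cache$inv^3
  dmu <- -sum(dxhat) * cache$inv + dvar * mean(-2 * x_mu)
  dx <- dxhat * cache$inv + dvar * 2 * x_mu / m + dmu / m
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

avgpool_fwd <- function(X, p) {
  Tn <- ncol(X); To <- Tn %/% p
  if (To < 1L) stop("pooling length exceeds the feature length")
  out <- matrix(0, nrow(X), To)
  for (j in seq_len(To))
    out[, j] <- rowMeans(X[, ((j - 1L) * p + 1L):(j * p), drop = FALSE])
  out
}

avgpool_bwd <- function(dY, p, Tn) {
  dX <- matrix(0, nrow(dY), Tn)
  for (j in seq_len(ncol(dY)))
    dX[, ((j - 1L) * p + 1L):(j * p)] <- dY[, j] / p
  dX
}

# ---- model ------------------------------------------------------------------

#' Build an untrained network from a configuration
#'
#' Initializes all convolution and dense weights (He/Glorot scaled Gaussians,
#' deterministic given the config seed) and the batch-norm parameters and
#' running statistics.
#'
#' @param cfg a `classifier_config`.
#' @return an object of class `eegnet_model`.
#' @export
build_eegnet <- function(cfg) {
  stopifnot(inherits(cfg, "classifier_config"))
  with_local_seed(cfg$seed, {
    C <- cfg$channels; Tn <- cfg$samples
    K1 <- cfg$k1; K2 <- cfg$k2; nF <- K1 * K2
    T2 <- Tn %/% min(cfg$pool1, Tn)
    p2 <- min(cfg$pool2, T2)
    T3 <- T2 %/% p2
    D <- nF * T3
    rnormw <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))
    params <- list(
      W1 = matrix(rnormw(K1 * cfg$l1, cfg$l1), K1, cfg$l1),
      W2 = lapply(seq_len(K1), function(i) matrix(rnormw(K2 * C, C), K2, C)),
      W3 = matrix(rnormw(nF * cfg$l2, cfg$l2), nF, cfg$l2),
      W4 = matrix(rnormw(nF * nF, nF), nF, nF),
      W5 = matrix(stats::rnorm(D, 0, sqrt(1 / max(D, 1))), D, 1),
      b5 = 0,
      bn1_gamma = rep(1, K1), bn1_beta = rep(0, K1),
      bn2_gamma = rep(1, nF), bn2_beta = rep(0, nF),
      bn3_gamma = rep(1, nF), bn3_beta = rep(0, nF))
    running <- list(bn1_mean = rep(0, K1), bn1_var = rep(1, K1),
                    bn2_mean = rep(0, nF), bn2_var = rep(1, nF),
                    bn3_mean = rep(0, nF), bn3_var = rep(1, nF))
    structure(list(cfg = cfg, params = params, running = running,
                   pool1 = min(cfg$pool1, Tn), pool2 = p2,
                   T2 = T2, T3 = T3, F = nF,
                   p1_left = (cfg$l1 - 1L) %/% 2L,
                   p2_left = (cfg$l2 - 1L) %/% 2L,
                   classes = NULL, trained = FALSE),
              class = "eegnet_model")
  })
}

#' @export
print.eegnet_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<eegnet_model> C=%d T=%d | K1=%d (L1=%d) K2=%d | L2=%d | %s\n",
              cfg$channels, cfg$samples, cfg$k1, cfg$l1, cfg$k2, cfg$l2,
              if (x$trained) paste0("trained (classes ",
                                    paste(x$classes, collapse = "/"), ")")
              else "untrained"))
  invisible(x)
}

# forward pass; X is N x C x T. Returns logits and, if requested, a cache for
# backward/multiplier passes.
eegnet_forward <- function(model, X, training = FALSE, masks = NULL,
                           keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params; run <- model$running
  N <- dim(X)[1L]; C <- cfg$channels; Tn <- cfg$samples
  K1 <- cfg$k1; K2 <- cfg$k2; nF <- model$F
  Xm <- matrix(X, nrow = N * C, ncol = Tn)
  cache <- list(Xm = Xm, N = N)
  # block 1: temporal conv + BN
  A <- vector("list", K1); bn1 <- vector("list", K1)
  for (k in seq_len(K1)) {
    A[[k]] <- conv_same_fwd(Xm, p$W1[k, ], model$p1_left)
    bn1[[k]] <- bn_fwd(A[[k]], p$bn1_gamma[k], p$bn1_beta[k],
                       run$bn1_mean[k], run$bn1_var[k], training)
  }
  cache$A <- A; cache$bn1 <- bn1
  # block 2: spatial conv + BN + ELU + pool + dropout
  Zp <- vector("list", K1)
  Fmaps <- vector("list", nF); bn2 <- vector("list", nF)
  pre_elu2 <- vector("list", nF); post2 <- vector("list", nF)
  for (k1 in seq_len(K1)) {
    Z <- array(bn1[[k1]]$y, dim = c(N, C, Tn))
    Zp[[k1]] <- matrix(aperm(Z, c(2L, 1L, 3L)), nrow = C)  # C x (N*T)
    M <- p$W2[[k1]] %*% Zp[[k1]]
    for (k2 in seq_len(K2)) {
      f <- (k1 - 1L) * K2 + k2
      Fmaps[[f]] <- matrix(M[k2, ], nrow = N)
      bn2[[f]] <- bn_fwd(Fmaps[[f]], p$bn2_gamma[f], p$bn2_beta[f],
                         run$bn2_mean[f], run$bn2_var[f], training)
      pre_elu2[[f]] <- bn2[[f]]$y
      h <- avgpool_fwd(elu(pre_elu2[[f]]), model$pool1)
      if (!is.null(masks)) h <- h * masks$m2[[f]]
      post2[[f]] <- h
    }
  }
  cache$Zp <- Zp; cache$Fmaps <- Fmaps; cache$bn2 <- bn2
  cache$pre_elu2 <- pre_elu2; cache$post2 <- post2
  # block 3: depthwise + pointwise + BN + ELU + pool + dropout
  Dw <- vector("list", nF)
  for (f in seq_len(nF))
    Dw[[f]] <- conv_same_fwd(post2[[f]], p$W3[f, ], model$p2_left)
  Pw <- vector("list", nF); bn3 <- vector("list", nF)
  pre_elu3 <- vector("list", nF); post3 <- vector("list", nF)
  for (fo in seq_len(nF)) {
    acc <- matrix(0, N, model$T2)
    for (f in seq_len(nF)) acc <- acc + p$W4[fo, f] * Dw[[f]]
    Pw[[fo]] <- acc
    bn3[[fo]] <- bn_fwd(acc, p$bn3_gamma[fo], p$bn3_beta[fo],
                        run$bn3_mean[fo], run$bn3_var[fo], training)
    pre_elu3[[fo]] <- bn3[[fo]]$y
    h <- avgpool_fwd(elu(pre_elu3[[fo]]), model$pool2)
    if (!is.null(masks)) h <- h * masks$m3[[fo]]
    post3[[fo]] <- h
  }
  cache$Dw <- Dw; cache$Pw <- Pw; cache$bn3 <- bn3
  cache$pre_elu3 <- pre_elu3; cache$post3 <- post3
  Zfl <- do.call(cbind, post3)             # N x (F*T3)
  logits <- as.numeric(Zfl %*% p$W5 + p$b5)
  cache$Zfl <- Zfl
  if (keep_cache) list(logits = logits, cache = cache) else list(logits = logits)
}

# backward pass; dlogits length N. elu_mult: optional list(e2, e3) of explicit
# elementwise multipliers replacing the ELU derivative (DeepLIFT rescale).
# Returns grads (same shapes as params) and dX (N x C x T).
eegnet_backward <- function(model, cache, dlogits, masks = NULL,
                            elu_mult = NULL) {
  cfg <- model$cfg; p <- model$params
  N <- cache$N; C <- cfg$channels; Tn <- cfg$samples
  K1 <- cfg$k1; K2 <- cfg$k2; nF <- model$F
  g <- list(W1 = matrix(0, K1, cfg$l1),
            W2 = lapply(seq_len(K1), function(i) matrix(0, K2, C)),
            W3 = matrix(0, nF, cfg$l2), W4 = matrix(0, nF, nF),
            W5 = matrix(0, nrow(p$W5), 1), b5 = 0,
            bn1_gamma = rep(0, K1), bn1_beta = rep(0, K1),
            bn2_gamma = rep(0, nF), bn2_beta = rep(0, nF),
            bn3_gamma = rep(0, nF), bn3_beta = rep(0, nF))
  g$W5 <- t(cache$Zfl) %*% matrix(dlogits, ncol = 1)
  g$b5 <- sum(dlogits)
  dZfl <- matrix(dlogits, ncol = 1) %*% t(p$W5)   # N x (F*T3)
  T3 <- model$T3
  dDw <- vector("list", nF)
  for (f in seq_len(nF)) dDw[[f]] <- matrix(0, N, model$T2)
  for (fo in seq_len(nF)) {
    dh <- dZfl[, ((fo - 1L) * T3 + 1L):(fo * T3), drop = FALSE]
    if (!is.null(masks)) dh <- dh * masks$m3[[fo]]
    dpre <- avgpool_bwd(dh, model$pool2, model$T2)
    dpre <- dpre * (if (is.null(elu_mult)) elu_grad(cache$pre_elu3[[fo]])
                    else elu_mult$e3[[fo]])
    bb <- bn_bwd(dpre, cache$bn3[[fo]], p$bn3_gamma[fo])
    g$bn3_gamma[fo] <- bb$dgamma; g$bn3_beta[fo] <- bb$dbeta
    dP <- bb$dx
    for (f in seq_len(nF)) {
      g$W4[fo, f] <- sum(dP * cache$Dw[[f]])
      dDw[[f]] <- dDw[[f]] + p$W4[fo, f] * dP
    }
  }
  dpost2 <- vector("list", nF)
  for (f in seq_len(nF)) {
    cb <- conv_same_bwd(dDw[[f]], cache$post2[[f]], p$W3[f, ], model$p2_left)
    g$W3[f, ] <- cb$dw
    dpost2[[f]] <- cb$dX
  }
  dXm <- matrix(0, N * C, Tn)
  for (k1 in seq_len(K1)) {
    dM <- matrix(0, K2, ncol(cache$Zp[[k1]]))
    for (k2 in seq_len(K2)) {
      f <- (k1 - 1L) * K2 + k2
      dh <- dpost2[[f]]
      if (!is.null(masks)) dh <- dh * masks$m2[[f]]
      dpre <- avgpool_bwd(dh, model$pool1, Tn)
      dpre <- dpre * (if (is.null(elu_mult)) elu_grad(cache$pre_elu2[[f]])
                      else elu_mult$e2[[f]])
      bb <- bn_bwd(dpre, cache$bn2[[f]], p$bn2_gamma[f])
      g$bn2_gamma[f] <- bb$dgamma; g$bn2_beta[f] <- bb$dbeta
      dM[k2, ] <- as.numeric(bb$dx)
    }
    g$W2[[k1]] <- dM %*% t(cache$Zp[[k1]])
    dZp <- t(p$W2[[k1]]) %*% dM                 # C x (N*T)
    dZ <- aperm(array(dZp, dim = c(C, N, Tn)), c(2L, 1L, 3L))
    dA <- matrix(dZ, nrow = N * C)
    bb <- bn_bwd(dA, cache$bn1[[k1]], p$bn1_gamma[k1])
    g$bn1_gamma[k1] <- bb$dgamma; g$bn1_beta[k1] <- bb$dbeta
    cb <- conv_same_bwd(bb$dx, cache$Xm, p$W1[k1, ], model$p1_left)
    g$W1[k1, ] <- cb$dw
    dXm <- dXm + cb$dX
  }
  list(grads = g, dX = array(dXm, dim = c(N, C, Tn)))
}

update_running <- function(model, caches, momentum = 0.1) {
  run <- model$running
  for (k in seq_len(model$cfg$k1)) {
    run$bn1_mean[k] <- (1 - momentum) * run$bn1_mean[k] + momentum * caches$bn1[[k]]$mu
    run$bn1_var[k] <- (1 - momentum) * run$bn1_var[k] + momentum * caches$bn1[[k]]$v
  }
  for (f in seq_len(model$F)) {
    run$bn2_mean[f] <- (1 - momentum) * run$bn2_mean[f] + momentum * caches$bn2[[f]]$mu
    run$bn2_var[f] <- (1 - momentum) * run$bn2_var[f] + momentum * caches$bn2[[f]]$v
    run$bn3_mean[f] <- (1 - momentum) * run$bn3_mean[f] + momentum * caches$bn3[[f]]$mu
    run$bn3_var[f] <- (1 - momentum) * run$bn3_var[f] + momentum * caches$bn3[[f]]$v
  }
  model$running <- run
  model
}

draw_masks <- function(model, N) {
  rate <- model$cfg$dropout
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  mk <- function(nr, nc) matrix(stats::rbinom(nr * nc, 1, keep) / keep, nr, nc)
  list(m2 = lapply(seq_len(model$F), function(f) mk(N, model$T2)),
       m3 = lapply(seq_len(model$F), function(f) mk(N, model$T3)))
}

# run body with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Train the network on an epoch_set
#'
#' Minimizes binary cross-entropy with Adam and L2 weight decay; batch
#' statistics feed the batch-norm layers during training and exponential
#' running statistics are kept for inference. Fully deterministic given the
#' config seed (fixed initialization, shuffling and dropout masks).
#'
#' @param epochs an `epoch_set` with exactly two condition labels, or a plain
#'   N x C x T array plus `labels`.
#' @param cfg a `classifier_config`; defaults to one sized to the input.
#' @param labels required when `epochs` is a bare array.
#' @param verbose print the loss every 10 epochs.
#' @return a trained `eegnet_model`; `classes` maps the sigmoid output to the
#'   second (positive) class.
#' @export
train_eegnet <- function(epochs, cfg = NULL, labels = NULL, verbose = FALSE) {
  if (inherits(epochs, "epoch_set")) {
    X <- epochs$data; labels <- epochs$labels
  } else X <- epochs
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly two classes")
  y <- as.numeric(labels == classes[2L])
  if (is.null(cfg))
    cfg <- classifier_config(channels = dim(X)[2L], samples = dim(X)[3L])
  model <- build_eegnet(cfg)
  model$classes <- classes
  adam <- list(m = rapply(model$params, function(x) x * 0, how = "replace"),
               v = rapply(model$params, function(x) x * 0, how = "replace"),
               t = 0L)
  N <- dim(X)[1L]
  with_local_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$n_epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (b0 in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
        if (length(idx) < 2L) next  # batch statistics need >= 2 rows
        Xb <- X[idx, , , drop = FALSE]
        yb <- y[idx]
        masks <- draw_masks(model, length(idx))
        fw <- eegnet_forward(model, Xb, training = TRUE, masks = masks,
                             keep_cache = TRUE)
        prob <- stats::plogis(fw$logits)
        loss <- -mean(yb * log(pmax(prob, 1e-12)) +
                        (1 - yb) * log(pmax(1 - prob, 1e-12)))
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep,
               " (logit range [", min(fw$logits), ", ", max(fw$logits), "])")
        losses <- c(losses, loss)
        dlogits <- (prob - yb) / length(idx)
        bw <- eegnet_backward(model, fw$cache, dlogits, masks = masks)
        res <- adam_step(model$params, bw$grads, adam, cfg$lr,
                         cfg$weight_decay)
        model$params <- res$params; adam <- res$adam
        model <- update_running(model, fw$cache)
      }
      if (verbose && ep %% 10L == 0L)
        message(sprintf("epoch %3d  loss %.4f", ep, mean(losses)))
    }
  })
  model$trained <- TRUE
  model
}

adam_step <- function(params, grads, adam, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  adam$t <- adam$t + 1L
  step1 <- function(w, gw, m, v, decay) {
    if (decay) gw <- gw + weight_decay * w
    m <- beta1 * m + (1 - beta1) * gw
    v <- beta2 * v + (1 - beta2) * gw^2
    mh <- m / (1 - beta1^adam$t)
    vh <- v / (1 - beta2^adam$t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in names(params)) {
    decay <- startsWith(nm, "W")
    if (is.list(params[[nm]])) {
      for (i in seq_along(params[[nm]])) {
        r <- step1(params[[nm]][[i]], grads[[nm]][[i]],
                   adam$m[[nm]][[i]], adam$v[[nm]][[i]], decay)
        params[[nm]][[i]] <- r$w; adam$m[[nm]][[i]] <- r$m
        adam$v[[nm]][[i]] <- r$v
      }
    } else {
      r <- step1(params[[nm]], grads[[nm]], adam$m[[nm]], adam$v[[nm]], decay)
      params[[nm]] <- r$w; adam$m[[nm]] <- r$m; adam$v[[nm]] <- r$v
    }
  }
  list(params = params, adam = adam)
}

#' Predict class probabilities from a trained network
#'
#' @param object a trained `eegnet_model`.
#' @param newdata an `epoch_set` or N x C x T array.
#' @param type "prob" (probability of the positive class), "logit" or "class".
#' @param ... unused.
#' @return numeric vector (or character for `type = "class"`).
#' @export
predict.eegnet_model <- function(object, newdata, type = c("prob", "logit",
                                                           "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "epoch_set")) newdata$data else newdata
  if (length(dim(X)) == 2L) X <- array(X, dim = c(1L, dim(X)))
  logits <- eegnet_forward(object, X)$logits
  switch(type,
         logit = logits,
         prob = stats::plogis(logits),
         class = object$classes[1L + (stats::plogis(logits) > 0.5)])
}
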