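#' Configuration for the stacked sparse autoencoder classifier
#'
#' Two ReLU autoencoder layers (input -> hidden1 -> hidden2) trained greedily
#' without labels under a reconstruction + KL-sparsity loss, then stacked
#' under a softmax head and fine-tuned end-to-end with cross-entropy.
#' Defaults are the published training recipe for the 1000-feature
#' connectivity input: layers 1000/500/100, Adam, 50 pre-training epochs at
#' learning rate 1e-3, 50 fine-tuning epochs at 1e-4, weight decay 1e-4,
#' batch size 128, sparsity target rho = 0.2 with weight beta = 2.
#'
#' `rho_hat_mode` picks how the mean activation entering the KL term is
#' squashed into (0,1) under ReLU forward passes: `"sigmoid"` (default)
#' evaluates the KL on sigmoid(pre-activation); `"relu_clip"` uses the batch
#' mean of the ReLU outputs clipped to [0,1].
#'
#' @param input_dim,hidden1,hidden2 layer widths (hidden2 < hidden1 < input).
#' @param rho target sparsity in (0,1).
#' @param beta sparsity penalty weight.
#' @param pretrain_epochs,finetune_epochs epoch counts.
#' @param pretrain_lr,finetune_lr Adam learning rates.
#' @param weight_decay L2 weight decay coefficient.
#' @param batch_size minibatch size.
#' @param rho_hat_mode "sigmoid" or "relu_clip".
#' @param seed integer seed for weight init and batch shuffling.
#' @return list of class `ssae_config`.
#' @export
ssae_config <- function(input_dim = 1000, hidden1 = 500, hidden2 = 100,
                        rho = 0.2, beta = 2,
                        pretrain_epochs = 50, finetune_epochs = 50,
                        pretrain_lr = 1e-3, finetune_lr = 1e-4,
                        weight_decay = 1e-4, batch_size = 128,
                        rho_hat_mode = c("sigmoid", "relu_clip"),
                        seed = 1L) {
  rho_hat_mode <- match.arg(rho_hat_mode)
  if (!(hidden2 < hidden1 && hidden1 < input_dim))
    stop("layer widths must satisfy hidden2 < hidden1 < input_dim")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (pretrain_lr <= 0 || finetune_lr <= 0) stop("learning rates must be > 0")
  structure(list(input_dim = as.integer(input_dim),
                 hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 rho = rho, beta = beta,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 pretrain_lr = pretrain_lr, finetune_lr = finetune_lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 rho_hat_mode = rho_hat_mode, seed = as.integer(seed)),
            class = "ssae_config")
}

#' KL-divergence sparsity penalty
#'
#' Sum over hidden units of KL(rho || rho_hat_j) for Bernoulli rates:
#' rho*log(rho/rho_hat) + (1-rho)*log((1-rho)/(1-rho_hat)). Mean activations
#' are clipped into (eps, 1-eps) so boundary values never produce NaN.
#'
#' @param rho_hat vector of per-unit mean activations.
#' @param rho target sparsity in (0,1).
#' @param eps clipping margin.
#' @return non-negative scalar, zero iff every rho_hat equals rho.
#' @export
sparsity_penalty <- function(rho_hat, rho, eps = 1e-7) {
  rh <- pmin(pmax(rho_hat, eps), 1 - eps)
  sum(rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh)))
}

#' Sparse-autoencoder loss: reconstruction MSE plus weighted KL penalty
#'
#' @param x,x_hat input and reconstruction (equal-length vectors/matrices).
#' @param rho_hat per-hidden-unit mean activations.
#' @param config an [ssae_config()] supplying `rho` and `beta`.
#' @return scalar loss.
#' @export
ae_loss <- function(x, x_hat, rho_hat, config) {
  if (length(x) != length(x_hat)) stop("x and x_hat must have equal shape")
  mean((x - x_hat)^2) + config$beta * sparsity_penalty(rho_hat, config$rho)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## fan-in scaled uniform init
init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (n in names(params)) {
    g <- grads[[n]] + weight_decay * params[[n]]
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * g
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * g^2
    mhat <- state$m[[n]] / (1 - beta1^state$t)
    vhat <- state$v[[n]] / (1 - beta2^state$t)
    params[[n]] <- params[[n]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## rho_hat (and its backprop path) for a batch of pre-activations A with
## ReLU outputs H. Returns list(rho_hat, dA) where dA is the gradient of
## beta*KL wrt A (already scaled by batch size).
kl_grad <- function(A, H, rho, beta, mode, eps = 1e-7) {
  B <- nrow(A)
  if (mode == "sigmoid") {
    S <- sigmoid(A)
    rho_hat <- colMeans(S)
    rh <- pmin(pmax(rho_hat, eps), 1 - eps)
    dKLdrh <- -rho / rh + (1 - rho) / (1 - rh)
    dA <- sweep(S * (1 - S), 2, beta * dKLdrh / B, "*")
  } else {
    Hc <- pmin(H, 1)
    rho_hat <- colMeans(Hc)
    rh <- pmin(pmax(rho_hat, eps), 1 - eps)
    dKLdrh <- -rho / rh + (1 - rho) / (1 - rh)
    mask <- (A > 0) & (H < 1)
    dA <- sweep(mask * 1, 2, beta * dKLdrh / B, "*")
  }
  list(rho_hat = rho_hat, dA = dA)
}

## Train one sparse autoencoder layer (ReLU encoder, linear decoder).
train_ae_layer <- function(X, nin, nhid, config, lr, epochs, stage) {
  W <- init_mat(nin, nhid); b <- numeric(nhid)
  Wd <- init_mat(nhid, nin); bd <- numeric(nin)
  params <- list(W = W, b = b, Wd = Wd, bd = bd)
  st <- adam_new(params)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  rho_hat <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batch <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      B <- nrow(Xb)
      A <- sweep(Xb %*% params$W, 2, params$b, "+")
      H <- pmax(A, 0)
      Xhat <- sweep(H %*% params$Wd, 2, params$bd, "+")
      kg <- kl_grad(A, H, config$rho, config$beta, config$rho_hat_mode)
      loss <- mean((Xb - Xhat)^2) +
        config$beta * sparsity_penalty(kg$rho_hat, config$rho)
      if (!is.finite(loss))
        stop(sprintf("non-finite %s loss at epoch %d (lr = %g)",
                     stage, ep, lr))
      dXhat <- 2 * (Xhat - Xb) / (B * nin)
      gWd <- crossprod(H, dXhat)
      gbd <- colSums(dXhat)
      dH <- tcrossprod(dXhat, params$Wd)
      dA <- dH * (A > 0) + kg$dA
      gW <- crossprod(Xb, dA)
      gb <- colSums(dA)
      up <- adam_step(params, list(W = gW, b = gb, Wd = gWd, bd = gbd),
                      st, lr, config$weight_decay)
      params <- up$params; st <- up$state
      ep_loss <- ep_loss + loss; n_batch <- n_batch + 1L
      rho_hat <- kg$rho_hat
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n_batch))
  }
  list(W = params$W, b = params$b, Wd = params$Wd, bd = params$bd,
       history = history, rho_hat = rho_hat)
}

#' Greedy layer-wise pre-training of the stacked sparse autoencoder
#'
#' Trains the first autoencoder (input -> hidden1 -> input) on the feature
#' matrix under the reconstruction + KL-sparsity loss, freezes its encoder,
#' pushes the data through it, and trains the second autoencoder
#' (hidden1 -> hidden2 -> hidden1) on those codes.
#'
#' @param features n x input_dim numeric matrix (standardised upstream).
#' @param config an [ssae_config()].
#' @return list of class `ssae_pretrained` with encoder/decoder weights for
#'   both layers, per-epoch loss histories, and final batch mean activations
#'   (`rho_hat1`, `rho_hat2`).
#' @export
ssae_pretrain <- function(features, config) {
  stopifnot(ncol(features) == config$input_dim)
  set.seed(config$seed)
  ae1 <- train_ae_layer(features, config$input_dim, config$hidden1,
                        config, config$pretrain_lr, config$pretrain_epochs,
                        "AE1")
  H1 <- pmax(sweep(features %*% ae1$W, 2, ae1$b, "+"), 0)
  ae2 <- train_ae_layer(H1, config$hidden1, config$hidden2,
                        config, config$pretrain_lr, config$pretrain_epochs,
                        "AE2")
  structure(list(encoder1 = list(W = ae1$W, b = ae1$b),
                 decoder1 = list(W = ae1$Wd, b = ae1$bd),
                 encoder2 = list(W = ae2$W, b = ae2$b),
                 decoder2 = list(W = ae2$Wd, b = ae2$bd),
                 rho_hat1 = ae1$rho_hat, rho_hat2 = ae2$rho_hat,
                 history = rbind(cbind(stage = "AE1", ae1$history),
                                 cbind(stage = "AE2", ae2$history)),
                 config = config),
            class = "ssae_pretrained")
}

softmax_rows <- function(L) {
  E <- exp(L - apply(L, 1, max))
  E / rowSums(E)
}

#' Supervised fine-tuning of the stacked encoders plus softmax head
#'
#' Stacks encoder1 -> encoder2 -> softmax and minimises cross-entropy over
#' the labels, updating all parameters jointly. When validation data are
#' supplied, per-epoch validation loss/accuracy are recorded and the
#' checkpoint with the best validation accuracy is returned; otherwise the
#' final-epoch weights are returned.
#'
#' @param pretrained an `ssae_pretrained`, or `NULL` to fine-tune from a
#'   random initialisation (used to quantify the value of pre-training).
#' @param features,labels training matrix and two-level factor
#'   (levels: control, case).
#' @param config an [ssae_config()].
#' @param val_features,val_labels optional validation split.
#' @return list of class `ssae_model` with weights `W1,b1,W2,b2,W3,b3`,
#'   `history` (epoch, train_loss, train_acc, val_loss, val_acc), `config`,
#'   and `classes`.
#' @export
ssae_finetune <- function(pretrained, features, labels, config,
                          val_features = NULL, val_labels = NULL) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (length(classes) != 2) stop("finetune expects a two-level factor")
  set.seed(config$seed + 1L)
  if (is.null(pretrained)) {
    params <- list(W1 = init_mat(config$input_dim, config$hidden1),
                   b1 = numeric(config$hidden1),
                   W2 = init_mat(config$hidden1, config$hidden2),
                   b2 = numeric(config$hidden2),
                   W3 = init_mat(config$hidden2, 2L), b3 = numeric(2L))
  } else {
    params <- list(W1 = pretrained$encoder1$W, b1 = pretrained$encoder1$b,
                   W2 = pretrained$encoder2$W, b2 = pretrained$encoder2$b,
                   W3 = init_mat(config$hidden2, 2L), b3 = numeric(2L))
  }
  st <- adam_new(params)
  Y <- cbind(labels == classes[1], labels == classes[2]) * 1
  n <- nrow(features)
  bs <- min(config$batch_size, n)
  hist_rows <- vector("list", config$finetune_epochs)
  best <- list(acc = -Inf, loss = Inf, params = params)
  for (ep in seq_len(config$finetune_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- features[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      B <- nrow(Xb)
      A1 <- sweep(Xb %*% params$W1, 2, params$b1, "+"); H1 <- pmax(A1, 0)
      A2 <- sweep(H1 %*% params$W2, 2, params$b2, "+"); H2 <- pmax(A2, 0)
      L <- sweep(H2 %*% params$W3, 2, params$b3, "+")
      P <- softmax_rows(L)
      loss <- -mean(rowSums(Yb * log(pmax(P, 1e-12))))
      if (!is.finite(loss))
        stop(sprintf("non-finite fine-tune loss at epoch %d (lr = %g)",
                     ep, config$finetune_lr))
      dL <- (P - Yb) / B
      gW3 <- crossprod(H2, dL); gb3 <- colSums(dL)
      dH2 <- tcrossprod(dL, params$W3); dA2 <- dH2 * (A2 > 0)
      gW2 <- crossprod(H1, dA2); gb2 <- colSums(dA2)
      dH1 <- tcrossprod(dA2, params$W2); dA1 <- dH1 * (A1 > 0)
      gW1 <- crossprod(Xb, dA1); gb1 <- colSums(dA1)
      up <- adam_step(params,
                      list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                           W3 = gW3, b3 = gb3),
                      st, config$finetune_lr, config$weight_decay)
      params <- up$params; st <- up$state
    }
    tr <- eval_softmax(params, features, Y)
    va <- if (!is.null(val_features)) {
      Yv <- cbind(val_labels == classes[1], val_labels == classes[2]) * 1
      eval_softmax(params, val_features, Yv)
    } else list(loss = NA_real_, acc = NA_real_)
    hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = tr$loss,
                                  train_acc = tr$acc, val_loss = va$loss,
                                  val_acc = va$acc)
    ## best validation accuracy; ties broken by lower validation loss so a
    ## later, better-converged checkpoint wins over an early lucky one
    sel_acc <- if (is.na(va$acc)) tr$acc else va$acc
    sel_loss <- if (is.na(va$acc)) tr$loss else va$loss
    if (sel_acc > best$acc ||
        (sel_acc == best$acc && sel_loss < best$loss))
      best <- list(acc = sel_acc, loss = sel_loss, params = params,
                   epoch = ep)
  }
  structure(c(best$params,
              list(classes = classes, config = config,
                   best_epoch = best$epoch,
                   history = do.call(rbind, hist_rows))),
            class = "ssae_model")
}

eval_softmax <- function(params, X, Y) {
  H1 <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
  H2 <- pmax(sweep(H1 %*% params$W2, 2, params$b2, "+"), 0)
  P <- softmax_rows(sweep(H2 %*% params$W3, 2, params$b3, "+"))
  list(loss = -mean(rowSums(Y * log(pmax(P, 1e-12)))),
       acc = mean(max.col(P, ties.method = "first") ==
                    max.col(Y, ties.method = "first")))
}

#' Forward pass of a trained SSAE classifier
#'
#' @param model an `ssae_model`.
#' @param X n x input_dim matrix.
#' @return list with pre-activations `a1`, `a2`, hidden activations `h1`,
#'   `h2`, `logits`, and class `probs` (rows on the 2-class simplex).
#' @export
ssae_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  a1 <- sweep(X %*% model$W1, 2, model$b1, "+"); h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% model$W2, 2, model$b2, "+"); h2 <- pmax(a2, 0)
  logits <- sweep(h2 %*% model$W3, 2, model$b3, "+")
  list(a1 = a1, h1 = h1, a2 = a2, h2 = h2, logits = logits,
       probs = softmax_rows(logits))
}

#' Predict class labels or probabilities from a trained SSAE
#'
#' @param object an `ssae_model`; @param newdata feature matrix;
#' @param type "class" or "prob"; @param ... ignored.
#' @export
predict.ssae_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  P <- ssae_forward(object, newdata)$probs
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}
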