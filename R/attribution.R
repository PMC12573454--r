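#' @name attribution
#' @title Feature-attribution methods for the SSAE classifier
#'
#' @description Seven per-feature importance methods over a trained
#' [ssae_finetune()] model: four gradient-based (Integrated Gradients,
#' DeepLift, DeepLiftShap, GradientShap), Guided Backprop, and two
#' perturbation-based black-box methods (LIME, kernel SHAP). All methods
#' attribute the logit of the model's predicted class (per sample) unless a
#' target class is forced, and use an all-zero baseline/background by
#' default — zero Fisher-Z correlation carries no connectivity information,
#' so it is the natural "absent" value.
NULL

## rows of target logits: predicted class by default
target_cols <- function(model, X, target = NULL) {
  if (!is.null(target)) return(rep_len(as.integer(target), nrow(as_mat(X))))
  P <- ssae_forward(model, X)$probs
  max.col(P, ties.method = "first")
}

as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x

## value of the target-class logit
logit_value <- function(model, X, tcol) {
  L <- ssae_forward(model, X)$logits
  L[cbind(seq_len(nrow(L)), tcol)]
}

## gradient of the target logit wrt inputs; guided switches to the
## Guided-Backprop rule (ReLUs pass only positive gradients from positive
## activations)
logit_gradient <- function(model, X, tcol, guided = FALSE) {
  X <- as_mat(X)
  fw <- ssae_forward(model, X)
  g3 <- matrix(0, nrow(X), 2L)
  g3[cbind(seq_len(nrow(X)), tcol)] <- 1
  dH2 <- tcrossprod(g3, model$W3)
  dA2 <- if (guided) dH2 * (fw$a2 > 0) * (dH2 > 0) else dH2 * (fw$a2 > 0)
  dH1 <- tcrossprod(dA2, model$W2)
  dA1 <- if (guided) dH1 * (fw$a1 > 0) * (dH1 > 0) else dH1 * (fw$a1 > 0)
  tcrossprod(dA1, model$W1)
}

#' Integrated Gradients
#'
#' Path-integral attribution along the straight line from `baseline` to each
#' sample, using a midpoint Riemann discretisation of the gradient of the
#' target-class logit: attribution_i = (x_i - b_i) * mean_s grad_i(b +
#' (s-1/2)/n * (x-b)). Satisfies completeness up to discretisation error.
#'
#' @param model trained `ssae_model`.
#' @param X sample matrix (rows = samples) or single vector.
#' @param baseline baseline vector (default all-zero).
#' @param n_steps Riemann steps (default 200).
#' @param target fixed target class column (1 or 2), or `NULL` for the
#'   predicted class.
#' @return attribution matrix, same shape as `X`.
#' @export
integrated_gradients <- function(model, X, baseline = NULL, n_steps = 200,
                                 target = NULL) {
  X <- as_mat(X)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (is.null(baseline)) baseline <- numeric(ncol(X))
  tcol <- target_cols(model, X, target)
  D <- sweep(X, 2, baseline)
  acc <- matrix(0, nrow(X), ncol(X))
  for (s in seq_len(n_steps)) {
    alpha <- (s - 0.5) / n_steps
    Xa <- sweep(D * alpha, 2, baseline, "+")
    acc <- acc + logit_gradient(model, Xa, tcol)
  }
  D * acc / n_steps
}

#' Guided Backprop attribution
#'
#' Gradient of the target logit where every ReLU passes gradient only if
#' both its input and the incoming gradient are positive.
#' @inheritParams integrated_gradients
#' @return attribution matrix.
#' @export
guided_backprop <- function(model, X, target = NULL) {
  X <- as_mat(X)
  logit_gradient(model, X, target_cols(model, X, target), guided = TRUE)
}

#' DeepLift (rescale rule) attribution
#'
#' Propagates differences-from-reference through the network: linear layers
#' distribute deltas through their weights, ReLUs use the rescale multiplier
#' (h - h_ref)/(a - a_ref), falling back to the local gradient where the
#' pre-activation delta is ~0. For this architecture the attributions
#' satisfy summation-to-delta exactly.
#' @inheritParams integrated_gradients
#' @return attribution matrix.
#' @export
deeplift <- function(model, X, baseline = NULL, target = NULL) {
  X <- as_mat(X)
  if (is.null(baseline)) baseline <- numeric(ncol(X))
  tcol <- target_cols(model, X, target)
  fw <- ssae_forward(model, X)
  fw0 <- ssae_forward(model, matrix(baseline, 1))
  m_relu <- function(a, h, a0, h0) {
    da <- sweep(a, 2, a0)
    m <- sweep(h, 2, h0) / da
    small <- abs(da) < 1e-9
    m[small] <- (a > 0)[small] * 1
    m
  }
  r3 <- matrix(0, nrow(X), 2L)
  r3[cbind(seq_len(nrow(X)), tcol)] <- 1
  rh2 <- tcrossprod(r3, model$W3)
  ra2 <- rh2 * m_relu(fw$a2, fw$h2, fw0$a2[1, ], fw0$h2[1, ])
  rh1 <- tcrossprod(ra2, model$W2)
  ra1 <- rh1 * m_relu(fw$a1, fw$h1, fw0$a1[1, ], fw0$h1[1, ])
  rx <- tcrossprod(ra1, model$W1)
  sweep(X, 2, baseline) * rx
}

#' DeepLiftShap: DeepLift averaged over a baseline distribution
#'
#' @inheritParams integrated_gradients
#' @param baselines matrix of baseline samples (>= 1 row).
#' @return attribution matrix.
#' @export
deepliftshap <- function(model, X, baselines, target = NULL) {
  baselines <- as_mat(baselines)
  if (!nrow(baselines)) stop("baselines must contain at least one sample")
  X <- as_mat(X)
  tcol <- target_cols(model, X, target)
  acc <- matrix(0, nrow(X), ncol(X))
  for (b in seq_len(nrow(baselines)))
    acc <- acc + deeplift(model, X, baselines[b, ], target = tcol)
  acc / nrow(baselines)
}

#' GradientShap: expected gradients over a baseline distribution
#'
#' Averages grad(b + u*(x + eps - b)) * (x - b) over random baselines b,
#' uniform interpolation points u and Gaussian input noise eps; a stochastic
#' estimator of Integrated Gradients expectations under the baseline
#' distribution.
#' @inheritParams deepliftshap
#' @param n_samples Monte-Carlo draws per input sample.
#' @param stdev sd of the added input noise.
#' @param seed integer seed.
#' @return attribution matrix.
#' @export
gradientshap <- function(model, X, baselines, n_samples = 50, stdev = 0.1,
                         seed = 1L, target = NULL) {
  baselines <- as_mat(baselines)
  if (!nrow(baselines)) stop("baselines must contain at least one sample")
  X <- as_mat(X)
  tcol <- target_cols(model, X, target)
  set.seed(seed)
  acc <- matrix(0, nrow(X), ncol(X))
  for (s in seq_len(n_samples)) {
    b <- baselines[sample.int(nrow(baselines), 1), ]
    u <- stats::runif(1)
    noise <- matrix(stats::rnorm(length(X), sd = stdev), nrow(X), ncol(X))
    Xt <- sweep((sweep(X + noise, 2, b)) * u, 2, b, "+")
    acc <- acc + logit_gradient(model, Xt, tcol) * sweep(X, 2, b)
  }
  acc / n_samples
}

#' LIME: local linear surrogate with zero-imputation perturbations
#'
#' Perturbs each sample by zeroing random feature subsets (zero being the
#' uninformative connectivity value), queries the model's target logit, and
#' fits a kernel-weighted ridge surrogate whose coefficients are the
#' attributions.
#' @inheritParams integrated_gradients
#' @param n_perturbations perturbed copies per sample.
#' @param kernel_width width of the exponential proximity kernel on the
#'   fraction of masked features.
#' @param ridge ridge penalty for the surrogate fit.
#' @param seed integer seed.
#' @return attribution matrix.
#' @export
lime_explain <- function(model, X, n_perturbations = 5000,
                         kernel_width = 0.25, ridge = 1e-3, seed = 1L,
                         target = NULL) {
  X <- as_mat(X)
  p <- ncol(X)
  if (n_perturbations < p / 10)
    warning("n_perturbations < n_features/10: unstable LIME surrogate")
  tcol <- target_cols(model, X, target)
  set.seed(seed)
  out <- matrix(0, nrow(X), p)
  for (i in seq_len(nrow(X))) {
    Z <- matrix(stats::rbinom(n_perturbations * p, 1, 0.5),
                n_perturbations, p)
    Xp <- Z * matrix(X[i, ], n_perturbations, p, byrow = TRUE)
    y <- logit_value(model, Xp, rep(tcol[i], n_perturbations))
    d <- 1 - rowMeans(Z)  # fraction of features masked
    w <- exp(-(d / kernel_width)^2)
    Zc <- cbind(1, Z)
    A <- crossprod(Zc * w, Zc) + ridge * diag(p + 1)
    beta <- solve(A, crossprod(Zc * w, y))
    out[i, ] <- beta[-1]
  }
  out
}

#' Kernel SHAP: Shapley values by weighted least squares over coalitions
#'
#' Samples feature coalitions, evaluates the model with absent features set
#' to the background value, and solves the Shapley-kernel-weighted
#' regression with the local-accuracy constraint (attributions sum to
#' f(x) - f(background)) enforced exactly.
#' @inheritParams integrated_gradients
#' @param background background vector (default all-zero).
#' @param n_samples number of sampled coalitions.
#' @param ridge ridge stabiliser for the WLS solve.
#' @param seed integer seed.
#' @return attribution matrix; attribute `base_value` holds f(background).
#' @export
shap_explain <- function(model, X, background = NULL, n_samples = 2048,
                         ridge = 1e-6, seed = 1L, target = NULL) {
  X <- as_mat(X)
  p <- ncol(X)
  if (is.null(background)) background <- numeric(p)
  tcol <- target_cols(model, X, target)
  set.seed(seed)
  sizes <- seq_len(p - 1)
  size_w <- (p - 1) / (sizes * (p - sizes))
  out <- matrix(0, nrow(X), p)
  base_vals <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    f0 <- logit_value(model, matrix(background, 1), tcol[i])
    fx <- logit_value(model, X[i, , drop = FALSE], tcol[i])
    s <- sample(sizes, n_samples, replace = TRUE, prob = size_w)
    Z <- matrix(0L, n_samples, p)
    for (r in seq_len(n_samples))
      Z[r, sample.int(p, s[r])] <- 1L
    Xp <- Z * matrix(X[i, ], n_samples, p, byrow = TRUE) +
      (1 - Z) * matrix(background, n_samples, p, byrow = TRUE)
    y <- logit_value(model, Xp, rep(tcol[i], n_samples)) - f0
    ## constrained WLS: min ||Z beta - y||_W  s.t.  sum(beta) = fx - f0.
    ## Coalitions of a given size share one kernel weight, already the
    ## sampling distribution, so the solve is uniform-weighted.
    A <- crossprod(Z) + ridge * diag(p)
    c0 <- crossprod(Z, y)
    Ainv_c <- solve(A, c0)
    Ainv_1 <- solve(A, rep(1, p))
    lambda <- (sum(Ainv_c) - (fx - f0)) / sum(Ainv_1)
    out[i, ] <- Ainv_c - lambda * Ainv_1
    base_vals[i] <- f0
  }
  attr(out, "base_value") <- base_vals
  out
}

#' Compute one attribution method over a sample set
#'
#' Uniform front-end for the seven methods; returns the per-sample,
#' per-feature score matrix with the method name and settings attached.
#'
#' @param model trained `ssae_model`.
#' @param X samples (rows) in the model's input space.
#' @param method one of "integrated_gradients", "lime", "shap", "deeplift",
#'   "deepliftshap", "gradientshap", "guided_backprop".
#' @param baselines baseline sample matrix for the *shap variants (defaults
#'   to a single all-zero row).
#' @param seed seed for the stochastic methods.
#' @param ... forwarded to the method.
#' @return object of class `attribution_matrix`.
#' @export
attribution_matrix <- function(model, X, method, baselines = NULL,
                               seed = 1L, ...) {
  X <- as_mat(X)
  if (is.null(baselines)) baselines <- matrix(0, 1, ncol(X))
  scores <- switch(
    method,
    integrated_gradients = integrated_gradients(model, X, ...),
    guided_backprop = guided_backprop(model, X, ...),
    deeplift = deeplift(model, X, ...),
    deepliftshap = deepliftshap(model, X, baselines, ...),
    gradientshap = gradientshap(model, X, baselines, seed = seed, ...),
    lime = lime_explain(model, X, seed = seed, ...),
    shap = shap_explain(model, X, seed = seed, ...),
    stop("unknown attribution method: ", method))
  if (!all(is.finite(scores))) stop("non-finite attribution scores")
  structure(scores, class = c("attribution_matrix", class(scores)),
            method = method, baseline_spec = "all-zero connectivity",
            seed = seed)
}

#' Rank features by aggregate attribution
#'
#' Cohort-level ranking from a per-sample score matrix: by default the mean
#' absolute score per feature ("mean_abs"); "signed_mean" ranks by the mean
#' signed score's magnitude.
#'
#' @param scores attribution matrix (samples x features).
#' @param aggregate "mean_abs" or "signed_mean".
#' @return data.frame (feature_index, score, rank) sorted by decreasing
#'   score; rank 1 = most important. Ties break by ascending feature index.
#' @export
rank_features <- function(scores, aggregate = c("mean_abs", "signed_mean")) {
  aggregate <- match.arg(aggregate)
  s <- if (aggregate == "mean_abs") colMeans(abs(scores))
       else abs(colMeans(scores))
  ord <- order(-s, seq_along(s))
  data.frame(feature_index = ord, score = s[ord],
             rank = seq_along(s))
}
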