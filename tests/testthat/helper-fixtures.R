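# Shared fixtures, computed lazily once per test session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# Default synthetic cohort (the study conditions), FD-filtered, with
# extracted Fisher-Z features. Used by the acceptance suite and the heavier
# property tests.
default_cohort_features <- function() {
  cached("default_fx", {
    coh <- filter_by_fd(generate_cohort(cohort_spec(seed = 11)))
    extract_features(coh)
  })
}

# Full cross-validated pipeline on the default cohort (per-fold RFE to 1000
# + SSAE at the published recipe).
default_cv <- function() {
  cached("default_cv", {
    fx <- default_cohort_features()
    run_cv(fx$features, fx$labels, ssae = ssae_config(seed = 5),
           rfe_k = 1000, n_folds = 5, seed = 2)
  })
}

# Fold-1 training data in the model's input space plus its IG attribution
# ranking (local = selected-subspace indices, original = 6670-space).
default_fold1_attr <- function() {
  cached("default_attr", {
    fx <- default_cohort_features()
    cv <- default_cv()
    f1 <- cv$folds[[1]]
    Xtr <- f1$scaler$apply(
      fx$features[f1$fold$train, , drop = FALSE])[, f1$selected,
                                                  drop = FALSE]
    ig <- attribution_matrix(f1$model, Xtr, "integrated_gradients",
                             n_steps = 100)
    rk <- rank_features(ig)
    rk_orig <- rk
    rk_orig$feature_index <- f1$selected[rk$feature_index]
    list(fold = f1, Xtr = Xtr, ig = ig, rank_local = rk,
         rank_original = rk_orig)
  })
}

# Small trained SSAE on a 12-feature separable problem, for attribution
# axiom checks where exhaustive/kernel estimators must be accurate.
small_trained_model <- function() {
  cached("small_model", {
    set.seed(2)
    n <- 120; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- factor(ifelse(X[, 1] + X[, 2] - X[, 3] + rnorm(n, 0, 0.3) > 0,
                       "case", "control"), levels = c("control", "case"))
    cfg <- ssae_config(input_dim = p, hidden1 = 8, hidden2 = 4,
                       pretrain_epochs = 100, finetune_epochs = 200,
                       finetune_lr = 1e-3, seed = 7)
    m <- ssae_finetune(ssae_pretrain(X, cfg), X, y, cfg)
    list(model = m, X = X, y = y, p = p)
  })
}

# An exactly affine "network": biases push every ReLU into its linear
# regime over the tested input range, so logit(class 1) = w.x + const.
linear_logit_model <- function(w = c(0.8, -0.5, 0.3, 1.1), big = 50) {
  p <- length(w)
  m <- list(W1 = diag(p), b1 = rep(big, p),
            W2 = diag(p), b2 = rep(big, p),
            W3 = cbind(w, -w), b3 = c(0, 0),
            classes = c("control", "case"))
  class(m) <- "ssae_model"
  m
}
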