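test_that("all gradient-based methods coincide exactly on a linear logit", {
  w <- c(0.8, -0.5, 0.3, 1.1)
  m <- linear_logit_model(w)
  x <- matrix(c(0.5, -1, 2, 0.3), 1)
  base <- matrix(0, 1, 4)
  ig <- integrated_gradients(m, x, n_steps = 50, target = 1)
  dl <- deeplift(m, x, target = 1)
  dls <- deepliftshap(m, x, baselines = base, target = 1)
  gs <- gradientshap(m, x, baselines = base, n_samples = 20, stdev = 0,
                     seed = 5, target = 1)
  expect_equal(ig, w * as.numeric(x), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(dl, ig, tolerance = 1e-12)
  expect_equal(dls, ig, tolerance = 1e-12)
  expect_equal(gs, ig, tolerance = 1e-12)
})

test_that("integrated gradients: zero at baseline, completeness on SSAE", {
  sm <- small_trained_model()
  x <- sm$X[3, , drop = FALSE]
  expect_equal(integrated_gradients(sm$model, matrix(0, 1, sm$p),
                                    n_steps = 10),
               matrix(0, 1, sm$p), ignore_attr = TRUE)
  fw <- ssae_forward(sm$model, x)
  tc <- which.max(fw$probs)
  delta <- fw$logits[, tc] -
    ssae_forward(sm$model, matrix(0, 1, sm$p))$logits[, tc]
  att <- integrated_gradients(sm$model, x, n_steps = 200, target = tc)
  expect_lt(abs(sum(att) - delta) / abs(delta), 0.01)
  expect_error(integrated_gradients(sm$model, x, n_steps = 0), "n_steps")
})

test_that("IG discretisation error shrinks with more steps", {
  sm <- small_trained_model()
  x <- sm$X[5, , drop = FALSE]
  fw <- ssae_forward(sm$model, x)
  tc <- which.max(fw$probs)
  delta <- fw$logits[, tc] -
    ssae_forward(sm$model, matrix(0, 1, sm$p))$logits[, tc]
  gaps <- vapply(c(10, 50, 200), function(ns)
    abs(sum(integrated_gradients(sm$model, x, n_steps = ns,
                                 target = tc)) - delta), 0)
  # non-increasing within tolerance, and small at 200 steps
  expect_true(all(diff(gaps) <= abs(delta) * 0.01 + 1e-10))
  expect_lt(gaps[3], abs(delta) * 0.01)
})

test_that("DeepLift satisfies summation-to-delta; single-baseline shap = base", {
  sm <- small_trained_model()
  X <- sm$X[1:5, ]
  fw <- ssae_forward(sm$model, X)
  tc <- max.col(fw$probs, ties.method = "first")
  f0 <- ssae_forward(sm$model, matrix(0, 1, sm$p))$logits
  dl <- deeplift(sm$model, X)
  deltas <- fw$logits[cbind(1:5, tc)] - f0[tc]
  expect_equal(rowSums(dl), deltas, tolerance = 1e-10)
  dls <- deepliftshap(sm$model, X,
                      baselines = matrix(0, 3, sm$p))  # repeated baseline
  expect_equal(dls, dl, tolerance = 1e-12)
  expect_error(deepliftshap(sm$model, X, baselines = matrix(0, 0, sm$p)),
               "at least one")
})

test_that("guided backprop obeys the positive-gradient ReLU rule", {
  # single ReLU with negative pre-activation blocks everything upstream
  m <- list(W1 = diag(2), b1 = c(-5, 0), W2 = diag(2), b2 = c(50, 50),
            W3 = cbind(c(1, 1), c(-1, -1)), b3 = c(0, 0),
            classes = c("a", "b"))
  class(m) <- "ssae_model"
  g <- guided_backprop(m, matrix(c(1, 1), 1), target = 1)
  expect_equal(g[1, 1], 0)  # unit 1 is off (1 - 5 < 0)
  expect_gt(g[1, 2], 0)
  # all-positive-weight network in the linear regime: equals the gradient
  set.seed(1)
  mp <- list(W1 = matrix(abs(rnorm(12)), 4, 3), b1 = rep(50, 3),
             W2 = matrix(abs(rnorm(6)), 3, 2), b2 = rep(50, 2),
             W3 = matrix(abs(rnorm(4)), 2, 2), b3 = c(0, 0),
             classes = c("a", "b"))
  class(mp) <- "ssae_model"
  xp <- matrix(rnorm(4), 1)
  expect_equal(guided_backprop(mp, xp, target = 1),
               fcxai:::logit_gradient(mp, xp, 1L), tolerance = 1e-12)
  sm <- small_trained_model()
  g100 <- guided_backprop(sm$model, sm$X[1:100, ])
  expect_true(all(is.finite(g100)))
})

test_that("kernel SHAP: local accuracy and additivity on a linear model", {
  sm <- small_trained_model()
  x <- sm$X[2, , drop = FALSE]
  fw <- ssae_forward(sm$model, x)
  tc <- which.max(fw$probs)
  f0 <- ssae_forward(sm$model, matrix(0, 1, sm$p))$logits[, tc]
  sh <- shap_explain(sm$model, x, n_samples = 1024, seed = 3, target = tc)
  fx <- fw$logits[, tc]
  expect_lt(abs(sum(sh) + f0 - fx) / abs(fx), 0.02)
  # additive (linear) model with zero background: shap_i = w_i x_i
  w <- c(0.8, -0.5, 0.3, 1.1)
  m <- linear_logit_model(w)
  xl <- matrix(c(0.5, -1, 2, 0.3), 1)
  shl <- shap_explain(m, xl, n_samples = 2000, seed = 4, target = 1)
  expect_equal(as.numeric(shl), w * as.numeric(xl), tolerance = 1e-6)
})

test_that("LIME and SHAP return zero for a constant model, LIME tracks a
           linear one", {
  sm <- small_trained_model()
  mc <- sm$model
  mc$W1[] <- 0; mc$W2[] <- 0; mc$W3[] <- 0
  x <- sm$X[1, , drop = FALSE]
  expect_lt(max(abs(lime_explain(mc, x, n_perturbations = 400, seed = 3))),
            1e-4)
  expect_equal(max(abs(shap_explain(mc, x, n_samples = 400, seed = 3))), 0)
  w <- c(0.8, -0.5, 0.3, 1.1)
  m <- linear_logit_model(w)
  xl <- matrix(c(0.5, -1, 2, 0.3), 1)
  lm <- lime_explain(m, xl, n_perturbations = 2000, seed = 6, target = 1)
  expect_gt(cor(as.numeric(lm), w * as.numeric(xl)), 0.99)
  expect_warning(lime_explain(sm$model, x, n_perturbations = 1, seed = 1),
                 "unstable")
})

test_that("stochastic methods are bit-reproducible at a fixed seed", {
  sm <- small_trained_model()
  x <- sm$X[4, , drop = FALSE]
  B <- sm$X[10:14, ]
  expect_identical(
    gradientshap(sm$model, x, B, n_samples = 10, seed = 7),
    gradientshap(sm$model, x, B, n_samples = 10, seed = 7))
  expect_identical(shap_explain(sm$model, x, n_samples = 128, seed = 7),
                   shap_explain(sm$model, x, n_samples = 128, seed = 7))
  expect_identical(
    lime_explain(sm$model, x, n_perturbations = 200, seed = 7),
    lime_explain(sm$model, x, n_perturbations = 200, seed = 7))
})

test_that("the attribution front-end runs every method and ranks features", {
  sm <- small_trained_model()
  X <- sm$X[1:4, ]
  for (meth in c("integrated_gradients", "guided_backprop", "deeplift",
                 "deepliftshap", "gradientshap", "lime", "shap")) {
    args <- list(sm$model, X, meth, seed = 2)
    if (meth == "integrated_gradients") args$n_steps <- 20
    if (meth == "lime") args$n_perturbations <- 300
    if (meth %in% c("shap", "gradientshap")) args$n_samples <- 200
    am <- do.call(attribution_matrix, args)
    expect_equal(dim(am), dim(X))
    expect_true(all(is.finite(am)))
    expect_identical(attr(am, "method"), meth)
  }
  expect_error(attribution_matrix(sm$model, X, "gradcam"), "unknown")
  rk <- rank_features(abs(matrix(c(1, 3, 2, 1, 3, 2), 2, byrow = TRUE)))
  expect_equal(rk$feature_index, c(2, 3, 1))
  expect_equal(rk$rank, 1:3)
})

test_that("IG ranking concentrates the planted features in the top decile", {
  fx <- default_cohort_features()
  at <- default_fold1_attr()
  pp <- default_planted_pairs()
  pidx <- mapply(function(i, j) {
    a <- max(i, j); b <- min(i, j); (a - 1) * (a - 2) / 2 + b
  }, pp$roi_i, pp$roi_j)
  sel_planted <- which(at$fold$selected %in% pidx)
  top_decile <- at$rank_local$feature_index[1:100]
  n_hit <- sum(top_decile %in% sel_planted)
  # chance expectation is length(sel_planted)/10; require > 3x enrichment
  expect_gt(n_hit, 0.3 * length(sel_planted))
})
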