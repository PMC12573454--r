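test_that("sparsity penalty is the Bernoulli KL with its closed form", {
  expect_equal(sparsity_penalty(rep(0.2, 5), 0.2), 0)
  # one unit, rho 0.2, rho_hat 0.5
  expect_equal(sparsity_penalty(0.5, 0.2),
               0.2 * log(0.4) + 0.8 * log(1.6), tolerance = 1e-12)
  expect_equal(sparsity_penalty(0.5, 0.2), 0.1927, tolerance = 5e-4)
  # convex in rho_hat with minimum at rho
  g <- seq(0.02, 0.98, by = 0.02)
  v <- vapply(g, sparsity_penalty, 0, rho = 0.2)
  expect_true(all(v >= 0))
  expect_equal(g[which.min(v)], 0.2)
  expect_true(all(diff(v, differences = 2) > -1e-12))
  # boundary activations are clipped, never NaN
  expect_true(is.finite(sparsity_penalty(c(0, 1), 0.2)))
})

test_that("ae_loss combines MSE and the weighted penalty", {
  cfg <- ssae_config(input_dim = 10, hidden1 = 4, hidden2 = 2, beta = 2)
  expect_equal(ae_loss(c(1, 2), c(1, 2), rep(0.2, 4), cfg), 0)
  expect_equal(ae_loss(c(1, 0), c(0, 0), rep(0.2, 4), cfg), 0.5)
  cfg0 <- ssae_config(input_dim = 10, hidden1 = 4, hidden2 = 2, beta = 0)
  expect_equal(ae_loss(c(1, 0), c(0, 0), rep(0.9, 4), cfg0), 0.5)
  expect_error(ae_loss(1:3, 1:2, 0.2, cfg), "equal shape")
})

test_that("greedy pre-training reduces reconstruction loss, reproducibly", {
  set.seed(10)
  X <- scale(matrix(rnorm(150 * 30), 150, 30))
  cfg <- ssae_config(input_dim = 30, hidden1 = 12, hidden2 = 5,
                     pretrain_epochs = 40, seed = 3)
  pre <- ssae_pretrain(X, cfg)
  h1 <- pre$history[pre$history$stage == "AE1", ]
  h2 <- pre$history[pre$history$stage == "AE2", ]
  expect_lt(tail(h1$loss, 1), h1$loss[1])
  expect_lt(tail(h2$loss, 1), h2$loss[1])
  pre2 <- ssae_pretrain(X, cfg)
  expect_equal(tail(pre2$history$loss, 1), tail(pre$history$loss, 1),
               tolerance = 1e-4)
})

test_that("large beta drives mean activations to the sparsity target", {
  set.seed(4)
  X <- scale(matrix(rnorm(200 * 60), 200, 60))
  cfg <- ssae_config(input_dim = 60, hidden1 = 30, hidden2 = 10,
                     beta = 50, pretrain_epochs = 2000, seed = 9)
  pre <- ssae_pretrain(X, cfg)
  expect_lt(abs(mean(pre$rho_hat1) - 0.2), 0.05)
})

test_that("sparsity pressure is monotone in beta", {
  set.seed(4)
  X <- scale(matrix(rnorm(200 * 60), 200, 60))
  dev <- vapply(c(0, 2, 20), function(b) {
    cfg <- ssae_config(input_dim = 60, hidden1 = 30, hidden2 = 10,
                       beta = b, pretrain_epochs = 400, seed = 9)
    mean(abs(ssae_pretrain(X, cfg)$rho_hat1 - 0.2))
  }, 0)
  expect_true(all(diff(dev) <= 1e-6))
})

test_that("both rho_hat modes train and stay finite", {
  set.seed(5)
  X <- scale(matrix(rnorm(100 * 20), 100, 20))
  for (mode in c("sigmoid", "relu_clip")) {
    cfg <- ssae_config(input_dim = 20, hidden1 = 8, hidden2 = 3,
                       pretrain_epochs = 20, rho_hat_mode = mode, seed = 2)
    pre <- ssae_pretrain(X, cfg)
    expect_true(all(is.finite(pre$history$loss)))
    expect_true(all(pre$rho_hat1 >= 0 & pre$rho_hat1 <= 1))
  }
})

test_that("fine-tuning fits separable data and outputs proper probabilities", {
  set.seed(6)
  n <- 100; p <- 16
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  X[y == "case", 1:3] <- X[y == "case", 1:3] + 3
  cfg <- ssae_config(input_dim = p, hidden1 = 8, hidden2 = 4,
                     pretrain_epochs = 50, finetune_epochs = 50,
                     finetune_lr = 1e-2, seed = 8)
  m <- ssae_finetune(ssae_pretrain(X, cfg), X, y, cfg)
  expect_equal(tail(m$history$train_acc, 1), 1.0)
  P <- predict(m, X, type = "prob")
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_equal(colnames(P), c("control", "case"))
})

test_that("validation loss shows no sustained divergence on cohort data", {
  cv <- default_cv()
  for (f in cv$folds) {
    vl <- f$model$history$val_loss
    expect_lte(tail(vl, 1), 1.2 * min(vl))
  }
})

test_that("pre-training speeds up fine-tuning relative to random init", {
  set.seed(12)
  n <- 160; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  X[y == "case", 1:6] <- X[y == "case", 1:6] + 0.9
  tr <- c(1:60, 81:140); va <- c(61:80, 141:160)
  epochs_to <- function(hist, acc = 0.85) {
    w <- which(hist$val_acc >= acc)
    if (length(w)) w[1] else nrow(hist) + 1
  }
  res <- vapply(1:5, function(s) {
    cfg <- ssae_config(input_dim = p, hidden1 = 16, hidden2 = 6,
                       pretrain_epochs = 60, finetune_epochs = 60,
                       finetune_lr = 3e-4, seed = 100 + s)
    pre <- ssae_pretrain(X[tr, ], cfg)
    mp <- ssae_finetune(pre, X[tr, ], y[tr], cfg, X[va, ], y[va])
    mr <- ssae_finetune(NULL, X[tr, ], y[tr], cfg, X[va, ], y[va])
    c(pre = epochs_to(mp$history), rand = epochs_to(mr$history))
  }, c(pre = 0, rand = 0))
  expect_lte(mean(res["pre", ]), mean(res["rand", ]))
})

test_that("config invariants are enforced", {
  expect_error(ssae_config(input_dim = 10, hidden1 = 12, hidden2 = 4),
               "hidden2 < hidden1 < input_dim")
  expect_error(ssae_config(rho = 1.5), "rho")
  expect_error(ssae_config(pretrain_lr = 0), "learning rates")
})
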