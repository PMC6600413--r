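# RBM core: sigmoid, energy, conditionals vs enumeration, CD-1, training,
# and the exact-gradient oracle itself.

test_that("sigmoid matches its closed form and stays stable at extremes", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.8807971, tolerance = 1e-7)
  x <- seq(-30, 30, length.out = 101)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 101))
  expect_equal(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 0)
})

test_that("energy evaluates the bilinear form and is linear in parameters", {
  p <- rbm_params(1, 1, W = matrix(2), a = 0.5, b = 0.3)
  expect_equal(rbm_energy(p, 1, 1), -2.8)

  zero <- rbm_params(3, 2, W = matrix(0, 3, 2), a = numeric(3), b = numeric(2))
  expect_equal(rbm_energy(zero, runif(3), runif(2)), 0)

  set.seed(1)
  p1 <- random_rbm(3, 2); p2 <- random_rbm(3, 2)
  v <- runif(3); h <- runif(2)
  expect_equal(rbm_energy(p1, rep(0, 3), h), -sum(p1$b * h))
  # superposition: E is linear in (W, a, b) jointly
  psum <- rbm_params(3, 2, W = p1$W + p2$W, a = p1$a + p2$a, b = p1$b + p2$b)
  expect_equal(rbm_energy(psum, v, h),
               rbm_energy(p1, v, h) + rbm_energy(p2, v, h))
  expect_error(rbm_energy(p1, runif(2), h), "mismatch")
})

test_that("conditional probabilities match Boltzmann enumeration (n, m <= 3)", {
  set.seed(20)
  max_err <- 0
  for (draw in 1:50) {
    n <- sample(1:3, 1); m <- sample(1:3, 1)
    p <- random_rbm(n, m, scale = 1.5)
    v <- sample(c(0, 1), n, replace = TRUE)
    h <- sample(c(0, 1), m, replace = TRUE)
    max_err <- max(max_err,
      abs(hidden_probs(p, v) - oracle_hidden_conditional(p$W, p$a, p$b, v)),
      abs(visible_probs(p, h) - oracle_visible_conditional(p$W, p$a, p$b, h)))
  }
  expect_lt(max_err, 1e-10)
})

test_that("zero-parameter RBM gives 0.5 everywhere and batches work", {
  p <- rbm_params(4, 3, W = matrix(0, 4, 3), a = numeric(4), b = numeric(3))
  expect_equal(hidden_probs(p, runif(4)), rep(0.5, 3))
  expect_equal(visible_probs(p, runif(3)), rep(0.5, 4))
  B <- matrix(runif(8), 2, 4)
  expect_equal(dim(hidden_probs(p, B)), c(2L, 3L))
})

test_that("visible_probs equals hidden_probs of the transposed RBM", {
  set.seed(7)
  p <- random_rbm(4, 3)
  tp <- rbm_params(3, 4, W = t(p$W), a = p$b, b = p$a)
  h <- runif(3)
  expect_equal(visible_probs(p, h), hidden_probs(tp, h))
})

test_that("hidden activation is monotone in a positively-weighted input", {
  p <- rbm_params(2, 1, W = matrix(c(1.3, 0.2), 2, 1), a = numeric(2), b = 0.1)
  v_lo <- c(0.2, 0.5); v_hi <- c(0.9, 0.5)
  expect_gt(hidden_probs(p, v_hi), hidden_probs(p, v_lo))
})

test_that("sample_bernoulli hits its degenerate and statistical bounds", {
  expect_equal(sample_bernoulli(rep(0, 10)), rep(0, 10))
  expect_equal(sample_bernoulli(rep(1, 10)), rep(1, 10))
  expect_error(sample_bernoulli(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(123)
  draws <- sample_bernoulli(rep(0.3, 10000))
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
})

test_that("CD update scales with the learning rate and vanishes at a fixed point", {
  set.seed(5)
  p <- random_rbm(3, 2, scale = 0.3)
  batch <- matrix(sample(c(0, 1), 30, replace = TRUE), 10, 3)
  upd0 <- cd_k_update(p, batch, cd_config(learning_rate = 0, dropout_rate = 0))
  expect_equal(upd0$dW, matrix(0, 3, 2))
  expect_equal(upd0$da, rep(0, 3))
  expect_equal(upd0$db, rep(0, 2))

  # saturated RBM that reproduces an all-ones batch exactly
  sat <- rbm_params(2, 2, W = matrix(0, 2, 2),
                    a = rep(50, 2), b = rep(50, 2))
  ones <- matrix(1, 5, 2)
  upd <- cd_k_update(sat, ones, cd_config(learning_rate = 0.1, dropout_rate = 0))
  expect_equal(max(abs(c(upd$dW, upd$da, upd$db))), 0, tolerance = 1e-12)

  expect_error(cd_k_update(p, matrix(numeric(0), 0, 3), cd_config()),
               "non-empty")
})

test_that("averaged CD-1 update aligns with the exact log-likelihood gradient", {
  set.seed(31)
  p <- random_rbm(3, 2, scale = 0.1)
  batch <- matrix(sample(c(0, 1), 60, replace = TRUE, prob = c(0.4, 0.6)),
                  20, 3)
  exact <- exact_loglik_grad(p, batch)
  config <- cd_config(learning_rate = 1, dropout_rate = 0)
  acc <- numeric(3 * 2 + 3 + 2)
  set.seed(77)
  for (i in 1:10000) {
    upd <- cd_k_update(p, batch, config)
    acc <- acc + c(as.numeric(upd$dW), upd$da, upd$db)
  }
  acc <- acc / 10000
  expect_gt(cosine_sim(acc, c(as.numeric(exact$dW), exact$da, exact$db)), 0.9)
})

test_that("exact_loglik_grad matches finite differences of the enumerated likelihood", {
  set.seed(13)
  p <- random_rbm(3, 2, scale = 0.8)
  data <- matrix(sample(c(0, 1), 15, replace = TRUE), 5, 3)
  exact <- exact_loglik_grad(p, data)

  theta <- c(as.numeric(p$W), p$a, p$b)
  fn <- function(th) {
    oracle_loglik(matrix(th[1:6], 3, 2), th[7:9], th[10:11], data)
  }
  fd <- finite_diff(fn, theta)
  expect_equal(c(as.numeric(exact$dW), exact$da, exact$db), fd,
               tolerance = 1e-6)
  # the enumerated log-likelihood itself agrees with the oracle
  expect_equal(exact$loglik, fn(theta), tolerance = 1e-10)
})

test_that("zero-weight RBM has the closed-form visible-bias gradient", {
  p <- rbm_params(4, 2, W = matrix(0, 4, 2), a = numeric(4), b = numeric(2))
  data <- matrix(runif(20), 5, 4)
  exact <- exact_loglik_grad(p, data)
  expect_equal(exact$da, colMeans(data) - 0.5)
  expect_error(exact_loglik_grad(random_rbm(13, 2), matrix(0.5, 1, 13)),
               "<= 12")
})

test_that("a fitted 1x1 RBM is a stationary point of the likelihood", {
  # one visible, one hidden, data mean 0.75; fit by coarse optimisation
  data <- matrix(c(1, 1, 1, 0), 4, 1)
  obj <- function(th) -oracle_loglik(matrix(th[1]), th[2], th[3], data)
  fit <- optim(c(0, 0, 0), obj, method = "BFGS")
  p <- rbm_params(1, 1, W = matrix(fit$par[1]), a = fit$par[2], b = fit$par[3])
  g <- exact_loglik_grad(p, data)
  expect_lt(max(abs(c(g$dW, g$da, g$db))), 1e-4)
})

test_that("train_rbm is seeded, honours epochs = 0, and reduces reconstruction error", {
  set.seed(1)
  data <- matrix(runif(60), 10, 6)
  f0 <- train_rbm(data, 3, cd_config(epochs = 0, seed = 4))
  expect_equal(nrow(f0$trace), 0L)
  f0b <- train_rbm(data, 3, cd_config(epochs = 0, seed = 4))
  expect_identical(f0$params, f0b$params)

  f1 <- train_rbm(data, 3, cd_config(epochs = 10, seed = 4, dropout_rate = 0.2))
  f2 <- train_rbm(data, 3, cd_config(epochs = 10, seed = 4, dropout_rate = 0.2))
  expect_identical(f1$params, f2$params)
  expect_equal(nrow(f1$trace), 10L)

  # planted correlation structure: blocks of correlated variables
  set.seed(8)
  latent <- matrix(runif(200 * 3), 200, 3)
  corr_data <- sigmoid(latent[, rep(1:3, each = 10)] * 4 - 2 +
                         matrix(rnorm(200 * 30, sd = 0.3), 200, 30))
  fit <- train_rbm(corr_data, 8,
                   cd_config(epochs = 60, learning_rate = 0.05,
                             dropout_rate = 0, seed = 2))
  expect_lt(fit$trace$recon_mse[60], fit$trace$recon_mse[1])
  expect_error(train_rbm(corr_data, 0, cd_config()), ">= 1")
})
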