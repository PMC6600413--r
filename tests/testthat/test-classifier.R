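# Softmax head, end-to-end cost/gradient, fine-tuning by GD and L-BFGS.

test_that("softmax probabilities are uniform at zero parameters and normalised", {
  p <- list(W = matrix(0, 3, 4), b = numeric(3))
  F <- matrix(runif(8), 2, 4)
  expect_equal(softmax_probs(p, F), matrix(1 / 3, 2, 3))

  set.seed(1)
  p2 <- list(W = matrix(rnorm(12), 3, 4), b = rnorm(3))
  P <- softmax_probs(p2, matrix(rnorm(40, sd = 5), 10, 4))
  expect_equal(rowSums(P), rep(1, 10))
  expect_true(all(P >= 0))
})

test_that("two-class softmax reduces to the logistic sigmoid of the logit gap", {
  set.seed(2)
  W <- matrix(rnorm(6), 2, 3); b <- rnorm(2)
  F <- matrix(rnorm(15), 5, 3)
  P <- softmax_probs(list(W = W, b = b), F)
  gap <- F %*% (W[1, ] - W[2, ]) + (b[1] - b[2])
  expect_equal(P[, 1], as.numeric(sigmoid(gap)))
})

test_that("analytic gradient matches finite differences across architectures", {
  set.seed(3)
  cases <- list(list(sizes = c(5, 4, 3), k = 2),
                list(sizes = c(4, 3), k = 3),
                list(sizes = c(6, 5, 3, 2), k = 3),
                list(sizes = c(3, 2), k = 2))
  for (case in cases) {
    sizes <- case$sizes; k <- case$k
    dbn <- structure(list(
      layer_sizes = as.integer(sizes),
      rbms = lapply(seq_len(length(sizes) - 1),
                    function(l) random_rbm(sizes[l], sizes[l + 1], 0.4)),
      traces = NULL), class = "dbn_model")
    model <- make_test_model(dbn, k)
    n <- 7
    X <- matrix(runif(n * sizes[1]), n, sizes[1])
    Y <- one_hot(sample(LETTERS[1:k], n, replace = TRUE, prob = rep(1, k)),
                 LETTERS[1:k])
    masks <- lapply(sizes[-1], function(m) rbinom(m, 1, 0.7))

    res <- cost_and_grad(model, X, Y, lambda = 0.01, dropout_masks = masks)
    layers <- lapply(dbn$rbms, function(r) list(W = r$W, b = r$b))
    shapes <- metabodbn:::net_shapes(layers, model$softmax)
    theta <- metabodbn:::flatten_net(layers, model$softmax)
    fn <- function(th) metabodbn:::net_cost_grad(th, shapes, X, Y, 0.01,
                                                 masks = masks)$cost
    fd <- finite_diff(fn, theta)
    rel <- sqrt(sum((res$grad - fd)^2)) / sqrt(sum(fd^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("perfectly confident correct predictions give zero cost at lambda 0", {
  # huge logits -> probabilities numerically one-hot
  dbn <- structure(list(
    layer_sizes = c(2L, 2L),
    rbms = list(rbm_params(2, 2, W = matrix(0, 2, 2),
                           a = numeric(2), b = numeric(2))),
    traces = NULL), class = "dbn_model")
  model <- make_test_model(dbn, 2)
  model$softmax <- list(W = matrix(c(1000, -1000, 1000, -1000), 2, 2),
                        b = c(0, 0))
  X <- matrix(c(0.9, 0.1), 1, 2)   # hidden activations are (0.5, 0.5)
  # craft targets from the model's own argmax so the prediction is "correct"
  P <- softmax_probs(model$softmax,
                     dbn_forward(dbn, X))
  Y <- matrix(as.numeric(P > 0.5), 1, 2)
  res <- cost_and_grad(model, X, Y, lambda = 0)
  expect_equal(res$cost, 0, tolerance = 1e-10)
  expect_error(cost_and_grad(model, X, matrix(c(0.5, 0.5), 1, 2), lambda = 0),
               "one-hot")
})

test_that("the weight-decay term is linear in lambda", {
  set.seed(4)
  dbn <- structure(list(layer_sizes = c(3L, 2L),
                        rbms = list(random_rbm(3, 2)), traces = NULL),
                   class = "dbn_model")
  model <- make_test_model(dbn, 2)
  X <- matrix(runif(12), 4, 3)
  Y <- one_hot(sample(c("A", "B"), 4, replace = TRUE), c("A", "B"))
  c0 <- cost_and_grad(model, X, Y, lambda = 0)$cost
  c1 <- cost_and_grad(model, X, Y, lambda = 0.1)$cost
  c2 <- cost_and_grad(model, X, Y, lambda = 0.2)$cost
  sumsq <- sum(dbn$rbms[[1]]$W^2) + sum(model$softmax$W^2)
  expect_equal(c1 - c0, 0.05 * sumsq)
  expect_equal(c2 - c1, c1 - c0)
})

test_that("softmax head training separates a separable toy and is seeded", {
  set.seed(5)
  F <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
             matrix(rnorm(40, mean = -2), 20, 2))
  y <- rep(c("A", "B"), each = 20)
  Y <- one_hot(y, c("A", "B"))
  head1 <- train_softmax_head(F, Y, lambda = 0, iterations = 200, seed = 1)
  pred <- c("A", "B")[max.col(softmax_probs(head1, F), ties.method = "first")]
  expect_equal(accuracy_percent(pred, y), 100)

  head2 <- train_softmax_head(F, Y, lambda = 0, iterations = 200, seed = 1)
  expect_identical(head1, head2)

  zero <- train_softmax_head(F, Y, iterations = 0)
  expect_equal(zero$W, matrix(0, 2, 2))
  expect_error(train_softmax_head(F, one_hot(rep("A", 40), c("A", "B"))),
               "Degenerate")
})

fit_toy_model <- function(X, y, hidden = c(6, 4), seed = 11) {
  dbn <- dbn_pretrain(X, c(ncol(X), hidden),
                      cd_config(epochs = 10, seed = seed, dropout_rate = 0))
  model <- make_test_model(dbn, length(unique(y)))
  model$class_order <- sort(unique(y))
  model$softmax <- train_softmax_head(dbn_forward(dbn, X),
                                      one_hot(y, model$class_order),
                                      iterations = 20, seed = seed)
  model
}

toy_training_setup <- function(seed = 31, n_per = 12, p = 20) {
  peaks <- toy_peaks(n_per_class = n_per, p = p, seed = seed)
  parts <- metabodbn:::peaks_split(peaks, "group")
  st <- fit_normalizer(peaks)
  X <- metabodbn:::normalize_matrix(parts$X, st)
  list(X = X, y = parts$labels, Y = one_hot(parts$labels))
}

test_that("finetune bookkeeping: zero iterations, trace lengths, thinning", {
  setup <- toy_training_setup()
  model <- fit_toy_model(setup$X, setup$y)
  r0 <- finetune(model, setup$X, setup$Y,
                 config = finetune_config(iterations = 0, dropout_rate = 0))
  expect_equal(nrow(r0$trace), 0L)
  expect_identical(metabodbn:::flatten_net(metabodbn:::dbn_layers(r0$model$dbn),
                                           r0$model$softmax),
                   metabodbn:::flatten_net(metabodbn:::dbn_layers(model$dbn),
                                           model$softmax))

  r <- finetune(model, setup$X, setup$Y,
                config = finetune_config(method = "gd", iterations = 7,
                                         dropout_rate = 0))
  expect_equal(r$trace$iteration, 1:7)
  expect_true(all(r$trace$fmr >= 0 & r$trace$fmr <= 1))
  expect_true(all(is.na(r$trace$tmr)))

  thin <- finetune(model, setup$X, setup$Y,
                   config = finetune_config(method = "gd", iterations = 10,
                                            dropout_rate = 0, trace_every = 4))
  expect_equal(thin$trace$iteration, c(4L, 8L, 10L))
})

test_that("small-step GD descends monotonically with dropout off", {
  setup <- toy_training_setup()
  model <- fit_toy_model(setup$X, setup$y)
  r <- finetune(model, setup$X, setup$Y,
                config = finetune_config(method = "gd", iterations = 40,
                                         learning_rate = 0.02,
                                         weight_decay = 1e-4,
                                         dropout_rate = 0))
  expect_true(all(diff(r$trace$cost) <= 1e-12))
})

test_that("L-BFGS reaches a cost no worse than GD at the same iteration cap", {
  setup <- toy_training_setup(seed = 17)
  model <- fit_toy_model(setup$X, setup$y)
  cap <- 60
  gd <- finetune(model, setup$X, setup$Y,
                 config = finetune_config(method = "gd", iterations = cap,
                                          dropout_rate = 0))
  lb <- finetune(model, setup$X, setup$Y,
                 config = finetune_config(method = "lbfgs", iterations = cap,
                                          dropout_rate = 0))
  expect_lte(min(lb$trace$cost), min(gd$trace$cost))
})

test_that("in-package L-BFGS agrees with optim's L-BFGS-B optimum", {
  setup <- toy_training_setup(seed = 23, n_per = 8, p = 12)
  model <- fit_toy_model(setup$X, setup$y, hidden = c(5, 3))
  layers <- metabodbn:::dbn_layers(model$dbn)
  shapes <- metabodbn:::net_shapes(layers, model$softmax)
  theta0 <- metabodbn:::flatten_net(layers, model$softmax)
  lambda <- 1e-3

  lb <- finetune(model, setup$X, setup$Y,
                 config = finetune_config(method = "lbfgs", iterations = 150,
                                          weight_decay = lambda,
                                          dropout_rate = 0))
  ref <- optim(theta0,
               fn = function(th) metabodbn:::net_cost_grad(th, shapes, setup$X,
                                                           setup$Y, lambda)$cost,
               gr = function(th) metabodbn:::net_cost_grad(th, shapes, setup$X,
                                                           setup$Y, lambda)$grad,
               method = "L-BFGS-B", control = list(maxit = 500))
  expect_lt(abs(min(lb$trace$cost) - ref$value), 0.05)
})

test_that("test data shapes the TMR trace but never the parameters", {
  setup <- toy_training_setup(seed = 41)
  model <- fit_toy_model(setup$X, setup$y)
  n_test <- 9
  X_test <- setup$X[1:n_test, , drop = FALSE]
  Y_good <- setup$Y[1:n_test, , drop = FALSE]
  Y_bad <- Y_good[, c(2, 3, 1)]   # corrupted test labels
  colnames(Y_bad) <- colnames(Y_good)

  config <- finetune_config(method = "lbfgs", iterations = 20,
                            dropout_rate = 0.3, seed = 5)
  r1 <- finetune(model, setup$X, setup$Y, X_test, Y_good, config)
  r2 <- finetune(model, setup$X, setup$Y, X_test, Y_bad, config)
  expect_identical(
    metabodbn:::flatten_net(metabodbn:::dbn_layers(r1$model$dbn), r1$model$softmax),
    metabodbn:::flatten_net(metabodbn:::dbn_layers(r2$model$dbn), r2$model$softmax))
  expect_false(identical(r1$trace$tmr, r2$trace$tmr))
})

test_that("prediction follows the argmax with first-class tie-breaking", {
  dbn <- structure(list(layer_sizes = c(2L, 2L),
                        rbms = list(rbm_params(2, 2, W = matrix(0, 2, 2),
                                               a = numeric(2), b = numeric(2))),
                        traces = NULL), class = "dbn_model")
  model <- make_test_model(dbn, 3)
  model$class_order <- c("CG", "MG", "RG")
  model$softmax <- list(W = matrix(0, 3, 2), b = numeric(3))
  model$normalizer <- structure(list(min = c(v1 = 0, v2 = 0),
                                     max = c(v1 = 1, v2 = 1),
                                     variable_ids = c("v1", "v2"),
                                     fitted_on_n = 2L),
                                class = "minmax_normalizer")
  model$dropout_rate <- 0
  X <- matrix(runif(6), 3, 2, dimnames = list(NULL, c("v1", "v2")))
  # uniform probabilities -> earliest class for every sample
  expect_equal(metabodbn:::mdbn_predict_matrix(model, X), rep("CG", 3))

  set.seed(8)
  model$softmax <- list(W = matrix(rnorm(6), 3, 2), b = rnorm(3))
  P <- metabodbn:::mdbn_predict_matrix(model, X, type = "prob")
  manual <- model$class_order[apply(P, 1, which.max)]
  expect_equal(metabodbn:::mdbn_predict_matrix(model, X), manual)
  expect_equal(metabodbn:::mdbn_predict_matrix(model, X),
               metabodbn:::mdbn_predict_matrix(model, X))
})

test_that("a seeded end-to-end fit is bit-reproducible", {
  peaks <- toy_peaks(n_per_class = 8, p = 16, seed = 3)
  spec <- mdbn_spec(hidden = c(6, 3), pretrain_epochs = 8,
                    finetune_iterations = 15)
  f1 <- mdbn(peaks, spec, seed = 99)
  f2 <- mdbn(peaks, spec, seed = 99)
  expect_identical(f1$softmax, f2$softmax)
  expect_identical(f1$dbn$rbms, f2$dbn$rbms)
  expect_identical(f1$trace, f2$trace)
})

test_that("models survive a JSON serialisation round trip", {
  peaks <- toy_peaks(n_per_class = 6, p = 10, seed = 13)
  fit <- mdbn(peaks, mdbn_spec(hidden = c(4), pretrain_epochs = 5,
                               finetune_iterations = 10), seed = 1)
  tf <- withr::local_tempfile(fileext = ".json")
  write_mdbn(fit, tf)
  back <- read_mdbn(tf)
  expect_equal(back$softmax$W, fit$softmax$W)
  expect_equal(predict(back, peaks)$.pred_class,
               predict(fit, peaks)$.pred_class)
})
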