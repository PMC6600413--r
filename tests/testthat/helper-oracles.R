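# Independent brute-force oracles used across the suite. These deliberately
# use explicit loops over enumerated joint states and never call the
# package's sigmoid/energy code paths.

# P(h_j = 1 | v) by enumerating every hidden configuration of the Boltzmann
# distribution exp(-E(v, h)) / Z_v.
oracle_hidden_conditional <- function(W, a, b, v) {
  m <- length(b)
  hs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  un <- apply(hs, 1, function(h) {
    exp(sum(a * v) + sum(b * h) + sum(outer(v, h) * W))
  })
  sapply(seq_len(m), function(j) sum(un[hs[, j] == 1]) / sum(un))
}

# P(v_i = 1 | h) by enumerating every visible configuration.
oracle_visible_conditional <- function(W, a, b, h) {
  n <- length(a)
  vs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  un <- apply(vs, 1, function(v) {
    exp(sum(a * v) + sum(b * h) + sum(outer(v, h) * W))
  })
  sapply(seq_len(n), function(i) sum(un[vs[, i] == 1]) / sum(un))
}

# Mean log-likelihood of binary rows under the RBM, by full joint enumeration.
oracle_loglik <- function(W, a, b, data) {
  n <- length(a); m <- length(b)
  vs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  hs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  joint <- function(v) {
    sum(apply(hs, 1, function(h) {
      exp(sum(a * v) + sum(b * h) + sum(outer(v, h) * W))
    }))
  }
  Z <- sum(apply(vs, 1, joint))
  mean(apply(data, 1, function(v) log(joint(v) / Z)))
}

# Central finite differences of a scalar function of a flat vector.
finite_diff <- function(fn, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    (fn(up) - fn(dn)) / (2 * h)
  }, numeric(1))
}

cosine_sim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

random_rbm <- function(n, m, scale = 0.5) {
  rbm_params(n, m,
             W = matrix(rnorm(n * m, sd = scale), n, m),
             a = rnorm(n, sd = scale), b = rnorm(m, sd = scale))
}

# Small labelled peaks tibble used by classifier/evaluation tests.
toy_peaks <- function(n_per_class = 10, p = 30, effect = 2, seed = 42) {
  generate_peaks(synthetic_config(
    n_per_class = n_per_class, n_variables = p,
    n_informative = max(4, round(p / 4)), effect_size = effect,
    sparsity = 0.2, seed = seed))
}

# A zero-initialised mdbn shell around a pretrained DBN, for gradient tests.
make_test_model <- function(dbn, k, dropout_rate = 0) {
  f <- dbn$layer_sizes[length(dbn$layer_sizes)]
  structure(list(dbn = dbn,
                 softmax = list(W = matrix(rnorm(k * f, sd = 0.1), k, f),
                                b = rnorm(k, sd = 0.1)),
                 dropout_rate = dropout_rate,
                 class_order = LETTERS[seq_len(k)],
                 normalizer = NULL, spec = mdbn_spec(), trace = NULL),
            class = "mdbn")
}
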