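# Restricted Boltzmann machine core: energy, conditionals, CD-K updates,
# epoch training, and an exact-gradient oracle by state enumeration.

#' Numerically stable logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, elementwise, stable for |x| up to ~700.
#'
#' @param x Numeric vector, matrix, or scalar.
#' @return Values in (0, 1) with the shape of `x`.
#' @export
sigmoid <- function(x) {
  # plogis is the stable closed form of 1/(1+exp(-x))
  out <- stats::plogis(x)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Construct RBM parameters
#'
#' An RBM over `n` visible and `m` hidden units is parameterised by
#' `theta = {W, a, b}`: an `n x m` weight matrix, visible biases `a`
#' (length `n`) and hidden biases `b` (length `m`). Weights are initialised
#' from a zero-mean Gaussian with standard deviation `init_scale`; biases
#' start at zero.
#'
#' @param n_visible,n_hidden Layer sizes.
#' @param init_scale Standard deviation of the Gaussian weight initialiser.
#' @param W,a,b Optional explicit parameter values (bypass the initialiser).
#' @return An object of class `rbm_params`.
#' @export
rbm_params <- function(n_visible, n_hidden, init_scale = 0.01,
                       W = NULL, a = NULL, b = NULL) {
  if (n_hidden < 1L || n_visible < 1L) abort("Layer sizes must be >= 1.")
  W <- W %||% matrix(rnorm(n_visible * n_hidden, sd = init_scale),
                     n_visible, n_hidden)
  a <- a %||% numeric(n_visible)
  b <- b %||% numeric(n_hidden)
  if (!all(is.finite(W)) || !all(is.finite(a)) || !all(is.finite(b))) {
    abort("RBM parameters must be finite.")
  }
  if (nrow(W) != length(a) || ncol(W) != length(b)) {
    abort("Inconsistent RBM parameter shapes.")
  }
  structure(list(W = W, a = a, b = b), class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("<rbm_params> %d visible x %d hidden\n", nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' RBM energy of a joint state
#'
#' `E(v, h) = -sum_i a_i v_i - sum_j b_j h_j - sum_ij v_i W_ij h_j`.
#' The Boltzmann distribution of the RBM is `P(v, h) proportional to
#' exp(-E(v, h))`.
#'
#' @param params An `rbm_params`.
#' @param v Visible state vector (length n, values in `[0, 1]`).
#' @param h Hidden state vector (length m).
#' @return The scalar energy.
#' @export
rbm_energy <- function(params, v, h) {
  if (length(v) != length(params$a) || length(h) != length(params$b)) {
    abort("Dimension mismatch between states and RBM parameters.")
  }
  -sum(params$a * v) - sum(params$b * h) -
    as.numeric(crossprod(v, params$W %*% h))
}

as_batch <- function(x, width) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L, ncol = width)
}

#' Hidden-unit activation probabilities
#'
#' `P(h_j = 1 | v) = sigmoid(b_j + sum_i v_i W_ij)`, the conditional of the
#' Boltzmann distribution given the visible state; also the deterministic
#' feed-forward activation used when stacking RBMs.
#'
#' @param params An `rbm_params`.
#' @param v Visible vector (length n) or batch matrix (rows = samples).
#' @return Probability vector of length m, or a batch matrix.
#' @export
hidden_probs <- function(params, v) {
  V <- as_batch(v, length(params$a))
  if (ncol(V) != nrow(params$W)) {
    abort(sprintf("Visible dimension mismatch: got %d, RBM has %d.",
                  ncol(V), nrow(params$W)))
  }
  P <- sigmoid(sweep(V %*% params$W, 2, params$b, "+"))
  if (is.matrix(v)) P else drop(P)
}

#' Visible-unit reconstruction probabilities
#'
#' `P(v_i = 1 | h) = sigmoid(a_i + sum_j W_ij h_j)`; the mirror of
#' [hidden_probs()] under the transposed RBM.
#'
#' @param params An `rbm_params`.
#' @param h Hidden vector (length m) or batch matrix.
#' @return Probability vector of length n, or a batch matrix.
#' @export
visible_probs <- function(params, h) {
  H <- as_batch(h, length(params$b))
  if (ncol(H) != ncol(params$W)) {
    abort(sprintf("Hidden dimension mismatch: got %d, RBM has %d.",
                  ncol(H), ncol(params$W)))
  }
  P <- sigmoid(sweep(tcrossprod(H, params$W), 2, params$a, "+"))
  if (is.matrix(h)) P else drop(P)
}

#' Independent Bernoulli draws
#'
#' Draws 0/1 values with the given success probabilities, consuming the
#' global RNG stream (seed it with `set.seed()` for reproducibility).
#'
#' @param p Probability vector or matrix, entries in `[0, 1]`.
#' @return 0/1 values with the shape of `p`.
#' @export
sample_bernoulli <- function(p) {
  if (any(p < 0 | p > 1)) abort("Probabilities must lie in [0, 1].")
  u <- runif(length(p))
  out <- as.numeric(u < p)
  if (is.matrix(p)) dim(out) <- dim(p)
  out
}

#' Contrastive divergence configuration
#'
#' @param learning_rate Step size epsilon in the CD updates.
#' @param epochs Number of full-batch update sweeps.
#' @param K Number of Gibbs reconstruction steps (CD-K); the default CD-1
#'   performs a single reconstruction.
#' @param dropout_rate Probability of zeroing each hidden unit's activation
#'   during pretraining (a fresh 0/1 unit mask each epoch); 0 disables.
#' @param seed Integer seed making training deterministic.
#' @param weight_init_scale SD of the Gaussian weight initialiser.
#' @return A list of class `cd_config`.
#' @export
cd_config <- function(learning_rate = 0.1, epochs = 100L, K = 1L,
                      dropout_rate = 0.2, seed = 1L,
                      weight_init_scale = 0.01) {
  assert_scalar_number(learning_rate, "learning_rate", lower = 0)
  assert_scalar_number(epochs, "epochs", lower = 0)
  assert_scalar_number(K, "K", lower = 1)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(weight_init_scale, "weight_init_scale", lower = 1e-12)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 K = as.integer(K), dropout_rate = dropout_rate,
                 seed = as.integer(seed),
                 weight_init_scale = weight_init_scale),
            class = "cd_config")
}

#' One CD-K parameter update from a batch
#'
#' Computes the contrastive-divergence updates
#' `dW = eps * (<v h>_data - <v h>_recon)`,
#' `da = eps * (<v>_data - <v>_recon)`,
#' `db = eps * (<h>_data - <h>_recon)`,
#' with associations averaged over the batch. The positive phase uses hidden
#' probabilities on the data; binary hidden samples drive the Gibbs
#' reconstruction; after K half-step pairs the negative phase uses visible
#' probabilities and their hidden probabilities (the standard low-variance
#' convention). Consumes the global RNG stream.
#'
#' @param params An `rbm_params`.
#' @param batch Matrix of visible configurations in `[0, 1]`, rows = samples.
#' @param config A [cd_config()].
#' @param hidden_mask Optional 0/1 vector (length m) applied to hidden
#'   probabilities in both phases (pretraining dropout).
#' @return List with `dW`, `da`, `db` and `recon`, the reconstructed visible
#'   probabilities (used for the reconstruction-error trace).
#' @export
cd_k_update <- function(params, batch, config = cd_config(),
                        hidden_mask = NULL) {
  if (!is.matrix(batch) || nrow(batch) == 0L) abort("`batch` must be a non-empty matrix.")
  if (ncol(batch) != nrow(params$W)) {
    abort("Batch width does not match the RBM's visible dimension.")
  }
  eps <- config$learning_rate
  nb <- nrow(batch)

  ph_data <- hidden_probs(params, batch)
  if (!is.null(hidden_mask)) ph_data <- sweep(ph_data, 2, hidden_mask, "*")
  h <- sample_bernoulli(ph_data)
  for (step in seq_len(config$K)) {
    pv <- visible_probs(params, h)
    ph <- hidden_probs(params, pv)
    if (!is.null(hidden_mask)) ph <- sweep(ph, 2, hidden_mask, "*")
    if (step < config$K) h <- sample_bernoulli(ph)
  }

  list(dW = eps * (crossprod(batch, ph_data) - crossprod(pv, ph)) / nb,
       da = eps * (colMeans(batch) - colMeans(pv)),
       db = eps * (colMeans(ph_data) - colMeans(ph)),
       recon = pv)
}

#' Train one RBM with full-batch CD-K
#'
#' Applies [cd_k_update()] to the whole data matrix once per epoch (no
#' mini-batches). With a non-zero `dropout_rate` a fresh 0/1 unit mask is
#' resampled each epoch and applied to the hidden probabilities of both
#' phases. Deterministic given `config$seed`.
#'
#' @param data Matrix in `[0, 1]`, rows = samples.
#' @param n_hidden Number of hidden units.
#' @param config A [cd_config()].
#' @return List with `params` (`rbm_params`) and `trace`, a tibble with one
#'   row per epoch (`epoch`, `recon_mse`: mean squared difference between the
#'   data and the epoch's reconstructed visible probabilities).
#' @export
train_rbm <- function(data, n_hidden, config = cd_config()) {
  if (!is.matrix(data) || nrow(data) == 0L) abort("`data` must be a non-empty matrix.")
  if (n_hidden < 1L) abort("`n_hidden` must be >= 1.")
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  params <- rbm_params(ncol(data), n_hidden,
                       init_scale = config$weight_init_scale)
  recon_mse <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    mask <- if (config$dropout_rate > 0) {
      sample_bernoulli(rep(1 - config$dropout_rate, n_hidden))
    }
    upd <- cd_k_update(params, data, config, hidden_mask = mask)
    params$W <- params$W + upd$dW
    params$a <- params$a + upd$da
    params$b <- params$b + upd$db
    recon_mse[epoch] <- mean((data - upd$recon)^2)
  }
  list(params = params,
       trace = tibble(epoch = seq_len(config$epochs), recon_mse = recon_mse))
}

# Enumerate all binary configurations of `size` units as a 2^size x size matrix.
enumerate_states <- function(size) {
  S <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), size)))
  dimnames(S) <- NULL
  S
}

#' Exact log-likelihood gradient of a small RBM
#'
#' Computes the gradient of the mean log-likelihood
#' `mean_v log P(v)` with `P(v) = sum_h exp(-E(v, h)) / Z` by exhaustive
#' enumeration of all `2^n x 2^m` joint states. Feasible only for small
#' RBMs; serves as the independent oracle that CD-K approximates.
#'
#' @param params An `rbm_params` with at most 12 units per layer.
#' @param data Matrix of visible configurations (rows = samples; values in
#'   `[0, 1]`, the positive phase uses conditional hidden means).
#' @return List with `dW`, `da`, `db` (same shapes as the parameters) and
#'   `loglik`, the mean log-likelihood itself.
#' @export
exact_loglik_grad <- function(params, data) {
  n <- nrow(params$W); m <- ncol(params$W)
  if (n > 12L || m > 12L) abort("Enumeration limited to n, m <= 12.")
  data <- as_batch(data, n)

  V <- enumerate_states(n)                      # 2^n x n
  # log sum_h exp(-E(v,h)) = a.v + sum_j log(1 + exp(b_j + v.W_j))
  free <- as.numeric(V %*% params$a) +
    rowSums(log1p(exp(sweep(V %*% params$W, 2, params$b, "+"))))
  logZ <- max(free) + log(sum(exp(free - max(free))))
  pv <- exp(free - logZ)                        # model marginal P(v)

  ph_model <- hidden_probs(params, V)           # E[h | v] for each state
  Evh_model <- crossprod(V * pv, ph_model)      # sum_v P(v) v E[h|v]'
  Ev_model <- colSums(V * pv)
  Eh_model <- colSums(ph_model * pv)

  ph_data <- hidden_probs(params, data)
  Evh_data <- crossprod(data, ph_data) / nrow(data)

  loglik_rows <- {
    fr_data <- as.numeric(data %*% params$a) +
      rowSums(log1p(exp(sweep(data %*% params$W, 2, params$b, "+"))))
    fr_data - logZ
  }

  list(dW = unname(Evh_data - Evh_model),
       da = unname(colMeans(data) - Ev_model),
       db = unname(colMeans(ph_data) - Eh_model),
       loglik = mean(loglik_rows))
}
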