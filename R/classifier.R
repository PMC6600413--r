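# Softmax head and end-to-end fine-tuning of the DBN + softmax network.
#
# Fine-tuning treats the pretrained stack plus the softmax head as one
# feed-forward network and minimises multiclass cross-entropy with L2 weight
# decay on the weights (biases excluded), by full-batch gradient descent or
# L-BFGS. Parameters are flattened in a fixed documented order:
#   for each hidden layer l (bottom-up): vec(W_l) column-major, then b_l;
#   then vec(softmax W) column-major (k x features), then softmax biases.

#' Softmax class probabilities
#'
#' Numerically stable softmax of the affine logits `F W' + b` (row-max
#' subtracted before exponentiation).
#'
#' @param params List with `W` (k classes x feature dim) and `b` (length k).
#' @param features Feature matrix (rows = samples) or a single feature vector.
#' @return Probability matrix whose rows sum to 1.
#' @export
softmax_probs <- function(params, features) {
  F <- as_batch(features, ncol(params$W))
  if (ncol(F) != ncol(params$W)) {
    abort(sprintf("Feature dimension mismatch: got %d, head expects %d.",
                  ncol(F), ncol(params$W)))
  }
  logits <- sweep(tcrossprod(F, params$W), 2, params$b, "+")
  logits <- logits - apply(logits, 1, max)
  E <- exp(logits)
  E / rowSums(E)
}

softmax_params <- function(k, n_features) {
  list(W = matrix(0, k, n_features), b = numeric(k))
}

# ---- parameter flattening ---------------------------------------------------

net_shapes <- function(layers, softmax) {
  list(layers = lapply(layers, function(l) dim(l$W)),
       softmax = dim(softmax$W))
}

flatten_net <- function(layers, softmax) {
  unlist(c(lapply(layers, function(l) c(as.numeric(l$W), l$b)),
           list(c(as.numeric(softmax$W), softmax$b))),
         use.names = FALSE)
}

unflatten_net <- function(theta, shapes) {
  at <- 0L
  layers <- lapply(shapes$layers, function(d) {
    nw <- d[1] * d[2]
    W <- matrix(theta[at + seq_len(nw)], d[1], d[2])
    b <- theta[at + nw + seq_len(d[2])]
    at <<- at + nw + d[2]
    list(W = W, b = b)
  })
  d <- shapes$softmax
  nw <- d[1] * d[2]
  W <- matrix(theta[at + seq_len(nw)], d[1], d[2])
  b <- theta[at + nw + seq_len(d[1])]
  list(layers = layers, softmax = list(W = W, b = b))
}

# Extract the feed-forward layers (weights + hidden biases) from a DBN.
dbn_layers <- function(dbn) {
  lapply(dbn$rbms, function(r) list(W = r$W, b = r$b))
}

# ---- cost and gradient ------------------------------------------------------

# Multiply activations by a dropout mask: a matrix mask elementwise, a unit
# vector mask across every row.
mask_mult <- function(A, mask) {
  if (is.matrix(mask)) A * mask else sweep(A, 2, mask, "*")
}

# Core objective on flattened parameters. `masks`: NULL (no dropout /
# inference scaling via `infer_scale`), or a list with one fixed train-mode
# 0/1 mask per hidden layer — either a unit vector (recycled across the
# batch) or a full sample-by-unit matrix (standard per-sample dropout).
net_cost_grad <- function(theta, shapes, X, Y, lambda, masks = NULL,
                          infer_scale = 1) {
  net <- unflatten_net(theta, shapes)
  L <- length(net$layers)
  H <- vector("list", L + 1L)
  S <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(H[[l]] %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    S[[l]] <- sigmoid(Z)
    H[[l + 1L]] <- if (!is.null(masks)) {
      mask_mult(S[[l]], masks[[l]])
    } else if (infer_scale != 1) S[[l]] * infer_scale else S[[l]]
  }
  P <- softmax_probs(net$softmax, H[[L + 1L]])
  n <- nrow(X)
  ce <- -sum(Y * log(pmax(P, 1e-300))) / n
  decay <- sum(vapply(net$layers, function(l) sum(l$W^2), numeric(1))) +
    sum(net$softmax$W^2)
  cost <- ce + lambda / 2 * decay

  D <- (P - Y) / n
  gWs <- crossprod(D, H[[L + 1L]]) + lambda * net$softmax$W
  gbs <- colSums(D)
  G <- D %*% net$softmax$W
  gl <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (!is.null(masks)) {
      G <- mask_mult(G, masks[[l]])
    } else if (infer_scale != 1) G <- G * infer_scale
    G <- G * S[[l]] * (1 - S[[l]])
    gl[[l]] <- list(W = crossprod(H[[l]], G) + lambda * net$layers[[l]]$W,
                    b = colSums(G))
    G <- tcrossprod(G, net$layers[[l]]$W)
  }
  list(cost = cost,
       grad = flatten_net(gl, list(W = gWs, b = gbs)),
       probs = P)
}

#' Cost and exact gradient of the full network
#'
#' Mean multiclass cross-entropy plus `(lambda/2)` times the sum of squared
#' weights (all hidden-layer weights and softmax weights; biases excluded),
#' with the exact analytic gradient with respect to every parameter,
#' flattened bottom-up (each layer's weights column-major then its hidden
#' biases, finally the softmax weights and biases). Supplying fixed
#' `dropout_masks` makes the objective deterministic, so finite-difference
#' checks are well-posed.
#'
#' @param model A fitted or initialised [mdbn()] model.
#' @param X Normalised input matrix (rows = samples, values in `[0, 1]`).
#' @param Y One-hot target matrix (see [one_hot()]).
#' @param lambda Weight-decay coefficient.
#' @param dropout_masks Optional list of fixed 0/1 masks, one per hidden
#'   layer: either unit vectors (shared across samples) or sample-by-unit
#'   matrices (standard per-sample dropout, as fine-tuning resamples them).
#' @return List with `cost` (scalar), `grad` (flat numeric vector) and
#'   `probs` (the predicted class probabilities).
#' @export
cost_and_grad <- function(model, X, Y, lambda = 1e-4, dropout_masks = NULL) {
  stopifnot(inherits(model, "mdbn"))
  if (!all(rowSums(Y) == 1) || !all(Y %in% c(0, 1))) {
    abort("`Y` must be a one-hot matrix (rows summing to 1).")
  }
  layers <- dbn_layers(model$dbn)
  shapes <- net_shapes(layers, model$softmax)
  theta <- flatten_net(layers, model$softmax)
  net_cost_grad(theta, shapes, X, Y, lambda, masks = dropout_masks)
}

# ---- softmax head pretraining ----------------------------------------------

#' Train the softmax head on frozen DBN features
#'
#' Optimises the softmax regression objective (cross-entropy plus weight
#' decay) on fixed features with L-BFGS from a zero initialisation, giving
#' the head informed starting weights before joint fine-tuning.
#'
#' @param features Feature matrix (top DBN layer activations).
#' @param Y One-hot target matrix.
#' @param lambda Weight-decay coefficient.
#' @param iterations Optimiser iteration cap; 0 returns the zero
#'   initialisation untouched.
#' @param seed Integer seed (the optimisation itself is deterministic; the
#'   seed is part of the reproducibility contract).
#' @return List with `W` (k x feature dim) and `b` (length k).
#' @export
train_softmax_head <- function(features, Y, lambda = 1e-4, iterations = 100L,
                               seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(Y)) abort("Row mismatch between features and Y.")
  k <- ncol(Y)
  if (sum(colSums(Y) > 0) < 2L) {
    abort("Degenerate targets: need at least two classes present.")
  }
  params <- softmax_params(k, ncol(features))
  if (iterations == 0L) return(params)
  shapes <- list(layers = list(), softmax = dim(params$W))
  fn <- function(theta) {
    net_cost_grad(theta, shapes, features, Y, lambda)$cost
  }
  gr <- function(theta) {
    net_cost_grad(theta, shapes, features, Y, lambda)$grad
  }
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  opt <- stats::optim(flatten_net(list(), params), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = as.integer(iterations)))
  unflatten_net(opt$par, shapes)$softmax
}

# ---- fine-tuning ------------------------------------------------------------

#' Fine-tuning configuration
#'
#' @param method `"lbfgs"` (limited-memory quasi-Newton with strong-Wolfe
#'   line search) or `"gd"` (full-batch fixed-step gradient descent).
#' @param iterations Iteration cap (conventional budgets: 300 for L-BFGS,
#'   5000 for GD).
#' @param learning_rate GD step size (ignored by L-BFGS).
#' @param weight_decay L2 coefficient lambda on weights.
#' @param lbfgs_history Number of curvature pairs retained.
#' @param tolerance Gradient sup-norm below which optimisation stops.
#' @param dropout_rate Fine-tuning dropout on hidden layers (fresh per-unit
#'   masks each iteration); 0 disables.
#' @param trace_every Record the FMSE/FMR/TMR trace every this many
#'   iterations (the final iteration is always recorded).
#' @param seed Integer seed for mask sampling.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(method = c("lbfgs", "gd"), iterations = 300L,
                            learning_rate = 0.1, weight_decay = 1e-4,
                            lbfgs_history = 20L, tolerance = 1e-6,
                            dropout_rate = 0.5, trace_every = 1L,
                            seed = 1L) {
  method <- match.arg(method)
  assert_scalar_number(iterations, "iterations", lower = 0)
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  assert_scalar_number(weight_decay, "weight_decay", lower = 0)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-12)
  structure(list(method = method, iterations = as.integer(iterations),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 lbfgs_history = as.integer(lbfgs_history),
                 tolerance = tolerance, dropout_rate = dropout_rate,
                 trace_every = as.integer(trace_every),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

# Strong-Wolfe line search (bracketing + zoom). `phi` returns list(f, d):
# objective value and directional derivative at step alpha.
wolfe_line_search <- function(phi, f0, d0, alpha1 = 1, c1 = 1e-4, c2 = 0.9,
                              max_evals = 25L) {
  alpha_prev <- 0; f_prev <- f0; d_prev <- d0
  alpha <- alpha1
  zoom <- function(lo, f_lo, d_lo, hi, f_hi, evals) {
    for (i in seq_len(max_evals - evals)) {
      a <- (lo + hi) / 2
      p <- phi(a)
      if (p$f > f0 + c1 * a * d0 || p$f >= f_lo) {
        hi <- a; f_hi <- p$f
      } else {
        if (abs(p$d) <= -c2 * d0) return(list(alpha = a, f = p$f, d = p$d))
        if (p$d * (hi - lo) >= 0) { hi <- lo; f_hi <- f_lo }
        lo <- a; f_lo <- p$f; d_lo <- p$d
      }
    }
    list(alpha = lo, f = f_lo, d = d_lo)
  }
  for (i in seq_len(max_evals)) {
    p <- phi(alpha)
    if (p$f > f0 + c1 * alpha * d0 || (i > 1 && p$f >= f_prev)) {
      return(zoom(alpha_prev, f_prev, d_prev, alpha, p$f, i))
    }
    if (abs(p$d) <= -c2 * d0) return(list(alpha = alpha, f = p$f, d = p$d))
    if (p$d >= 0) return(zoom(alpha, p$f, p$d, alpha_prev, f_prev, i))
    alpha_prev <- alpha; f_prev <- p$f; d_prev <- p$d
    alpha <- 2 * alpha
  }
  NULL
}

# L-BFGS two-loop recursion: approximate -H^{-1} g from curvature history.
lbfgs_direction <- function(g, S, Yv) {
  if (length(S) == 0L) return(-g)
  q <- g
  k <- length(S)
  alpha <- numeric(k)
  rho <- vapply(seq_len(k), function(i) 1 / sum(Yv[[i]] * S[[i]]), numeric(1))
  for (i in rev(seq_len(k))) {
    alpha[i] <- rho[i] * sum(S[[i]] * q)
    q <- q - alpha[i] * Yv[[i]]
  }
  gamma <- sum(S[[k]] * Yv[[k]]) / sum(Yv[[k]]^2)
  r <- gamma * q
  for (i in seq_len(k)) {
    beta <- rho[i] * sum(Yv[[i]] * r)
    r <- r + (alpha[i] - beta) * S[[i]]
  }
  -r
}

#' Jointly fine-tune a DBN + softmax model
#'
#' Optimises every network parameter on labelled training data by the
#' configured method. After each iteration the trace records the training
#' objective (`cost`), the mean squared error between predicted
#' probabilities and one-hot targets (`fmse`), the training
#' misclassification rate (`fmr`), and the test misclassification rate
#' (`tmr`; `NA` when no test set is given) — all evaluated in inference
#' mode, so test data never influences the parameter updates. With a
#' non-zero dropout rate fresh per-sample 0/1 masks are resampled each
#' iteration in both methods; within an L-BFGS iteration the masks stay
#' fixed so the Wolfe conditions refer to a single deterministic objective,
#' and the curvature pair is formed from gradients under that same mask.
#'
#' @param model An [mdbn()] model (head initialised, e.g. via
#'   [train_softmax_head()]).
#' @param train_X,train_Y Normalised training inputs and one-hot targets.
#' @param test_X,test_Y Optional held-out set for the TMR trace.
#' @param config A [finetune_config()].
#' @return List with `model` (updated) and `trace` (tibble with columns
#'   `iteration`, `cost`, `fmse`, `fmr`, `tmr`).
#' @export
finetune <- function(model, train_X, train_Y, test_X = NULL, test_Y = NULL,
                     config = finetune_config()) {
  stopifnot(inherits(model, "mdbn"), inherits(config, "finetune_config"))
  layers <- dbn_layers(model$dbn)
  shapes <- net_shapes(layers, model$softmax)
  theta <- flatten_net(layers, model$softmax)
  lambda <- config$weight_decay
  rate <- config$dropout_rate
  infer_scale <- 1 - rate
  hidden_sizes <- model$dbn$layer_sizes[-1]

  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)

  n_train <- nrow(train_X)
  sample_masks <- function() {
    if (rate == 0) return(NULL)
    lapply(hidden_sizes, function(m) {
      matrix(sample_bernoulli(rep(1 - rate, n_train * m)), n_train, m)
    })
  }
  eval_trace <- function(theta, it, rows) {
    res <- net_cost_grad(theta, shapes, train_X, train_Y, lambda,
                         infer_scale = infer_scale)
    pred_tr <- max.col(res$probs, ties.method = "first")
    fmr <- mean(pred_tr != max.col(train_Y, ties.method = "first"))
    tmr <- NA_real_
    if (!is.null(test_X)) {
      rt <- net_cost_grad(theta, shapes, test_X, test_Y, lambda,
                          infer_scale = infer_scale)
      tmr <- mean(max.col(rt$probs, ties.method = "first") !=
                    max.col(test_Y, ties.method = "first"))
    }
    rows[[length(rows) + 1L]] <- tibble(
      iteration = it, cost = res$cost,
      fmse = mean((res$probs - train_Y)^2), fmr = fmr, tmr = tmr)
    rows
  }

  rows <- list()
  S <- list(); Yv <- list()
  it_done <- 0L
  for (it in seq_len(config$iterations)) {
    masks <- sample_masks()
    fg <- net_cost_grad(theta, shapes, train_X, train_Y, lambda,
                        masks = masks, infer_scale = infer_scale)
    if (max(abs(fg$grad)) < config$tolerance) break
    if (config$method == "gd") {
      theta <- theta - config$learning_rate * fg$grad
    } else {
      d <- lbfgs_direction(fg$grad, S, Yv)
      dd <- sum(d * fg$grad)
      if (!is.finite(dd) || dd >= 0) {            # not a descent direction
        d <- -fg$grad; dd <- -sum(fg$grad^2)
        S <- list(); Yv <- list()
      }
      phi <- function(alpha) {
        r <- net_cost_grad(theta + alpha * d, shapes, train_X, train_Y,
                           lambda, masks = masks, infer_scale = infer_scale)
        list(f = r$cost, d = sum(r$grad * d))
      }
      alpha1 <- if (length(S)) 1 else min(1, 1 / max(1e-12, sqrt(sum(d^2))))
      ls <- wolfe_line_search(phi, fg$cost, dd, alpha1 = alpha1)
      if (is.null(ls) || !is.finite(ls$f) || ls$alpha <= 0) {
        # line search failed on this mask's objective: take a tiny safe step
        step <- 1e-3 / max(1, sqrt(sum(fg$grad^2)))
        theta_new <- theta - step * fg$grad
        g_new <- net_cost_grad(theta_new, shapes, train_X, train_Y, lambda,
                               masks = masks, infer_scale = infer_scale)$grad
      } else {
        theta_new <- theta + ls$alpha * d
        g_new <- net_cost_grad(theta_new, shapes, train_X, train_Y, lambda,
                               masks = masks, infer_scale = infer_scale)$grad
      }
      s_vec <- theta_new - theta
      y_vec <- g_new - fg$grad
      sy <- sum(s_vec * y_vec)
      if (is.finite(sy) && sy > 1e-10 * sqrt(sum(s_vec^2) * sum(y_vec^2))) {
        S <- c(S, list(s_vec)); Yv <- c(Yv, list(y_vec))
        if (length(S) > config$lbfgs_history) {
          S <- S[-1L]; Yv <- Yv[-1L]
        }
      }
      theta <- theta_new
    }
    it_done <- it
    if (it %% config$trace_every == 0L || it == config$iterations) {
      rows <- eval_trace(theta, it, rows)
    }
  }
  if (it_done > 0L && it_done %% config$trace_every != 0L &&
      it_done != config$iterations) {
    rows <- eval_trace(theta, it_done, rows)
  }

  net <- unflatten_net(theta, shapes)
  for (l in seq_along(net$layers)) {
    model$dbn$rbms[[l]]$W <- net$layers[[l]]$W
    model$dbn$rbms[[l]]$b <- net$layers[[l]]$b
  }
  model$softmax <- net$softmax
  trace <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(iteration = integer(), cost = numeric(), fmse = numeric(),
           fmr = numeric(), tmr = numeric())
  }
  model$trace <- trace
  list(model = model, trace = trace)
}
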