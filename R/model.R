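#' Leaky rectified linear activation
#'
#' `max(0.01 x, x)`, applied elementwise. Used by every hidden neuron of the
#' gene-modular network; the small negative slope avoids permanently
#' inactive ("dying") units.
#'
#' @param x Numeric vector or matrix.
#' @return Object of the same shape.
#' @export
#' @examples
#' leaky_relu(c(-1, 0, 2))  # -0.01 0 2
leaky_relu <- function(x) pmax(0.01 * x, x)

#' Model configuration for the gene-modular network
#'
#' Defaults follow the published training recipe for small exome cohorts:
#' RMSprop with learning rate 0.001, 100 epochs, batch size 3, dropout 0.1
#' on the per-gene latent vector, and a high L2 penalty (lambda = 1)
#' applied to every trainable parameter, biases included, as
#' optimizer-level weight decay does.
#'
#' @param n_genes Number of panel genes G (width of the final layer).
#' @param g_hidden_width Hidden width of the shared gene module (default 32).
#' @param dropout_p Dropout probability on the concatenated gene latent
#'   vector, training mode only (default 0.1).
#' @param l2_lambda Coefficient of the sum-of-squared-parameters penalty
#'   (default 1).
#' @param learning_rate RMSprop learning rate (default 0.001).
#' @param epochs Local training epochs (default 100).
#' @param batch_size Mini-batch size (default 3).
#' @param rmsprop_alpha Smoothing constant of the running squared-gradient
#'   mean (default 0.99).
#' @param rmsprop_eps Denominator stabilizer (default 1e-8).
#' @param seed Integer seed for initialization and training randomness.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_genes, g_hidden_width = 32L, dropout_p = 0.1,
                         l2_lambda = 1, learning_rate = 0.001,
                         epochs = 100L, batch_size = 3L,
                         rmsprop_alpha = 0.99, rmsprop_eps = 1e-8,
                         seed = 1L) {
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  stop_if_not(g_hidden_width >= 1, "g_hidden_width must be >= 1")
  stop_if_not(dropout_p >= 0 && dropout_p < 1, "dropout_p must be in [0, 1)")
  stop_if_not(l2_lambda >= 0, "l2_lambda must be >= 0")
  stop_if_not(learning_rate > 0, "learning_rate must be > 0")
  stop_if_not(epochs >= 1 && batch_size >= 1, "epochs and batch_size must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 g_hidden_width = as.integer(g_hidden_width),
                 dropout_p = dropout_p, l2_lambda = l2_lambda,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps,
                 seed = as.integer(seed)),
            class = "model_config")
}

# parameter block sizes; the shared module |G| = 13 h + 1 is independent of
# the number of genes
n_params_gmodule <- function(h) 13L * as.integer(h) + 1L

#' Total trainable parameter count
#' @param config A [model_config()].
#' @return Integer: |G| + n_genes + 1.
#' @export
n_params <- function(config) {
  n_params_gmodule(config$g_hidden_width) + config$n_genes + 1L
}

#' Initialize model parameters
#'
#' Random initialization, uniform in (-1/sqrt(fan_in), 1/sqrt(fan_in)) per
#' layer, reproducible from `config$seed`. Parameters live in a single flat
#' vector with a stable layout (shared-module weights first, then the final
#' layer), which is what the aggregation strategies operate on.
#'
#' @param config A [model_config()].
#' @return A list of class `model_params` with elements `theta` (flat
#'   numeric vector), `n_genes`, `hidden` and `config`.
#' @export
init_model <- function(config) {
  h <- config$g_hidden_width
  G <- config$n_genes
  theta <- with_seed(derive_seed(config$seed, "init"), {
    u <- function(n, fan_in) runif(n, -1, 1) / sqrt(fan_in)
    c(u(h * 11L, 11), u(h, 11),      # W1, b1
      u(h, h), u(1L, h),             # w2, b2
      u(G, G), u(1L, G))             # wf, bf
  })
  structure(list(theta = theta, n_genes = G, hidden = h, config = config),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %d genes, shared module width %d, %d parameters\n",
              x$n_genes, x$hidden, length(x$theta)))
  invisible(x)
}

#' Flatten model parameters / rebuild from a flat vector
#'
#' The flat layout is `[vec(W1), b1, w2, b2, wf, bf]` with `W1` stored
#' column-major. `set_theta()` is the inverse used when a server hands a
#' model an aggregated vector.
#'
#' @param model A `model_params` object.
#' @param theta Flat numeric vector of matching length.
#' @return `flatten_params()` the flat vector; `set_theta()` the updated
#'   model; `unflatten_params()` a list of weight blocks
#'   (`W1`, `b1`, `w2`, `b2`, `wf`, `bf`).
#' @export
flatten_params <- function(model) model$theta

#' @rdname flatten_params
#' @export
set_theta <- function(model, theta) {
  stop_if_not(length(theta) == length(model$theta),
              "parameter vector length mismatch")
  model$theta <- as.numeric(theta)
  model
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(model) {
  h <- model$hidden
  G <- model$n_genes
  th <- model$theta
  k <- 0L
  take <- function(n) {
    out <- th[(k + 1L):(k + n)]
    k <<- k + n
    out
  }
  list(W1 = matrix(take(h * 11L), h, 11L), b1 = take(h),
       w2 = take(h), b2 = take(1L), wf = take(G), bf = take(1L))
}

# R reference forward pass over an (N, 11, G) tensor; eval mode unless a
# dropout mask is supplied. Independent of the compiled path on purpose: it
# is the oracle the C++ gradients are checked against.
forward_tensor_r <- function(model, tensor, dropout_mask = NULL) {
  p <- unflatten_params(model)
  n <- dim(tensor)[1]
  G <- dim(tensor)[3]
  M <- matrix(aperm(tensor, c(2, 3, 1)), nrow = 11)      # 11 x (G*N)
  H <- leaky_relu(p$W1 %*% M + p$b1)
  s <- leaky_relu(drop(crossprod(H, p$w2)) + p$b2)       # G*N
  S <- matrix(s, nrow = G)                               # G x N
  if (!is.null(dropout_mask)) S <- S * dropout_mask
  drop(sigmoid(crossprod(S, p$wf) + p$bf))
}

#' Forward pass for one sample
#'
#' Applies the shared gene module to every gene column of the (11 x G)
#' sample matrix, concatenates the G latent values, applies dropout (in
#' training mode only), and maps through the logistic final layer.
#'
#' @param model A `model_params` object.
#' @param sample Numeric (11 x G) matrix (one column per panel gene).
#' @param training Logical; if `TRUE`, an inverted-dropout mask with the
#'   configured `dropout_p` is drawn from the current RNG state.
#' @return Case probability in (0, 1).
#' @export
forward <- function(model, sample, training = FALSE) {
  stop_if_not(is.matrix(sample) && nrow(sample) == 11,
              "sample must be an 11 x G matrix")
  stop_if_not(ncol(sample) == model$n_genes,
              "sample gene axis must match the model's n_genes")
  tensor <- array(0, dim = c(1, 11, model$n_genes))
  tensor[1, , ] <- sample
  mask <- NULL
  if (training && model$config$dropout_p > 0) {
    p <- model$config$dropout_p
    mask <- matrix((runif(model$n_genes) >= p) / (1 - p), ncol = 1)
  }
  unname(forward_tensor_r(model, tensor, mask))
}

#' Predict case probabilities for a cohort
#'
#' Deterministic evaluation-mode forward pass (dropout disabled) over all
#' samples, using the compiled batch kernel.
#'
#' @param model A `model_params` object.
#' @param cohort A [cohort_dataset()] (or a bare (N, 11, G) array).
#' @return Numeric vector of N probabilities.
#' @export
predict_proba <- function(model, cohort) {
  tensor <- if (inherits(cohort, "cohort_dataset")) cohort$tensor else cohort
  stop_if_not(dim(tensor)[3] == model$n_genes,
              "cohort gene axis must match the model's n_genes")
  drop(cdk_forward_cpp(model$theta, aperm(tensor, c(2, 3, 1)), model$hidden))
}

#' Binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))`, with predictions clamped away from 0
#' and 1 by `eps`.
#'
#' @param prediction Predicted probabilities.
#' @param label Labels in \{0, 1\}.
#' @param eps Clamp width (default 1e-12).
#' @return Elementwise loss (same length as inputs).
#' @export
#' @examples
#' bce_loss(0.5, 1)  # log(2)
bce_loss <- function(prediction, label, eps = 1e-12) {
  p <- pmin(pmax(prediction, eps), 1 - eps)
  -(label * log(p) + (1 - label) * log(1 - p))
}

# Penalized training objective on a full tensor (eval mode): mean BCE plus
# l2 * sum of squared parameters (biases included, mirroring
# optimizer-level weight decay). Used by the finite-difference gradient
# checks.
penalized_loss <- function(model, tensor, labels, l2 = model$config$l2_lambda) {
  p <- forward_tensor_r(model, tensor)
  mean(bce_loss(p, labels)) + l2 * sum(model$theta^2)
}

#' Train the model locally on one cohort
#'
#' Mini-batch RMSprop on binary cross-entropy plus an L2 penalty on all
#' trainable parameters. Sample order is reshuffled every epoch and the
#' final short batch is used as-is. Fully reproducible from `config$seed`.
#'
#' @param model A `model_params` object (starting point; not modified).
#' @param cohort A [cohort_dataset()] with G = `model$n_genes`.
#' @param config A [model_config()]; defaults to the model's own.
#' @return A list with `model` (trained `model_params`) and `trace`
#'   (per-epoch mean training loss).
#' @export
train_local <- function(model, cohort, config = model$config) {
  stop_if_not(n_samples(cohort) >= 1, "cohort must be non-empty")
  stop_if_not(dim(cohort$tensor)[3] == model$n_genes,
              "cohort gene axis must match the model's n_genes")
  if (length(unique(cohort$labels)) < 2)
    warning("single-class cohort: training proceeds but cannot discriminate")
  X <- aperm(cohort$tensor, c(2, 3, 1))  # 11 x G x N for the kernel
  fit <- with_seed(derive_seed(config$seed, "train"),
    cdk_train_cpp(model$theta, X, as.numeric(cohort$labels),
                  model$hidden, config$epochs, config$batch_size,
                  config$learning_rate, config$l2_lambda,
                  config$dropout_p, config$rmsprop_alpha,
                  config$rmsprop_eps))
  list(model = set_theta(model, drop(fit$theta)),
       trace = drop(fit$trace))
}

#' Save / load a model checkpoint
#'
#' Portable JSON container holding the configuration and the flat parameter
#' vector at full precision.
#'
#' @param model A `model_params` object.
#' @param path Output path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` the restored model.
#' @export
write_checkpoint <- function(model, path) {
  obj <- list(format = "fedgi-checkpoint-v1",
              config = unclass(model$config),
              theta = model$theta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if_not(identical(obj$format, "fedgi-checkpoint-v1"),
              "not a fedgi checkpoint")
  config <- do.call(model_config, as.list(obj$config))
  set_theta(init_model(config), obj$theta)
}
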