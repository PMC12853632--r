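#' Autoencoder parameters for cross-domain profile learning
#'
#' The symptom and herb cross-domain modules each train a two-layer
#' autoencoder on the padded co-occurrence profiles of both domains:
#' `y_hat = f1(W2 f2(W1 y + b1) + b2)` with ReLU for both activations. In
#' this implementation vectors are rows, so `W1` has shape
#' `input_dim x latent_dim` and acts as `y %*% W1 + b1`, and `W2` has shape
#' `latent_dim x input_dim`.
#'
#' @param W1,b1 Encoder weights (`input_dim x latent_dim`) and bias
#'   (`latent_dim`).
#' @param W2,b2 Decoder weights (`latent_dim x input_dim`) and bias
#'   (`input_dim`).
#' @param alpha Nonnegative L2 regularisation strength on all four parameter
#'   blocks.
#' @return An object of class `cdl_autoencoder`.
#' @export
autoencoder_params <- function(W1, b1, W2, b2, alpha = 0) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  if (ncol(W1) != nrow(W2) || nrow(W1) != ncol(W2)) {
    abort("autoencoder shapes do not compose: need W1 (in x d) and W2 (d x in)")
  }
  if (length(b1) != ncol(W1) || length(b2) != ncol(W2)) {
    abort("bias lengths do not match weight shapes")
  }
  if (alpha < 0) abort("alpha must be nonnegative")
  net <- structure(list(
    layers = list(list(W = W1, b = as.numeric(b1)),
                  list(W = W2, b = as.numeric(b2))),
    activations = c("relu", "relu")
  ), class = "nn_mlp")
  structure(list(net = net, alpha = alpha, latent_dim = ncol(W1),
                 input_dim = nrow(W1)),
            class = "cdl_autoencoder")
}

as_profile_matrix <- function(y, input_dim) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  y <- as.matrix(y)
  if (ncol(y) != input_dim) {
    abort(sprintf("profile length %d does not match autoencoder input_dim %d",
                  ncol(y), input_dim))
  }
  y
}

#' Reconstruct co-occurrence profiles through the autoencoder
#'
#' @param y A profile vector or a matrix with one profile per row.
#' @param params A `cdl_autoencoder` (from [autoencoder_params()] or
#'   [train_autoencoder()]).
#' @return The reconstruction `y_hat`, same shape as `y`; entrywise
#'   nonnegative (ReLU output).
#' @examples
#' p <- autoencoder_params(W1 = diag(3), b1 = rep(0, 3),
#'                         W2 = diag(3), b2 = rep(0, 3))
#' encode_decode(c(1, 0, 2), p)  # identity on nonnegative input
#' @export
encode_decode <- function(y, params) {
  vec_in <- is.null(dim(y))
  y <- as_profile_matrix(y, params$input_dim)
  out <- nn_forward(params$net, y)$out
  if (vec_in) drop(out) else out
}

#' Latent features of a profile
#'
#' The encoder half only: `f = ReLU(W1 y + b1)`. These latent vectors are the
#' inputs to the correlation-pattern predictor.
#'
#' @inheritParams encode_decode
#' @return Latent matrix (or vector), entrywise nonnegative.
#' @export
latent_features <- function(y, params) {
  vec_in <- is.null(dim(y))
  y <- as_profile_matrix(y, params$input_dim)
  f <- nn_act(sweep(y %*% params$net$layers[[1]]$W, 2,
                    params$net$layers[[1]]$b, "+"), "relu")
  if (vec_in) drop(f) else f
}

#' Regularised masked square loss of the autoencoder
#'
#' Sum over the batch of squared reconstruction error restricted to the
#' observed positions, plus `alpha * (||W1||_F^2 + ||W2||_F^2 + ||b1||^2 +
#' ||b2||^2)`. Observed positions default to the nonzero entries of each
#' profile (implicit-feedback convention); unobserved entries never influence
#' the loss.
#'
#' @inheritParams encode_decode
#' @param mask Logical matrix (or vector) of observed positions, same shape
#'   as `y`; defaults to `y != 0`.
#' @return A nonnegative scalar.
#' @export
cdl_loss <- function(y, params, mask = NULL) {
  vec_in <- is.null(dim(y))
  y <- as_profile_matrix(y, params$input_dim)
  if (nrow(y) == 0L) abort("cdl_loss: empty batch")
  if (is.null(mask)) mask <- y != 0
  if (vec_in && is.null(dim(mask))) mask <- matrix(mask, nrow = 1L)
  if (!identical(dim(mask), dim(y))) abort("mask shape must match y")
  if (params$alpha < 0) abort("alpha must be nonnegative")
  yhat <- nn_forward(params$net, y)$out
  sum(((yhat - y) * mask)^2) +
    params$alpha * nn_sq_norm(params$net)
}

#' Train a cross-domain autoencoder
#'
#' Full-batch Adam on the regularised masked square loss, with early stopping
#' once the loss has not improved for `patience` consecutive epochs. The
#' parameters achieving the best loss seen are returned, so the final
#' training loss never exceeds the loss of the seeded initial parameters.
#'
#' @param x Profile matrix, one entity per row (e.g. [padded_profiles()]`$x`).
#' @param latent_dim Latent dimension (>= 1).
#' @param alpha L2 regularisation strength (default 0.01).
#' @param lr Adam learning rate (default 1e-3).
#' @param max_epochs Maximum epochs (default 500); 0 returns the seeded
#'   initial parameters unchanged.
#' @param patience Early-stopping patience in epochs (default 20).
#' @param mask Observed-position mask; defaults to `x != 0`.
#' @param log1p_counts If `TRUE`, profiles are `log1p`-transformed before
#'   training (off by default).
#' @param seed Integer seed; training is a pure function of (data, config,
#'   seed).
#' @return A `cdl_autoencoder` with extra fields `loss_trace` (per-epoch
#'   loss, index 1 = initial parameters), `epochs_run`, `best_loss`, and the
#'   training config.
#' @export
train_autoencoder <- function(x, latent_dim, alpha = 0.01, lr = 1e-3,
                              max_epochs = 500L, patience = 20L, mask = NULL,
                              log1p_counts = FALSE, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) abort("train_autoencoder: need at least one profile")
  if (latent_dim < 1L) abort("latent_dim must be >= 1")
  if (alpha < 0) abort("alpha must be nonnegative")
  if (is.null(mask)) mask <- x != 0
  if (log1p_counts) x <- log1p(x)
  input_dim <- ncol(x)

  with_seed(seed, {
    net <- nn_init(c(input_dim, latent_dim, input_dim), c("relu", "relu"))
    # decoder bias starts at the column means so no output unit begins (or
    # easily drifts) into the dead region of the outer ReLU
    net$layers[[2]]$b <- colMeans(x)
    params <- structure(list(net = net, alpha = alpha, latent_dim = latent_dim,
                             input_dim = input_dim),
                        class = "cdl_autoencoder")
    loss_now <- cdl_loss(x, params, mask)
    trace <- loss_now
    best <- list(net = net, loss = loss_now)
    state <- nn_adam_init(net)
    stale <- 0L
    epoch <- 0L
    while (epoch < max_epochs) {
      epoch <- epoch + 1L
      cache <- nn_forward(net, x)
      dout <- 2 * (cache$out - x) * mask
      bp <- nn_backward(net, cache, dout)
      grads <- nn_add_grads(bp$grads, nn_l2_grads(net, alpha))
      st <- nn_adam_step(net, grads, state, lr = lr)
      net <- st$net; state <- st$state
      params$net <- net
      loss_now <- cdl_loss(x, params, mask)
      if (!is.finite(loss_now)) {
        abort(sprintf("train_autoencoder: non-finite loss at epoch %d", epoch))
      }
      trace <- c(trace, loss_now)
      if (loss_now < best$loss - 1e-12) {
        best <- list(net = net, loss = loss_now)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    params$net <- best$net
    params$loss_trace <- trace
    params$epochs_run <- epoch
    params$best_loss <- best$loss
    params$config <- list(latent_dim = latent_dim, alpha = alpha, lr = lr,
                          max_epochs = max_epochs, patience = patience,
                          log1p_counts = log1p_counts, seed = seed)
    params
  })
}

#' @exportS3Method
print.cdl_autoencoder <- function(x, ...) {
  cat(sprintf("<cdl_autoencoder> input_dim=%d latent_dim=%d alpha=%g",
              x$input_dim, x$latent_dim, x$alpha))
  if (!is.null(x$best_loss)) {
    cat(sprintf("; trained %d epochs, best loss %.6g", x$epochs_run, x$best_loss))
  }
  cat("\n")
  invisible(x)
}

#' @export
glance.cdl_autoencoder <- function(x, ...) {
  tibble(
    input_dim = x$input_dim, latent_dim = x$latent_dim, alpha = x$alpha,
    epochs_run = x$epochs_run %||% NA_integer_,
    best_loss = x$best_loss %||% NA_real_
  )
}

#' @export
tidy.cdl_autoencoder <- function(x, ...) {
  if (is.null(x$loss_trace)) return(tibble(epoch = integer(0), loss = numeric(0)))
  tibble(epoch = seq_along(x$loss_trace) - 1L, loss = x$loss_trace)
}
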