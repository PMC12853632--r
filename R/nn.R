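# Minimal dense neural-network engine on base matrix ops.
#
# A network is list(layers = list(list(W, b), ...), activations = chr).
# Inputs are row-major: x is n x in_dim, W is in_dim x out_dim, b length
# out_dim. Supported activations: "relu", "linear", "sigmoid".
# Everything here is internal; the model modules wrap it.

nn_init <- function(dims, activations, seed = NULL) {
  stopifnot(length(dims) >= 2, length(activations) == length(dims) - 1L)
  with_seed(seed, {
    layers <- lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      r <- sqrt(6 / max(fan_in, 1))  # He-style fan-in scaling, uniform
      list(
        W = matrix(runif(fan_in * dims[l + 1L], -r, r), fan_in, dims[l + 1L]),
        # slightly positive biases keep ReLU units alive at initialisation
        b = rep(0.1, dims[l + 1L])
      )
    })
    structure(list(layers = layers, activations = activations), class = "nn_mlp")
  })
}

nn_identity <- function(dim) {
  structure(list(
    layers = list(list(W = diag(dim), b = numeric(dim))),
    activations = "linear"
  ), class = "nn_mlp")
}

nn_act <- function(z, kind) {
  switch(kind,
    relu = pmax(z, 0),
    linear = z,
    sigmoid = 1 / (1 + exp(-z)),
    abort(paste0("unknown activation: ", kind))
  )
}

# Forward pass. Dropout (inverted) is applied after every hidden activation
# when training && dropout > 0; masks are cached so the backward pass matches.
nn_forward <- function(net, x, dropout = 0, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  L <- length(net$layers)
  a <- list(x)        # a[[l + 1]] = output of layer l
  z <- vector("list", L)
  h <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    h[[l]] <- nn_act(z[[l]], net$activations[l])
    if (training && dropout > 0 && l < L) {
      masks[[l]] <- matrix(
        (runif(length(h[[l]])) >= dropout) / (1 - dropout),
        nrow(h[[l]]), ncol(h[[l]])
      )
      a[[l + 1L]] <- h[[l]] * masks[[l]]
    } else {
      a[[l + 1L]] <- h[[l]]
    }
  }
  list(out = a[[L + 1L]], a = a, z = z, h = h, masks = masks)
}

nn_act_grad <- function(z, h, kind) {
  switch(kind,
    relu = (z > 0) * 1,
    linear = 1,
    sigmoid = h * (1 - h)
  )
}

# Backward pass from dL/d(out). Returns per-layer grads and dL/dx.
nn_backward <- function(net, cache, dout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  da <- dout
  for (l in rev(seq_len(L))) {
    if (!is.null(cache$masks[[l]])) da <- da * cache$masks[[l]]
    dz <- da * nn_act_grad(cache$z[[l]], cache$h[[l]], net$activations[l])
    grads[[l]] <- list(
      W = crossprod(cache$a[[l]], dz),
      b = colSums(dz)
    )
    da <- dz %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, dx = da)
}

nn_zero_grads <- function(net) {
  lapply(net$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
}

nn_add_grads <- function(g1, g2) {
  Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), g1, g2)
}

nn_scale_grads <- function(g, s) {
  lapply(g, function(a) list(W = a$W * s, b = a$b * s))
}

# Sum of squares of all parameters (weights and biases).
nn_sq_norm <- function(net) {
  sum(vapply(net$layers, function(ly) sum(ly$W^2) + sum(ly$b^2), numeric(1)))
}

# L2 gradient contribution: d/dtheta [alpha * ||theta||^2] = 2 alpha theta.
nn_l2_grads <- function(net, alpha) {
  lapply(net$layers, function(ly) list(W = 2 * alpha * ly$W, b = 2 * alpha * ly$b))
}

nn_adam_init <- function(net) {
  list(
    t = 0L,
    m = nn_zero_grads(net),
    v = nn_zero_grads(net)
  )
}

nn_adam_step <- function(net, grads, state, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / (1 - beta1^t)
      vhat <- state$v[[l]][[p]] / (1 - beta2^t)
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

# Equal-width hidden stack: depth counts the total number of weight layers.
nn_stack_dims <- function(in_dim, out_dim, depth, hidden) {
  if (depth <= 1L) c(in_dim, out_dim)
  else c(in_dim, rep(hidden, depth - 1L), out_dim)
}
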