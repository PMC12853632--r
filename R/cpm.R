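#' Correlation pattern predictor (adversarial cross-domain refinement)
#'
#' Refines the latent co-occurrence features of both domains in a shared
#' space. Three fully connected ReLU stacks share a composite objective:
#' a rating-pattern extractor (parameters `theta_f`) maps latent vectors to
#' refined features; a rating predictor (`theta_r`) reconstructs rating
#' vectors from them (squared error); and a domain classifier (`theta_c`)
#' predicts the domain label from the refined features (cross-entropy). The
#' composite loss is
#' `L = loss_pred(theta_f, theta_r) - mu * loss_domain(theta_c) + lambda * R`
#' with `R` the squared norm of all three parameter sets. The minus sign is
#' realised with a gradient-reversal layer: the classifier itself descends
#' its cross-entropy while the extractor ascends it, scaled by `mu`, so one
#' optimizer minimises the single composite objective.
#'
#' @param input_dim Dimension of the incoming latent features.
#' @param target_dim Dimension of the rating vectors the predictor
#'   reconstructs (defaults to `input_dim`: latent self-reconstruction).
#' @param feature_dim Dimension of the refined features (defaults to
#'   `input_dim`, keeping the embedding dimension unchanged).
#' @param depth Weight layers per stack (default 2, i.e. one hidden layer).
#' @param hidden Hidden width (default 64).
#' @param mu Adversarial weight (>= 0).
#' @param lambda L2 regularisation weight (>= 0, default 0.001).
#' @param seed Seed for parameter initialisation.
#' @return An object of class `cpm` holding the three networks and the
#'   hyper-parameters.
#' @export
cpm_params <- function(input_dim, target_dim = input_dim,
                       feature_dim = input_dim, depth = 2L, hidden = 64L,
                       mu = 1, lambda = 0.001, seed = 1L) {
  if (mu < 0 || lambda < 0) abort("mu and lambda must be nonnegative")
  with_seed(seed, {
    structure(list(
      extractor = nn_init(nn_stack_dims(input_dim, feature_dim, depth, hidden),
                          rep("relu", depth)),
      predictor = nn_init(nn_stack_dims(feature_dim, target_dim, depth, hidden),
                          c(rep("relu", depth - 1L), "linear")),
      classifier = nn_init(nn_stack_dims(feature_dim, 1L, depth, hidden),
                           c(rep("relu", depth - 1L), "sigmoid")),
      mu = mu, lambda = lambda,
      input_dim = input_dim, target_dim = target_dim, feature_dim = feature_dim
    ), class = "cpm")
  })
}

check_domain_labels <- function(domains, n) {
  bad <- setdiff(unique(domains), c("source", "target"))
  if (length(bad)) {
    abort(paste0("domain labels must be 'source' or 'target', got: ",
                 paste(bad, collapse = ", ")))
  }
  if (length(domains) != n) abort("number of domain labels must match features")
  as.numeric(domains == "target")
}

#' Composite adversarial loss of the correlation pattern predictor
#'
#' `loss_pred - mu * loss_domain + lambda * R`, with the prediction loss the
#' summed squared error of the reconstructed rating vectors, the domain loss
#' the summed cross-entropy of the classifier, and `R` the squared norm of
#' all parameters. Sums (not means) over the batch.
#'
#' @param features Latent feature matrix, one entity per row.
#' @param targets Rating-target matrix, same row count.
#' @param domains Character vector of `"source"`/`"target"` labels per row.
#' @param params A `cpm` object.
#' @return A scalar (may be negative: the adversarial term is subtracted).
#' @export
cpm_loss <- function(features, targets, domains, params) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  if (nrow(features) != nrow(targets)) abort("features/targets row mismatch")
  t_lab <- check_domain_labels(domains, nrow(features))
  g <- nn_forward(params$extractor, features)$out
  r <- nn_forward(params$predictor, g)$out
  p <- nn_forward(params$classifier, g)$out
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pred_loss <- sum((r - targets)^2)
  dom_loss <- -sum(t_lab * log(p) + (1 - t_lab) * log(1 - p))
  reg <- nn_sq_norm(params$extractor) + nn_sq_norm(params$predictor) +
    nn_sq_norm(params$classifier)
  pred_loss - params$mu * dom_loss + params$lambda * reg
}

#' Refined features from a trained pattern extractor
#'
#' @param params A `cpm` object.
#' @param features Latent feature matrix.
#' @return Matrix of refined features (row names preserved).
#' @export
cpm_extract <- function(params, features) {
  features <- as.matrix(features)
  out <- nn_forward(params$extractor, features)$out
  rownames(out) <- rownames(features)
  out
}

#' Train the correlation pattern predictor
#'
#' Full-batch Adam over the composite objective with gradient reversal on
#' the classifier branch. Early stopping watches the prediction component
#' (`loss_pred + lambda * R`): the adversarial term is excluded from the
#' stopping rule because an adversary can lower the composite loss
#' indefinitely by degrading the classifier. The parameters at the stopping
#' epoch are returned (no rollback: in adversarial training the useful
#' domain confusion accumulates over epochs). Seeded and reproducible.
#'
#' @param features_source,features_target Latent feature matrices for the two
#'   domains (rows may carry entity names).
#' @param targets_source,targets_target Rating-target matrices; default to
#'   the input features (latent self-reconstruction).
#' @param feature_dim,depth,hidden,mu,lambda As in [cpm_params()].
#' @param lr Adam learning rate.
#' @param max_epochs Maximum epochs (0 = return the seeded initial model; the
#'   refined features then pass through the initial extractor only).
#' @param patience Early-stopping patience (default 20).
#' @param seed Integer seed.
#' @return A `cpm` object with extra fields: `refined` (refined feature
#'   matrix for all inputs, source rows first), `domains`, `loss_trace`
#'   (composite loss per epoch), `pred_trace`, `epochs_run`.
#' @export
train_cpm <- function(features_source, features_target,
                      targets_source = NULL, targets_target = NULL,
                      feature_dim = NULL, depth = 2L, hidden = 64L,
                      mu = 1, lambda = 0.001, lr = 1e-3,
                      max_epochs = 300L, patience = 20L, seed = 1L) {
  fs <- as.matrix(features_source); ft <- as.matrix(features_target)
  if (nrow(fs) == 0L || nrow(ft) == 0L) {
    abort("train_cpm: both domains must be nonempty")
  }
  if (ncol(fs) != ncol(ft)) abort("train_cpm: feature dimensions differ")
  ts <- if (is.null(targets_source)) fs else as.matrix(targets_source)
  tt <- if (is.null(targets_target)) ft else as.matrix(targets_target)
  x <- rbind(fs, ft)
  targ <- rbind(ts, tt)
  domains <- rep(c("source", "target"), c(nrow(fs), nrow(ft)))
  t_lab <- as.numeric(domains == "target")
  feature_dim <- feature_dim %||% ncol(x)

  with_seed(seed, {
    params <- cpm_params(ncol(x), target_dim = ncol(targ),
                         feature_dim = feature_dim, depth = depth,
                         hidden = hidden, mu = mu, lambda = lambda, seed = NULL)
    states <- list(f = nn_adam_init(params$extractor),
                   r = nn_adam_init(params$predictor),
                   c = nn_adam_init(params$classifier))
    monitor <- function() {
      g <- nn_forward(params$extractor, x)$out
      r <- nn_forward(params$predictor, g)$out
      sum((r - targ)^2) + lambda * (nn_sq_norm(params$extractor) +
                                      nn_sq_norm(params$predictor) +
                                      nn_sq_norm(params$classifier))
    }
    trace <- cpm_loss(x, targ, domains, params)
    pred_trace <- monitor()
    best <- list(value = pred_trace, epoch = 0L)
    stale <- 0L; epoch <- 0L
    eps <- 1e-7
    while (epoch < max_epochs) {
      epoch <- epoch + 1L
      cache_f <- nn_forward(params$extractor, x)
      g <- cache_f$out
      cache_r <- nn_forward(params$predictor, g)
      cache_c <- nn_forward(params$classifier, g)
      p <- pmin(pmax(cache_c$out, eps), 1 - eps)

      dr <- 2 * (cache_r$out - targ)
      bp_r <- nn_backward(params$predictor, cache_r, dr)
      # classifier descends its cross-entropy; d(BCE)/d(sigmoid out) chained
      # through the cached sigmoid derivative equals (p - t) at the logit
      dp <- (p - matrix(t_lab)) / pmax(p * (1 - p), eps)
      bp_c <- nn_backward(params$classifier, cache_c, dp)
      # gradient reversal: extractor ascends the domain loss, scaled by mu
      dg <- bp_r$dx - params$mu * bp_c$dx
      bp_f <- nn_backward(params$extractor, cache_f, dg)

      g_f <- nn_add_grads(bp_f$grads, nn_l2_grads(params$extractor, lambda))
      g_r <- nn_add_grads(bp_r$grads, nn_l2_grads(params$predictor, lambda))
      g_c <- nn_add_grads(nn_scale_grads(bp_c$grads, max(params$mu, 1e-12)),
                          nn_l2_grads(params$classifier, lambda))

      st <- nn_adam_step(params$extractor, g_f, states$f, lr = lr)
      params$extractor <- st$net; states$f <- st$state
      st <- nn_adam_step(params$predictor, g_r, states$r, lr = lr)
      params$predictor <- st$net; states$r <- st$state
      st <- nn_adam_step(params$classifier, g_c, states$c, lr = lr)
      params$classifier <- st$net; states$c <- st$state

      comp <- cpm_loss(x, targ, domains, params)
      if (!is.finite(comp)) {
        abort(sprintf("train_cpm: non-finite loss at epoch %d", epoch))
      }
      trace <- c(trace, comp)
      m <- monitor()
      pred_trace <- c(pred_trace, m)
      if (m < best$value - 1e-12) {
        best <- list(value = m, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    params$best_pred <- best$value
    params$refined <- cpm_extract(params, x)
    params$domains <- domains
    params$loss_trace <- trace
    params$pred_trace <- pred_trace
    params$epochs_run <- epoch
    params
  })
}

#' @exportS3Method
print.cpm <- function(x, ...) {
  cat(sprintf("<cpm> input_dim=%d feature_dim=%d mu=%g lambda=%g",
              x$input_dim, x$feature_dim, x$mu, x$lambda))
  if (!is.null(x$epochs_run)) cat(sprintf("; trained %d epochs", x$epochs_run))
  cat("\n")
  invisible(x)
}

#' Cross-validated accuracy of a domain probe on a feature table
#'
#' Fits a logistic-regression probe predicting the domain label from the
#' features and reports its k-fold cross-validated accuracy (in-sample
#' accuracy would saturate whenever the feature dimension is comparable to
#' the number of entities). Used to verify domain confusion: after
#' adversarial training, probe accuracy on the refined features should sit
#' nearer 0.5 than on features passed through the untrained extractor.
#'
#' @param features Feature matrix.
#' @param domains `"source"`/`"target"` labels per row.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return Held-out accuracy in `[0, 1]`.
#' @export
domain_probe_accuracy <- function(features, domains, folds = 5L, seed = 1L) {
  features <- as.matrix(features)
  t_lab <- check_domain_labels(domains, nrow(features))
  n <- nrow(features)
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  df$.y <- t_lab
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df[!hold, , drop = FALSE],
                 family = stats::binomial())
    )
    pr <- suppressWarnings(
      stats::predict(fit, newdata = df[hold, , drop = FALSE], type = "response")
    )
    pred[hold] <- as.numeric(pr > 0.5)
  }
  mean(pred == t_lab)
}
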