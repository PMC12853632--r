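#' Recommender configuration
#'
#' Hyper-parameters of the neural collaborative filtering head. Defaults
#' follow the tuned full-scale settings: embedding dimension 500, a 7-layer
#' symptom-branch MLP and a 5-layer herb-branch MLP, no dropout, L2 weight
#' 0.001, Adam at learning rate 1e-3 with early-stopping patience 20.
#'
#' @param depth_s,depth_h Weight-layer counts of the symptom and herb branch
#'   MLPs (defaults 7 and 5).
#' @param out_width Shared output width of both branches, so their dot
#'   product is defined (default 128).
#' @param hidden Hidden width of both branches (default `out_width`).
#' @param dropout Dropout ratio in `[0, 1)` on hidden activations during
#'   training (default 0: dropout degrades this model).
#' @param lambda L2 weight-decay strength (default 0.001).
#' @param lr Adam learning rate (default 1e-3).
#' @param max_epochs Maximum training epochs (default 300).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param seed Integer seed.
#' @return A list of class `recommender_config`.
#' @export
recommender_config <- function(depth_s = 7L, depth_h = 5L, out_width = 128L,
                               hidden = out_width, dropout = 0,
                               lambda = 0.001, lr = 1e-3, max_epochs = 300L,
                               patience = 20L, seed = 1L) {
  if (depth_s < 1L || depth_h < 1L) abort("MLP depths must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  if (lambda < 0) abort("lambda must be nonnegative")
  structure(list(depth_s = as.integer(depth_s), depth_h = as.integer(depth_h),
                 out_width = as.integer(out_width), hidden = as.integer(hidden),
                 dropout = dropout, lambda = lambda, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = seed),
            class = "recommender_config")
}

active_rows <- function(P_i, E_s) {
  if (is.character(P_i)) {
    idx <- match(P_i, rownames(E_s))
    if (anyNA(idx)) {
      abort(paste0("symptom(s) missing from E_s: ",
                   paste(P_i[is.na(idx)], collapse = ", ")))
    }
  } else {
    if (length(P_i) != nrow(E_s)) abort("multi-hot length must match nrow(E_s)")
    idx <- which(P_i != 0)
  }
  if (!length(idx)) abort("patient has no active symptoms")
  idx
}

#' Patient embedding from a symptom multi-hot
#'
#' Selects the embedding rows of the patient's active symptoms, mean-pools
#' them into one `d`-vector, and passes it through the symptom-branch MLP
#' (final ReLU): `Z_p = ReLU(MLP(avg_pool(P_i . E_s)))`.
#'
#' @param P_i Either a 0/1 multi-hot vector over the symptom vocabulary
#'   (rows of `E_s`) or a character vector of symptom terms.
#' @param E_s Symptom embedding matrix with term row names.
#' @param mlp_s The symptom-branch network (an internal MLP; use a trained
#'   model's `$mlp_s`, or [identity_mlp()] for hand checks).
#' @return The patient representation `Z_p` (length = branch output width).
#' @export
patient_embedding <- function(P_i, E_s, mlp_s) {
  idx <- active_rows(P_i, E_s)
  pooled <- colMeans(E_s[idx, , drop = FALSE])
  drop(nn_forward(mlp_s, matrix(pooled, 1L))$out)
}

#' Herb representations through the herb-branch MLP
#'
#' `Z_h = ReLU(MLP(E_h))`, applied row-wise.
#'
#' @param E_h Herb embedding matrix with term row names.
#' @param mlp_h The herb-branch network.
#' @return Matrix `n_h x out_width` with the herb row names.
#' @export
herb_embeddings <- function(E_h, mlp_h) {
  if (!nrow(E_h)) abort("E_h must be nonempty")
  out <- nn_forward(mlp_h, as.matrix(E_h))$out
  rownames(out) <- rownames(E_h)
  out
}

#' An identity network (for hand-checkable examples)
#'
#' A single linear layer with identity weights and zero bias; composing it
#' with the branch operations leaves nonnegative inputs unchanged.
#'
#' @param dim Input (= output) dimension.
#' @return An internal MLP object.
#' @export
identity_mlp <- function(dim) nn_identity(dim)

#' Per-herb prescription probabilities
#'
#' `R_hat[j] = sigmoid(<Z_p, Z_h[j, ]>)`: the dot product of the patient
#' representation with every herb representation, squashed to `(0, 1)`.
#'
#' @param Z_p Patient representation vector.
#' @param Z_h Herb representation matrix (herbs x width).
#' @return Named probability vector over herbs.
#' @export
score_herbs <- function(Z_p, Z_h) {
  Z_h <- as.matrix(Z_h)
  if (length(Z_p) != ncol(Z_h)) {
    abort("branch widths disagree: length(Z_p) != ncol(Z_h)")
  }
  if (!all(is.finite(Z_p)) || !all(is.finite(Z_h))) {
    abort("score_herbs: non-finite inputs")
  }
  drop(1 / (1 + exp(-(Z_h %*% Z_p))))
}

#' Binary cross-entropy over all herbs
#'
#' `-[y log y' + (1 - y) log(1 - y')]`, with predicted probabilities clipped
#' to `[eps, 1 - eps]` (`eps = 1e-7`), averaged over herbs and over the
#' batch.
#'
#' @param y Binary labels (vector or matrix).
#' @param y_prime Predicted probabilities, same shape.
#' @param eps Clipping constant.
#' @return A nonnegative scalar.
#' @export
bce_loss <- function(y, y_prime, eps = 1e-7) {
  if (length(y) != length(y_prime)) abort("bce_loss: length mismatch")
  if (!all(y %in% c(0, 1))) abort("bce_loss: labels must be 0/1")
  p <- pmin(pmax(y_prime, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# Multi-hot design matrices for a record set against fixed vocab orders.
records_design <- function(records, sym_terms, herb_terms) {
  n <- nrow(records)
  P <- matrix(0, n, length(sym_terms))
  Y <- matrix(0, n, length(herb_terms))
  for (i in seq_len(n)) {
    si <- match(records$symptoms[[i]], sym_terms)
    hi <- match(records$herbs[[i]], herb_terms)
    if (anyNA(si)) {
      abort(paste0("symptom(s) missing from E_s: ",
                   paste(records$symptoms[[i]][is.na(si)], collapse = ", ")))
    }
    if (anyNA(hi)) {
      abort(paste0("herb(s) missing from E_h: ",
                   paste(records$herbs[[i]][is.na(hi)], collapse = ", ")))
    }
    P[i, si] <- 1
    Y[i, hi] <- 1
  }
  list(P = P, Y = Y)
}

#' Train the neural collaborative filtering recommender
#'
#' Trains the two branch MLPs (embeddings stay frozen) on the full multi-hot
#' herb labels with mean binary cross-entropy over all herbs — no negative
#' sampling — plus L2 weight decay. Full-batch Adam with early stopping on
#' the training loss; the best parameters seen are kept.
#'
#' @param records Training [clinical_records].
#' @param embeddings An `embedding_table` covering every term in `records`.
#' @param config A [recommender_config()].
#' @return A `herb_recommender`: branch networks, frozen embeddings, the
#'   training-loss trace and config.
#' @export
train_recommender <- function(records, embeddings, config = recommender_config()) {
  records <- clinical_records(records)
  if (!nrow(records)) abort("train_recommender: empty training set")
  E_s <- embeddings$E_s; E_h <- embeddings$E_h
  des <- records_design(records, rownames(E_s), rownames(E_h))
  P <- des$P; Y <- des$Y
  n <- nrow(P); n_h <- nrow(E_h)
  pooled <- (P / rowSums(P)) %*% E_s  # mean over each patient's active rows
  cfg <- config

  with_seed(cfg$seed, {
    mlp_s <- nn_init(nn_stack_dims(ncol(E_s), cfg$out_width, cfg$depth_s, cfg$hidden),
                     rep("relu", cfg$depth_s))
    mlp_h <- nn_init(nn_stack_dims(ncol(E_h), cfg$out_width, cfg$depth_h, cfg$hidden),
                     rep("relu", cfg$depth_h))

    loss_of <- function(ms, mh) {
      Zp <- nn_forward(ms, pooled)$out
      Zh <- nn_forward(mh, E_h)$out
      p <- 1 / (1 + exp(-(Zp %*% t(Zh))))
      bce_loss(Y, p) + cfg$lambda * (nn_sq_norm(ms) + nn_sq_norm(mh))
    }
    trace <- loss_of(mlp_s, mlp_h)
    best <- list(mlp_s = mlp_s, mlp_h = mlp_h, loss = trace)
    st_s <- nn_adam_init(mlp_s); st_h <- nn_adam_init(mlp_h)
    stale <- 0L; epoch <- 0L
    while (epoch < cfg$max_epochs) {
      epoch <- epoch + 1L
      cs <- nn_forward(mlp_s, pooled, dropout = cfg$dropout, training = TRUE)
      ch <- nn_forward(mlp_h, E_h, dropout = cfg$dropout, training = TRUE)
      Zp <- cs$out; Zh <- ch$out
      p <- 1 / (1 + exp(-(Zp %*% t(Zh))))
      dlogits <- (p - Y) / (n * n_h)   # grad of mean BCE through the sigmoid
      bp_s <- nn_backward(mlp_s, cs, dlogits %*% Zh)
      bp_h <- nn_backward(mlp_h, ch, t(dlogits) %*% Zp)
      g_s <- nn_add_grads(bp_s$grads, nn_l2_grads(mlp_s, cfg$lambda))
      g_h <- nn_add_grads(bp_h$grads, nn_l2_grads(mlp_h, cfg$lambda))
      st <- nn_adam_step(mlp_s, g_s, st_s, lr = cfg$lr)
      mlp_s <- st$net; st_s <- st$state
      st <- nn_adam_step(mlp_h, g_h, st_h, lr = cfg$lr)
      mlp_h <- st$net; st_h <- st$state

      loss_now <- loss_of(mlp_s, mlp_h)
      if (!is.finite(loss_now)) {
        abort(sprintf("train_recommender: non-finite loss at epoch %d", epoch))
      }
      trace <- c(trace, loss_now)
      if (loss_now < best$loss - 1e-12) {
        best <- list(mlp_s = mlp_s, mlp_h = mlp_h, loss = loss_now)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    structure(list(
      mlp_s = best$mlp_s, mlp_h = best$mlp_h,
      E_s = E_s, E_h = E_h,
      symptom_terms = rownames(E_s), herb_terms = rownames(E_h),
      config = cfg, loss_trace = trace, epochs_run = epoch,
      best_loss = best$loss
    ), class = "herb_recommender")
  })
}

#' @exportS3Method
print.herb_recommender <- function(x, ...) {
  cat(sprintf(
    "<herb_recommender> %d symptoms, %d herbs, d=%d, width=%d; %d epochs, loss %.5g\n",
    length(x$symptom_terms), length(x$herb_terms), ncol(x$E_s),
    x$config$out_width, x$epochs_run, x$best_loss))
  invisible(x)
}

#' @export
tidy.herb_recommender <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace) - 1L, loss = x$loss_trace)
}

#' @export
glance.herb_recommender <- function(x, ...) {
  tibble(n_symptoms = length(x$symptom_terms), n_herbs = length(x$herb_terms),
         d = ncol(x$E_s), out_width = x$config$out_width,
         epochs_run = x$epochs_run, best_loss = x$best_loss)
}

#' Rank herbs for a symptom set
#'
#' Scores every herb for the patient and returns the ranking: descending
#' probability, ties broken by ascending herb vocabulary index, so the
#' top-`K1` list is always a prefix of the top-`K2` list for `K1 <= K2`.
#' Symptoms unknown to the vocabulary are dropped with a warning; if none
#' remain it is an error.
#'
#' @param model A trained `herb_recommender`.
#' @param symptoms Character vector of symptom terms.
#' @param k How many herbs to return (default: all).
#' @return A `ranked_prescription` tibble: `rank`, `herb`, `probability`,
#'   with attributes `k` and `symptoms_used`.
#' @export
recommend <- function(model, symptoms, k = NULL) {
  known <- symptoms %in% model$symptom_terms
  if (any(!known)) {
    warn(paste0("dropping unknown symptom(s): ",
                paste(symptoms[!known], collapse = ", ")))
  }
  symptoms <- symptoms[known]
  if (!length(symptoms)) abort("recommend: no known symptoms in input")
  if (is.null(k)) k <- length(model$herb_terms)
  if (k < 1L) abort("k must be >= 1")
  k <- min(k, length(model$herb_terms))
  Z_p <- patient_embedding(symptoms, model$E_s, model$mlp_s)
  Z_h <- herb_embeddings(model$E_h, model$mlp_h)
  prob <- score_herbs(Z_p, Z_h)
  ord <- order(-prob, seq_along(prob))
  out <- tibble(
    rank = seq_len(k),
    herb = model$herb_terms[ord[seq_len(k)]],
    probability = unname(prob[ord[seq_len(k)]])
  )
  attr(out, "k") <- k
  attr(out, "symptoms_used") <- symptoms
  class(out) <- c("ranked_prescription", class(out))
  out
}

#' Top-K herb sets for a batch of records
#'
#' @param model A trained `herb_recommender`.
#' @param records [clinical_records] to score.
#' @param k List length per record.
#' @return A tibble `record_id`, `herbs` (list-column of top-k herb sets),
#'   `truth` (list-column of the records' herb sets).
#' @export
recommend_topk <- function(model, records, k) {
  records <- clinical_records(records)
  Z_h <- herb_embeddings(model$E_h, model$mlp_h)
  preds <- lapply(records$symptoms, function(s) {
    s <- s[s %in% model$symptom_terms]
    if (!length(s)) return(character(0))
    prob <- score_herbs(patient_embedding(s, model$E_s, model$mlp_s), Z_h)
    ord <- order(-prob, seq_along(prob))
    model$herb_terms[ord[seq_len(min(k, length(prob)))]]
  })
  tibble(record_id = records$record_id, herbs = preds, truth = records$herbs)
}

#' Seeded random top-K baseline
#'
#' Draws, for each of `n` patients, `k` herbs uniformly without replacement —
#' the chance-level ranker that a trained model must beat.
#'
#' @param herb_terms Herb vocabulary.
#' @param n Number of patients.
#' @param k List length.
#' @param seed Integer seed.
#' @return List of `n` character vectors.
#' @export
random_recommendations <- function(herb_terms, n, k, seed = 1L) {
  k <- min(k, length(herb_terms))
  with_seed(seed, lapply(seq_len(n), function(i) sample(herb_terms, k)))
}

#' Save and load a recommender checkpoint
#'
#' A checkpoint is a single JSON file holding every parameter array, the
#' frozen embeddings, the config, and the vocabularies. `load_recommender()`
#' validates internal consistency and, when `vocabs` is supplied, refuses to
#' load a checkpoint whose vocabularies do not match.
#'
#' @param model A `herb_recommender`.
#' @param path Checkpoint file path.
#' @param vocabs Optional vocabularies (from [build_vocabularies()]) to
#'   check the checkpoint against.
#' @return `save_recommender()` the path, invisibly; `load_recommender()` the
#'   model.
#' @export
save_recommender <- function(model, path) {
  net_to_list <- function(net) list(
    activations = net$activations,
    layers = lapply(net$layers, function(ly) list(W = ly$W, b = ly$b))
  )
  payload <- list(
    format = "presrec_recommender_v1",
    mlp_s = net_to_list(model$mlp_s), mlp_h = net_to_list(model$mlp_h),
    E_s = model$E_s, E_h = model$E_h,
    symptom_terms = model$symptom_terms, herb_terms = model$herb_terms,
    config = unclass(model$config),
    loss_trace = model$loss_trace, epochs_run = model$epochs_run,
    best_loss = model$best_loss
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_recommender
#' @export
load_recommender <- function(path, vocabs = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(raw$format, "presrec_recommender_v1")) {
    abort("not a recommender checkpoint")
  }
  net_from_list <- function(x) {
    structure(list(
      activations = x$activations,
      layers = lapply(x$layers, function(ly) {
        list(W = as.matrix(ly$W), b = as.numeric(ly$b))
      })
    ), class = "nn_mlp")
  }
  E_s <- as.matrix(raw$E_s); rownames(E_s) <- raw$symptom_terms
  E_h <- as.matrix(raw$E_h); rownames(E_h) <- raw$herb_terms
  if (!is.null(vocabs)) {
    if (!identical(sort(raw$symptom_terms), sort(vocabs$symptoms$term)) ||
        !identical(sort(raw$herb_terms), sort(vocabs$herbs$term))) {
      abort("checkpoint vocabulary does not match the supplied vocabularies")
    }
  }
  structure(list(
    mlp_s = net_from_list(raw$mlp_s), mlp_h = net_from_list(raw$mlp_h),
    E_s = E_s, E_h = E_h,
    symptom_terms = raw$symptom_terms, herb_terms = raw$herb_terms,
    config = do.call(recommender_config, as.list(raw$config)),
    loss_trace = raw$loss_trace, epochs_run = raw$epochs_run,
    best_loss = raw$best_loss
  ), class = "herb_recommender")
}
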