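toy_embeddings <- function() {
  E_s <- rbind(s1 = c(1, 0, 2), s2 = c(3, 2, 0), s3 = c(0, 1, 1))
  E_h <- rbind(h1 = c(1, 1, 0), h2 = c(0, 2, 1))
  list(E_s = E_s, E_h = E_h)
}

test_that("patient embedding mean-pools active rows then applies the MLP", {
  e <- toy_embeddings()
  id <- identity_mlp(3)
  expect_equal(patient_embedding("s1", e$E_s, id), c(1, 0, 2))
  expect_equal(patient_embedding(c("s1", "s2"), e$E_s, id), c(2, 1, 1))
  # multi-hot input gives the same answer as the term interface
  expect_equal(patient_embedding(c(1, 1, 0), e$E_s, id),
               patient_embedding(c("s1", "s2"), e$E_s, id))
  # hand-set one-layer MLP over three active symptoms
  W <- matrix(c(1, -1, 0.5, 0, 2, -0.3), 3, 2)
  b <- c(0.1, -0.2)
  mlp <- structure(list(layers = list(list(W = W, b = b)),
                        activations = "relu"), class = "nn_mlp")
  pooled <- colMeans(e$E_s)
  expect_equal(patient_embedding(c("s1", "s2", "s3"), e$E_s, mlp),
               pmax(as.numeric(pooled %*% W) + b, 0))
  expect_error(patient_embedding(rep(0, 3), e$E_s, id), "no active symptoms")
  expect_error(patient_embedding("nope", e$E_s, id), "nope")
})

test_that("herb representations are the row-wise ReLU MLP of E_h", {
  e <- toy_embeddings()
  expect_equal(herb_embeddings(e$E_h, identity_mlp(3)), e$E_h)
  zero <- structure(list(layers = list(list(W = matrix(0, 3, 2), b = rep(0, 2))),
                         activations = "relu"), class = "nn_mlp")
  expect_equal(unname(herb_embeddings(e$E_h, zero)), matrix(0, 2, 2))
  W <- matrix(c(0.2, 1, -1, 0.4, -0.5, 2), 3, 2)
  b <- c(-0.1, 0.3)
  mlp <- structure(list(layers = list(list(W = W, b = b)),
                        activations = "relu"), class = "nn_mlp")
  manual <- pmax(sweep(e$E_h %*% W, 2, b, "+"), 0)
  expect_equal(herb_embeddings(e$E_h, mlp), manual)
})

test_that("scores are the sigmoid of patient-herb dot products", {
  expect_equal(score_herbs(c(1, 0), rbind(c(0, 5), c(0, -2))),
               c(0.5, 0.5))  # orthogonal rows
  expect_equal(score_herbs(1, matrix(log(3))), 0.75)  # sigmoid(ln 3) = 3/4
  withr::with_seed(6, {
    Zp <- runif(4); Zh <- matrix(rnorm(16), 4, 4)
    expect_equal(score_herbs(Zp, Zh),
                 as.numeric(1 / (1 + exp(-(Zh %*% Zp)))))
  })
  expect_error(score_herbs(c(1, 2, 3), matrix(0, 2, 2)), "widths disagree")
  expect_error(score_herbs(c(1, NaN), matrix(0, 2, 2)), "non-finite")
})

test_that("binary cross-entropy is the clipped per-term mean", {
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2))
  y <- c(1, 0, 1, 0); yp <- c(0.9, 0.2, 0.6, 0.4)
  manual <- mean(-(y * log(yp) + (1 - y) * log(1 - yp)))
  expect_equal(bce_loss(y, yp), manual)
  expect_gte(bce_loss(y, yp), 0)
  expect_error(bce_loss(c(1, 0), 0.5), "length mismatch")
  expect_error(bce_loss(c(1, 2), c(0.5, 0.5)), "0/1")
})

planted_model <- function(max_epochs = 400) {
  spec <- corpus_spec(
    n_source = 80, n_target = 80, n_symptoms_source = 30,
    n_symptoms_target = 25, symptom_overlap = 10, n_herbs_source = 20,
    n_herbs_target = 15, herb_overlap = 8, mean_symptoms_source = 5,
    mean_symptoms_target = 5, mean_herbs_source = 5, mean_herbs_target = 4,
    rule_strength = 1, noise = 0, seed = 31
  )
  recs <- generate_corpus(spec)
  v <- build_vocabularies(recs)
  emb <- list(
    E_s = seeded_embed(v$symptoms$term, 16, 101),
    E_h = seeded_embed(v$herbs$term, 16, 102)
  )
  cfg <- recommender_config(depth_s = 2, depth_h = 2, out_width = 16,
                            hidden = 16, max_epochs = max_epochs, seed = 7)
  list(recs = recs, vocabs = v, emb = emb,
       model = train_recommender(recs, emb, cfg))
}

seeded_embed <- function(terms, d, seed) {
  withr::with_seed(seed, {
    E <- matrix(rnorm(length(terms) * d), length(terms), d)
    rownames(E) <- terms
    E
  })
}

test_that("training is seeded and a zero-epoch run returns the initial model", {
  e <- toy_embeddings()
  recs <- clinical_records(tibble::tibble(
    record_id = c("a", "b"), domain = c("source", "target"),
    symptoms = list("s1", c("s2", "s3")), herbs = list("h1", "h2")
  ))
  cfg0 <- recommender_config(depth_s = 2, depth_h = 2, out_width = 4,
                             hidden = 4, max_epochs = 0, seed = 3)
  m0a <- train_recommender(recs, e, cfg0)
  m0b <- train_recommender(recs, e, cfg0)
  expect_identical(m0a$mlp_s, m0b$mlp_s)
  expect_length(m0a$loss_trace, 1)

  cfg <- recommender_config(depth_s = 2, depth_h = 2, out_width = 4,
                            hidden = 4, max_epochs = 50, seed = 3)
  m1 <- train_recommender(recs, e, cfg)
  m2 <- train_recommender(recs, e, cfg)
  expect_identical(m1$best_loss, m2$best_loss)
  expect_lte(m1$best_loss, m1$loss_trace[1])

  bad <- recs; bad$herbs[[1]] <- "h99"
  expect_error(train_recommender(bad, e, cfg), "h99")
})

test_that("a planted symptom-herb rule is recovered by training", {
  # each herb is prescribed iff its fixed trigger symptom is present
  n_sym <- 16
  recs <- withr::with_seed(31, {
    syms <- sprintf("s%02d", 1:n_sym)
    herbs <- sprintf("h%02d", 1:n_sym)
    r <- tibble::tibble(
      record_id = paste0("r", 1:300),
      domain = rep(c("source", "target"), length.out = 300),
      symptoms = lapply(1:300, function(i) sample(syms, sample(2:4, 1))),
      herbs = list(NULL)
    )
    r$herbs <- lapply(r$symptoms, function(s) herbs[match(s, syms)])
    clinical_records(r)
  })
  v <- build_vocabularies(recs)
  emb <- list(E_s = seeded_embed(v$symptoms$term, 32, 101),
              E_h = seeded_embed(v$herbs$term, 32, 102))
  cfg <- recommender_config(depth_s = 1, depth_h = 1, out_width = 128,
                            hidden = 128, max_epochs = 3000, lr = 3e-3,
                            lambda = 0, patience = 1e9, seed = 7)
  model <- train_recommender(recs, emb, cfg)
  # every prescribed (= triggered) herb should rank above the median herb
  checks <- unlist(lapply(seq_len(nrow(recs)), function(i) {
    rk <- recommend(model, recs$symptoms[[i]])
    vapply(recs$herbs[[i]], function(h) which(rk$herb == h) <= n_sym / 2,
           logical(1))
  }))
  expect_gt(length(checks), 100)
  expect_gte(mean(checks), 0.9)
})

test_that("rankings are deterministic, prefix-nested and tie-broken by index", {
  fit <- planted_model(max_epochs = 30)
  m <- fit$model
  syms <- fit$recs$symptoms[[1]]
  all_ranked <- recommend(m, syms)
  expect_setequal(all_ranked$herb, m$herb_terms)  # K >= n_h: a permutation
  expect_equal(all_ranked$probability, sort(all_ranked$probability, decreasing = TRUE))
  top3 <- recommend(m, syms, k = 3)
  expect_equal(top3$herb, all_ranked$herb[1:3])   # prefix property

  # unknown symptoms drop with a warning; all-unknown errors
  expect_warning(r <- recommend(m, c(syms[1], "zzz"), k = 2), "zzz")
  expect_equal(r$herb, recommend(m, syms[1], k = 2)$herb)
  expect_error(suppressWarnings(recommend(m, "zzz")), "no known symptoms")

  # deterministic tie-break on equal scores: lower vocabulary index first
  e <- toy_embeddings()
  tie_model <- structure(list(
    mlp_s = identity_mlp(3), mlp_h = identity_mlp(3),
    E_s = e$E_s, E_h = rbind(h1 = c(1, 1, 0), h2 = c(1, 1, 0)),
    symptom_terms = rownames(e$E_s), herb_terms = c("h1", "h2"),
    config = recommender_config(seed = 1), loss_trace = 0, epochs_run = 0L,
    best_loss = 0
  ), class = "herb_recommender")
  rk <- recommend(tie_model, "s1")
  expect_equal(rk$herb, c("h1", "h2"))
})

test_that("scores ignore the ordering of inactive symptoms", {
  e <- toy_embeddings()
  id <- identity_mlp(3)
  Zh <- herb_embeddings(e$E_h, id)
  p1 <- score_herbs(patient_embedding(c(1, 0, 1), e$E_s, id), Zh)
  perm <- c(3, 2, 1)
  p2 <- score_herbs(patient_embedding(c(1, 0, 1)[perm], e$E_s[perm, ], id), Zh)
  expect_equal(p1, p2)
})

test_that("checkpoints round-trip and refuse mismatched vocabularies", {
  fit <- planted_model(max_epochs = 20)
  path <- withr::local_tempfile(fileext = ".json")
  save_recommender(fit$model, path)
  back <- load_recommender(path, vocabs = fit$vocabs)
  syms <- fit$recs$symptoms[[5]]
  expect_equal(recommend(back, syms, k = 5)$herb,
               recommend(fit$model, syms, k = 5)$herb)
  expect_equal(back$E_h, fit$model$E_h)

  other <- build_vocabularies(toy_corpus())
  expect_error(load_recommender(path, vocabs = other), "does not match")
})
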