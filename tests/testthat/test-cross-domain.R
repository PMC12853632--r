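test_that("encode_decode matches a pencil-and-paper two-layer evaluation", {
  z <- autoencoder_params(W1 = matrix(0, 3, 2), b1 = rep(0, 2),
                          W2 = matrix(0, 2, 3), b2 = rep(0, 3))
  expect_equal(encode_decode(c(1, 2, 3), z), rep(0, 3))

  id <- autoencoder_params(diag(3), rep(0, 3), diag(3), rep(0, 3))
  expect_equal(encode_decode(c(1, 0, 2), id), c(1, 0, 2))

  W1 <- matrix(c(0.5, -1, 0.2, 0.3, 0.1, -0.4), 3, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1, -0.5, 0.3, 0.2, -1, 0.8), 2, 3)
  b2 <- c(0.05, -0.1, 0.2)
  p <- autoencoder_params(W1, b1, W2, b2)
  y <- c(2, 1, 3)
  expect_equal(encode_decode(y, p), oracle_autoencode(y, W1, b1, W2, b2))
  expect_true(all(encode_decode(y, p) >= 0))
  expect_error(encode_decode(c(1, 2), p), "input_dim")
})

test_that("the masked square loss sums observed residuals plus the penalty", {
  id <- autoencoder_params(diag(2), rep(0, 2), diag(2), rep(0, 2))
  expect_equal(cdl_loss(c(3, 4), id), 0)  # perfect reconstruction, alpha 0

  z <- autoencoder_params(matrix(0, 3, 2), rep(0, 2), matrix(0, 2, 3), rep(0, 3))
  expect_equal(cdl_loss(c(3, 4, 0), z), 25)  # 9 + 16 on the observed entries

  withr::with_seed(11, {
    W1 <- matrix(rnorm(6), 3, 2); b1 <- rnorm(2)
    W2 <- matrix(rnorm(6), 2, 3); b2 <- rnorm(3)
    y <- matrix(rpois(12, 2), 4, 3)
    p <- autoencoder_params(W1, b1, W2, b2, alpha = 0.5)
    manual <- sum(vapply(1:4, function(i) {
      yhat <- oracle_autoencode(y[i, ], W1, b1, W2, b2)
      sum(((yhat - y[i, ])[y[i, ] != 0])^2)
    }, numeric(1))) +
      0.5 * (sum(W1^2) + sum(W2^2) + sum(b1^2) + sum(b2^2))
    expect_equal(cdl_loss(y, p), manual)
  })
})

test_that("unobserved positions never contribute to the masked loss", {
  withr::with_seed(4, {
    W1 <- matrix(rnorm(8), 4, 2); W2 <- matrix(rnorm(8), 2, 4)
    p <- autoencoder_params(W1, rnorm(2), W2, rnorm(4))
    y <- matrix(c(2, 0, 1, 0), 1)
    yhat <- encode_decode(y, p)
    # an all-unobserved mask leaves only the (zero here) penalty term
    expect_equal(cdl_loss(y, p, matrix(FALSE, 1, 4)), 0)
    # unmasking one extra position adds exactly that position's residual
    m1 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 1)
    m2 <- m1; m2[2] <- TRUE
    expect_equal(cdl_loss(y, p, m2) - cdl_loss(y, p, m1),
                 (yhat[2] - y[2])^2)
  })
})

test_that("autoencoder training is seeded, improving and early-stopping", {
  withr::with_seed(2, x <- outer(runif(12, 1, 3), runif(8, 1, 3)))  # rank 1

  ae0 <- train_autoencoder(x, latent_dim = 3, max_epochs = 0, seed = 5)
  ae0b <- train_autoencoder(x, latent_dim = 3, max_epochs = 0, seed = 5)
  expect_identical(ae0$net, ae0b$net)      # no-op training, seeded init
  expect_length(ae0$loss_trace, 1)

  ae <- train_autoencoder(x, latent_dim = 3, alpha = 0, max_epochs = 2000,
                          patience = 50, seed = 5)
  expect_lte(ae$best_loss, ae$loss_trace[1])  # never worse than initial
  recon <- encode_decode(x, ae)
  mask <- x != 0
  zero_loss <- sum(x[mask]^2)
  expect_lt(sum(((recon - x) * mask)^2), 0.1 * zero_loss)  # low-rank recovery

  ae2 <- train_autoencoder(x, latent_dim = 3, alpha = 0, max_epochs = 2000,
                           patience = 50, seed = 5)
  expect_identical(ae$loss_trace, ae2$loss_trace)  # same seed, same trajectory
})

test_that("latent features are the nonnegative encoder half", {
  z <- autoencoder_params(matrix(0, 3, 2), rep(0, 2), matrix(0, 2, 3), rep(0, 3))
  expect_equal(latent_features(c(1, 2, 3), z), rep(0, 2))

  W1 <- matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2)
  b1 <- c(-0.5, 1)
  p <- autoencoder_params(W1, b1, matrix(0, 2, 3), rep(0, 3))
  y <- c(1, 2, 3)
  expect_equal(latent_features(y, p), pmax(as.numeric(y %*% W1) + b1, 0))
  withr::with_seed(8, {
    for (i in 1:5) {
      expect_true(all(latent_features(runif(3, -5, 5), p) >= 0))
    }
  })
})

test_that("the composite adversarial loss decomposes term by term", {
  withr::with_seed(21, {
    f <- matrix(runif(12), 4, 3)
    targ <- matrix(runif(12), 4, 3)
    doms <- c("source", "source", "target", "target")

    p0 <- cpm_params(3, depth = 2, hidden = 4, mu = 0, lambda = 0, seed = 1)
    # mu = lambda = 0 leaves the prediction loss alone
    g <- nn_forward_oracle(p0$extractor, f)
    r <- nn_forward_oracle(p0$predictor, g)
    expect_equal(cpm_loss(f, targ, doms, p0), sum((r - targ)^2))

    # a perfect rating predictor with lambda = 0 leaves -mu * domain loss
    p1 <- cpm_params(3, depth = 1, hidden = 4, mu = 2, lambda = 0, seed = 2)
    p1$extractor <- identity_mlp(3)
    p1$predictor <- identity_mlp(3)
    pc <- nn_forward_oracle(p1$classifier, f)
    pc <- pmin(pmax(pc, 1e-7), 1 - 1e-7)
    t_lab <- c(0, 0, 1, 1)
    dom_loss <- -sum(t_lab * log(pc) + (1 - t_lab) * log(1 - pc))
    expect_equal(cpm_loss(f, f, doms, p1), -2 * dom_loss)

    # full brute-force evaluation with all three terms active
    p2 <- cpm_params(3, depth = 2, hidden = 4, mu = 0.7, lambda = 0.3, seed = 3)
    g2 <- nn_forward_oracle(p2$extractor, f)
    r2 <- nn_forward_oracle(p2$predictor, g2)
    pc2 <- pmin(pmax(nn_forward_oracle(p2$classifier, g2), 1e-7), 1 - 1e-7)
    manual <- sum((r2 - targ)^2) -
      0.7 * (-sum(t_lab * log(pc2) + (1 - t_lab) * log(1 - pc2))) +
      0.3 * (sq_norm_oracle(p2$extractor) + sq_norm_oracle(p2$predictor) +
               sq_norm_oracle(p2$classifier))
    expect_equal(cpm_loss(f, targ, doms, p2), manual)

    expect_error(cpm_loss(f, targ, c("source", "x", "target", "target"), p2),
                 "source")
  })
})

test_that("adversarial training confuses a domain probe on shifted Gaussians", {
  withr::with_seed(1, {
    n <- 80; d <- 8
    fs <- matrix(rnorm(n * d, mean = 0), n, d)
    ft <- matrix(rnorm(n * d, mean = 1.5), n, d)
  })
  doms <- rep(c("source", "target"), c(80, 80))

  cpm0 <- train_cpm(fs, ft, mu = 5, max_epochs = 0, seed = 5)
  expect_equal(cpm0$refined, cpm_extract(cpm0, rbind(fs, ft)))  # pass-through

  cpm1 <- train_cpm(fs, ft, mu = 5, max_epochs = 1000, patience = 1e9, seed = 5)
  acc0 <- domain_probe_accuracy(cpm0$refined, doms)
  acc1 <- domain_probe_accuracy(cpm1$refined, doms)
  expect_lt(abs(acc1 - 0.5), abs(acc0 - 0.5))

  cpm2 <- train_cpm(fs, ft, mu = 5, max_epochs = 1000, patience = 1e9, seed = 5)
  expect_identical(cpm1$refined, cpm2$refined)  # same seed, same outputs
  expect_equal(nrow(cpm1$refined), 160)         # a feature for every entity
})

test_that("embedding assembly keeps single-domain vectors and averages overlaps", {
  recs <- clinical_records(tibble::tibble(
    record_id = c("a", "b"), domain = c("source", "target"),
    symptoms = list(c("s1", "s2"), c("s2", "s3")),
    herbs = list(c("h1", "h2"), c("h2", "h3"))
  ))
  v <- build_vocabularies(recs)
  mk <- function(terms, val) {
    m <- matrix(val, length(terms), 2, byrow = TRUE)
    rownames(m) <- terms
    m
  }
  sym <- list(source = rbind(s1 = c(1, 2), s2 = c(3, 4)),
              target = rbind(s2 = c(5, 6), s3 = c(7, 8)))
  herb <- list(source = rbind(h1 = c(1, 1), h2 = c(2, 2)),
               target = rbind(h2 = c(2, 2), h3 = c(4, 4)))
  emb <- assemble_embeddings(sym, herb, v)
  expect_equal(emb$E_s["s1", ], c(1, 2))            # source-only: verbatim
  expect_equal(emb$E_s["s3", ], c(7, 8))            # target-only: verbatim
  expect_equal(emb$E_s["s2", ], c(4, 5))            # overlap: (u + v) / 2
  expect_equal(emb$E_h["h2", ], c(2, 2))            # identical vectors: idempotent

  cc <- assemble_embeddings(sym, herb, v, overlap = "concat")
  expect_equal(cc$E_s["s2", ], c(3, 4, 5, 6))
  expect_equal(cc$d, 4)

  sym_bad <- list(source = sym$source[1, , drop = FALSE], target = sym$target)
  sym_bad$source <- sym$source["s1", , drop = FALSE]
  sym_bad$target <- sym$target["s3", , drop = FALSE]
  expect_error(assemble_embeddings(sym_bad, herb, v), "s2")
})

test_that("embedding TSV export round-trips exactly", {
  withr::with_seed(3, {
    E <- matrix(rnorm(12) * 10^sample(-8:8, 12, TRUE), 3, 4)
  })
  rownames(E) <- c("甘草", "mint", "h3")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(E, path)
  expect_identical(read_embeddings(path), E)
})
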