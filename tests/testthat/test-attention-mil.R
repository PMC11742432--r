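test_that("identity-configured embedding reproduces its input", {
  m <- mil_model(3, hidden_dim = 3, attention_dim = 2, seed = 1)
  m$params$W1 <- diag(3); m$params$b1 <- rep(0, 3)
  m$params$W2 <- diag(3); m$params$b2 <- rep(0, 3)
  x <- c(0.5, 1.2, 0.1)          # nonnegative, so ReLU is the identity
  expect_equal(as.numeric(embed(x, m)), x)
  expect_equal(as.numeric(embed(rep(0, 3), m)), rep(0, 3))
  expect_error(embed(c(1, 2), m), "dimension mismatch")
})

test_that("embedding equals direct per-layer recomputation", {
  set.seed(4)
  m <- mil_model(6, hidden_dim = 4, attention_dim = 3, seed = 4)
  X <- matrix(rnorm(12), 2, 6)
  manual <- pmax(X %*% m$params$W1 +
                   matrix(m$params$b1, 2, 4, byrow = TRUE), 0)
  manual <- pmax(manual %*% m$params$W2 +
                   matrix(m$params$b2, 2, 4, byrow = TRUE), 0)
  expect_equal(embed(X, m), manual, tolerance = 1e-12)
})

test_that("attention scores follow w' tanh(V h) per instance", {
  m <- mil_model(4, hidden_dim = 3, attention_dim = 2, seed = 7)
  H <- matrix(rnorm(9), 3, 3)
  atts <- attention_scores(H, m)
  manual <- vapply(seq_len(3), function(j) {
    sum(m$params$w_att * tanh(m$params$V %*% H[j, ]))
  }, numeric(1))
  expect_equal(atts, manual, tolerance = 1e-12)
  # V = 0 kills every score; identical rows give identical scores
  m0 <- m; m0$params$V <- m$params$V * 0
  expect_equal(attention_scores(H, m0), rep(0, 3))
  H2 <- rbind(H[1, ], H[1, ])
  expect_equal(attention_scores(H2, m)[1], attention_scores(H2, m)[2])
})

test_that("attention weights are a shift-invariant softmax", {
  expect_equal(attention_weights(5), 1)
  expect_equal(attention_weights(rep(2.2, 4)), rep(0.25, 4))
  expect_equal(attention_weights(c(0, log(3))), c(0.25, 0.75))
  a <- attention_weights(c(-1, 0.5, 2))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_equal(attention_weights(c(-1, 0.5, 2) + 100), a, tolerance = 1e-12)
})

test_that("pooling is the attention-weighted instance average", {
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(pool(H, c(0, 1, 0, 0)), H[2, ])
  Hsame <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(pool(Hsame, c(0.1, 0.2, 0.3, 0.4)), c(1, 2, 3))
  a <- attention_weights(rnorm(4))
  manual <- colSums(H * a)
  expect_equal(pool(H, a), manual, tolerance = 1e-12)
  expect_error(pool(H, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("bag score is the logistic classifier on the pooled embedding", {
  m <- mil_model(3, hidden_dim = 3, seed = 2)
  m$params$w_cls <- rep(0, 3)
  expect_equal(bag_score(c(1, 2, 3), m), 0.5)
  m$params$w_cls <- c(1, 0, 0)
  expect_equal(bag_score(c(log(9), 5, -2), m), 0.9, tolerance = 1e-12)
  expect_lt(bag_score(c(0.2, 0, 0), m), bag_score(c(0.4, 0, 0), m))
})

test_that("MIL loss matches the Bernoulli negative log-likelihood", {
  expect_equal(loss_mil(0.5, 1), -log(0.5), tolerance = 1e-6)
  expect_equal(loss_mil(c(0.8, 0.2), c(1, 0)), 0.446287, tolerance = 1e-6)
  expect_lt(loss_mil(1 - 1e-7, 1), 1e-6)
  expect_error(loss_mil(0.5, 2), "labels")
})

test_that("full forward pass is permutation invariant", {
  set.seed(10)
  m <- mil_model(5, seed = 10)
  for (rep in 1:5) {
    X <- matrix(rnorm(7 * 5), 7, 5)
    fw <- bag_forward(X, m)
    expect_equal(sum(fw$a), 1, tolerance = 1e-6)
    perm <- sample(7)
    fw_p <- bag_forward(X[perm, ], m)
    expect_equal(fw_p$z, fw$z, tolerance = 1e-6)
    expect_equal(fw_p$P, fw$P, tolerance = 1e-6)
    expect_equal(fw_p$F, fw$F, tolerance = 1e-6)
    expect_equal(fw_p$f, fw$f[perm], tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences on a 2-bag toy", {
  set.seed(42)
  m <- mil_model(6, hidden_dim = 5, attention_dim = 4, seed = 3)
  X <- list(matrix(rnorm(24), 4, 6), matrix(rnorm(18), 3, 6))
  y <- c(1, 0)
  res <- pum6a:::pu_batch_gradients(m, X, y, lambda = 1e-3)
  num_grad <- function(nm, idx) {
    h <- 1e-5
    m1 <- m; m2 <- m
    m1$params[[nm]][idx] <- m1$params[[nm]][idx] + h
    m2$params[[nm]][idx] <- m2$params[[nm]][idx] - h
    r1 <- pum6a:::pu_batch_gradients(m1, X, y, lambda = 1e-3)
    r2 <- pum6a:::pu_batch_gradients(m2, X, y, lambda = 1e-3)
    ((r1$L_m + r1$L_p) - (r2$L_m + r2$L_p)) / (2 * h)
  }
  set.seed(1)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- if (length(p) > 1) sample(length(p), min(3, length(p))) else 1
    for (i in idx) {
      a <- res$grads[[nm]][i]
      n <- num_grad(nm, i)
      expect_lt(abs(a - n) / max(abs(n), 1e-6), 1e-4)
    }
  }
})

test_that("attention-removal ablation uses uniform weights end to end", {
  set.seed(5)
  m <- mil_model(4, attention = "none", seed = 5)
  X <- matrix(rnorm(6 * 4), 6, 4)
  fw <- bag_forward(X, m)
  expect_equal(fw$a, rep(1 / 6, 6))
  expect_true(fw$P > 0 && fw$P < 1)
  expect_true(fw$F >= 0 && fw$F <= 1)
})

test_that("checkpoints round-trip through the versioned JSON format", {
  set.seed(6)
  bags <- make_toy_bags(n_pos = 4, n_neg = 4, seed = 6)
  ds <- make_pu_scenario(bags, 1.0, seed = 6)
  fit <- train_pum6a(ds, train_config(epochs = 3, seed = 6))
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  X <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(bag_forward(X, m2)$F, bag_forward(X, fit$model)$F,
               tolerance = 1e-12)
  expect_identical(m2$pooling, fit$model$pooling)
  expect_identical(m2$bag_normalize, fit$model$bag_normalize)
  # corrupt the format tag
  txt <- sub("pumil-v1", "pumil-v9", readLines(path))
  writeLines(txt, path)
  expect_error(load_checkpoint(path), "unsupported checkpoint format")
})
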