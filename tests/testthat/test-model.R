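tiny_cfg <- function() {
  model_config(n_static = 3, n_timedep = 2,
               encoder_widths = c(4, 3, 3, 2, 2), hidden = 4, attn_dim = 3)
}

tiny_batch <- function(n = 5, seed = 42) {
  set.seed(seed)
  list(X = matrix(rnorm(n * 3), n, 3),
       Z = list(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2), n, 2)),
       y3 = rbinom(n, 1, 0.5), y6 = rbinom(n, 1, 0.5))
}

test_that("static encoder score is logistic and matches a loop-wise oracle", {
  set.seed(1)
  params <- cogconvert:::init_params(tiny_cfg())
  x <- rnorm(3)
  s <- encode_static(x, params)
  expect_gt(s, 0); expect_lt(s, 1)
  expect_equal(s, encoder_oracle(x, params), tolerance = 1e-6)

  # all-zero weights: logistic(0) = 0.5
  zero <- rapply(params, function(m) m * 0, how = "replace")
  expect_equal(encode_static(x, zero), 0.5)

  # batched rows agree with row-wise oracle
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(encode_static(X, params),
               apply(X, 1, encoder_oracle, params = params),
               tolerance = 1e-6)
})

test_that("scaled dot-product attention matches the direct softmax oracle", {
  # single key/value pair: weight exactly 1, context = V
  one <- attention(matrix(1:3, 1), matrix(rnorm(3), 1), matrix(5:7, 1))
  expect_equal(as.numeric(one$weights), 1)
  expect_equal(as.numeric(one$context), 5:7)

  # identical keys: uniform weights by symmetry
  K <- matrix(rep(c(1, 2), each = 4), 4, 2)
  u <- attention(matrix(c(1, 2), 1), K, matrix(rnorm(8), 4, 2))
  expect_equal(as.numeric(u$weights), rep(0.25, 4))

  set.seed(2)
  Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  got <- attention(Q, K, V)
  E <- exp(Q %*% t(K) / 2)                       # sqrt(4) = 2
  W <- E / rowSums(E)
  expect_equal(got$weights, W, tolerance = 1e-6)
  expect_equal(got$context, W %*% V, tolerance = 1e-6)
  expect_equal(rowSums(got$weights), rep(1, 3), tolerance = 1e-9)
  expect_true(all(got$weights >= 0))

  expect_error(attention(matrix(1, 1, 2), matrix(1, 1, 3), matrix(1, 1, 3)),
               "equal dimensionality")
  expect_error(attention(matrix(1, 1, 2), matrix(1, 2, 2), matrix(1, 3, 2)),
               "equal counts")
})

test_that("internal per-step attention rows sum to one and stay non-negative", {
  set.seed(3)
  params <- cogconvert:::init_params(tiny_cfg())
  b <- tiny_batch()
  fw <- cogconvert:::nn_forward(params, b$X, b$Z, b$y3)
  expect_equal(rowSums(fw$at2$weights), rep(1, 5), tolerance = 1e-9)
  expect_true(all(fw$at2$weights >= 0))
  expect_equal(as.numeric(fw$at1$weights), rep(1, 5), tolerance = 1e-9)
})

test_that("analytic gradients match central-difference differentiation", {
  for (seed in c(42, 7)) {
    set.seed(seed)
    params <- cogconvert:::init_params(tiny_cfg())
    b <- tiny_batch(seed = seed + 100)
    g <- cogconvert:::nn_grads(params, b$X, b$Z, b$y3, b$y6, b$y3)
    flat <- unlist(params)
    eps <- 1e-6
    num <- vapply(seq_along(flat), function(j) {
      up <- flat; up[j] <- up[j] + eps
      dn <- flat; dn[j] <- dn[j] - eps
      (cogconvert:::nn_loss(utils::relist(up, params), b$X, b$Z,
                            b$y3, b$y6, b$y3) -
         cogconvert:::nn_loss(utils::relist(dn, params), b$X, b$Z,
                              b$y3, b$y6, b$y3)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(unlist(g) - num)), 1e-7)
  }
})

test_that("forward pass is deterministic, in (0,1), and batching-invariant", {
  set.seed(4)
  params <- cogconvert:::init_params(tiny_cfg())
  b <- tiny_batch(n = 8)
  fw1 <- cogconvert:::nn_forward(params, b$X, b$Z, b$y3)
  fw2 <- cogconvert:::nn_forward(params, b$X, b$Z, b$y3)
  expect_identical(fw1$p6, fw2$p6)
  expect_true(all(fw1$p3 > 0 & fw1$p3 < 1))
  expect_true(all(fw1$p6 > 0 & fw1$p6 < 1))

  perm <- sample(8)
  fwp <- cogconvert:::nn_forward(params, b$X[perm, ],
                                 list(b$Z[[1]][perm, ], b$Z[[2]][perm, ]),
                                 b$y3[perm])
  expect_equal(fwp$p6, fw1$p6[perm], tolerance = 1e-6)
  expect_equal(fwp$p3, fw1$p3[perm], tolerance = 1e-6)
})

test_that("with a single time step the teacher-forcing signal is a no-op", {
  set.seed(5)
  params <- cogconvert:::init_params(tiny_cfg())
  b <- tiny_batch()
  a <- cogconvert:::nn_forward(params, b$X, b$Z[1])
  expect_identical(a$p3,
                   cogconvert:::nn_forward(params, b$X, b$Z[1], b$y3 * 0)$p3)
  expect_length(a$p6, 5)  # 6-month head applied to the baseline state
})

test_that("zeroed time-dependent inputs reduce the model to the static score", {
  set.seed(6)
  params <- cogconvert:::init_params(tiny_cfg())
  X <- rbind(rep(0.5, 3), rep(0.5, 3))
  Zz <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  fw <- cogconvert:::nn_forward(params, X, Zz, c(0, 0))
  expect_equal(fw$p6[1], fw$p6[2], tolerance = 1e-12)
  # different statics now give different outputs
  X2 <- rbind(rep(0.5, 3), rep(-2, 3))
  fw2 <- cogconvert:::nn_forward(params, X2, Zz, c(0, 0))
  expect_false(isTRUE(all.equal(fw2$p6[1], fw2$p6[2])))
})

make_training_cohort <- function(n = 80, seed = 13) {
  tab <- generate_cohort(planted_spec(n = n, seed = seed))
  lab <- label_conversion(tab)
  list(table = standardize_features(tab)$table, labels = lab)
}

test_that("training is seed-reproducible with a faithful history", {
  d <- make_training_cohort()
  cfg <- training_config(epochs = 1, restarts = 1, seed = 2)
  m1 <- train_conversion_model(d$table, d$labels, train_cfg = cfg)
  expect_equal(nrow(m1$history), 1)
  expect_equal(m1$selected_epoch, 1)

  cfg5 <- training_config(epochs = 5, restarts = 2, seed = 2)
  m2 <- train_conversion_model(d$table, d$labels, train_cfg = cfg5)
  m3 <- train_conversion_model(d$table, d$labels, train_cfg = cfg5)
  expect_identical(m2$params, m3$params)
  expect_identical(m2$history, m3$history)
  expect_equal(nrow(m2$history), 10)  # 2 restarts x 5 epochs
  expect_true(m2$selected_epoch %in% 1:5)
})

test_that("training refuses single-class labels", {
  d <- make_training_cohort(n = 40, seed = 14)
  lab <- d$labels
  lab$label[lab$month == 6] <- "CNI"  # degenerate 6-month outcome
  expect_error(
    train_conversion_model(d$table, lab,
                           train_cfg = training_config(epochs = 1,
                                                       restarts = 1)),
    "single-class")
})

test_that("training reduces loss on the planted-signal fixture", {
  d <- make_training_cohort(n = 150, seed = 15)
  m <- train_conversion_model(
    d$table, d$labels,
    train_cfg = training_config(epochs = 60, restarts = 1, seed = 3))
  h <- m$history
  expect_lt(h$loss[m$selected_epoch], h$loss[1])
  expect_lt(min(h$loss), h$loss[1])
})

test_that("prediction feeds the observed 3-month status when provided", {
  d <- make_training_cohort(n = 60, seed = 16)
  m <- train_conversion_model(
    d$table, d$labels,
    train_cfg = training_config(epochs = 10, restarts = 1, seed = 4))
  pr_own <- predict(m, d$table)
  pr_obs <- predict(m, d$table, labels3 = d$labels)
  expect_equal(pr_own$p3, pr_obs$p3)  # 3-month path unaffected
  expect_false(identical(pr_own$p6, pr_obs$p6))

  # withdrawal: length-1 sequence; observed labels must be ignored
  pr_w1 <- predict(m, d$table, withdraw_mid = TRUE)
  pr_w2 <- predict(m, d$table, labels3 = d$labels, withdraw_mid = TRUE)
  expect_identical(pr_w1, pr_w2)
  bad <- d$labels[d$labels$id %in% 1:5, ]
  expect_error(predict(m, d$table, labels3 = bad), "cover every patient")
})

test_that("JSON checkpoints restore a model that predicts identically", {
  d <- make_training_cohort(n = 40, seed = 17)
  m <- train_conversion_model(
    d$table, d$labels,
    train_cfg = training_config(epochs = 2, restarts = 1, seed = 5))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, d$table)$p6, predict(m, d$table)$p6,
               tolerance = 1e-12)
  expect_equal(m2$feature_names, m$feature_names)
})
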