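test_that("sinusoidal position embedding matches its closed form", {
  pe <- positionEmbedding(10, 8)
  expect_equal(pe[1, seq(1, 8, 2)], rep(0, 4)) # sin dims at pos 0
  expect_equal(pe[1, seq(2, 8, 2)], rep(1, 4)) # cos dims at pos 0
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[, 1], sin(0:9)) # i = 0: exponent 0
  expect_equal(pe[4, 3], sin(3 / 10000^(2 / 8)))
  expect_error(positionEmbedding(10, 7), "even")
})

test_that("uniform input combines motif and position embeddings", {
  u <- matrix(rnorm(12), 4, 3)
  pe <- matrix(rnorm(12), 4, 3)
  expect_equal(uniformInput(u, pe, alpha = 0), pe)
  expect_equal(uniformInput(u, pe, alpha = 1.5), 1.5 * u + pe)
  expect_equal(uniformInput(u, NULL, alpha = 2), 2 * u) # no-PE ablation
  expect_error(uniformInput(u, pe[1:2, ]), "shapes differ")
})

test_that("dependency measurement matches closed forms", {
  # constant scores: exact M = ln(L_K), sampled surrogate = 0
  Q <- matrix(1, 3, 1)
  K0 <- matrix(0, 7, 1)
  expect_equal(sparsityMeasurement(Q, K0, "exact"), rep(log(7), 3))
  expect_equal(sparsityMeasurement(matrix(1, 5, 2), matrix(2, 9, 2),
                                   "sampled", seed = 4), rep(0, 5))
  # d_h = 1, scores {2, 0}
  M <- sparsityMeasurement(matrix(1, 1, 1), matrix(c(2, 0), 2, 1), "exact")
  expect_equal(M, log(exp(2) + 1) - 1, tolerance = 1e-12)
  expect_error(sparsityMeasurement(Q, matrix(0, 0, 1)), "empty")
})

test_that("a key-score spike strictly increases the exact measurement", {
  set.seed(31)
  for (rep in 1:20) {
    Q <- matrix(rnorm(12 * 4), 12, 4)
    K <- matrix(rnorm(12 * 4), 12, 4)
    M0 <- sparsityMeasurement(Q, K, "exact")
    i <- sample(12, 1)
    Q2 <- Q
    Q2[i, ] <- Q2[i, ] + 8 * K[sample(12, 1), ] # spike one query's scores
    M1 <- sparsityMeasurement(Q2, K, "exact")
    expect_gt(M1[i], M0[i])
  }
})

test_that("probability-sparse attention reduces to dense attention at u = L", {
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(4:40, 1)
    dh <- sample(c(2, 4, 8), 1)
    Q <- matrix(rnorm(L * dh), L)
    K <- matrix(rnorm(L * dh), L)
    V <- matrix(rnorm(L * dh), L)
    expect_lt(max(abs(probDepAttention(Q, K, V, c = 100, mode = "exact") -
                      denseAttention(Q, K, V))), 1e-5)
  }
})

test_that("non-dominant queries receive the column mean of V", {
  set.seed(8)
  L <- 40
  Q <- matrix(rnorm(L * 4), L)
  K <- matrix(rnorm(L * 4), L)
  V <- matrix(rnorm(L * 4), L)
  out <- probDepAttention(Q, K, V, c = 0.3, mode = "exact") # u = 2
  vbar <- colMeans(V)
  devs <- apply(out, 1, function(r) max(abs(r - vbar)))
  expect_equal(sum(devs < 1e-6), L - 2)
  # single query-key pair: softmax of a scalar is 1
  expect_equal(probDepAttention(matrix(2, 1, 1), matrix(3, 1, 1),
                                matrix(5, 1, 1), c = 1),
               matrix(5, 1, 1))
})

test_that("dense attention oracle has the expected algebraic properties", {
  set.seed(9)
  Q <- matrix(rnorm(8 * 3), 8)
  V1 <- matrix(rnorm(3), 1)
  # single key: output is that value row regardless of Q
  out <- denseAttention(Q, matrix(rnorm(3), 1), V1)
  expect_equal(out, matrix(rep(V1, each = 8), 8))
  # jointly permuting key/value rows leaves the output unchanged
  K <- matrix(rnorm(6 * 3), 6)
  V <- matrix(rnorm(6 * 3), 6)
  p <- sample(6)
  expect_equal(denseAttention(Q, K, V), denseAttention(Q, K[p, ], V[p, ]))
})

test_that("binary cross-entropy matches hand arithmetic and is non-negative", {
  expect_equal(bceLoss(0.5, 1), log(2), tolerance = 1e-9)
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1e-6) # perfect, after clipping
  expect_equal(bceLoss(c(0.9, 0.1), c(1, 0)), -mean(log(c(0.9, 0.9))),
               tolerance = 1e-9)
  set.seed(10)
  for (rep in 1:20)
    expect_gte(bceLoss(runif(5, 0.01, 0.99), rbinom(5, 1, 0.5)), 0)
  expect_error(bceLoss(0.5, c(1, 0)), "lengths differ")
})

test_that("stem geometry follows the threshold rule", {
  g600 <- tokenGeometry(modelConfig(nCells = 2, inputLength = 600,
                                    embedDim = 8, heads = 2, layers = 1,
                                    stemThreshold = 5000))
  expect_equal(g600$stemStages, 0)
  expect_equal(g600$Ltok, 600)
  gLong <- tokenGeometry(modelConfig(nCells = 2, inputLength = 131072,
                                     embedDim = 8, heads = 2, layers = 1,
                                     stemThreshold = 5000))
  expect_equal(gLong$stemStages, 5) # 131072 / 2^5 = 4096
  expect_equal(gLong$Ltok, 4096)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_config(seed = 3)
  p <- initParameters(cfg, seed = 3)
  set.seed(1)
  B <- 2
  X <- random_onehot(16, B, seed = 2)@encoding
  Y <- matrix(rbinom(B * 5, 1, 0.5), B, 5)
  cl <- scAccessNet:::config_as_list(cfg)
  out <- scAccessNet:::.cpp_loss_grad(p, cl, X, Y, 1L)
  eps <- 1e-5
  worst <- 0
  for (nm in names(p)) {
    g <- out$grads[[nm]]
    v <- p[[nm]]
    for (i in sample(length(v), min(3, length(v)))) {
      p2 <- p
      p2[[nm]][i] <- v[i] + eps
      lp <- scAccessNet:::.cpp_loss_grad(p2, cl, X, Y, 1L)$loss
      p2[[nm]][i] <- v[i] - eps
      lm <- scAccessNet:::.cpp_loss_grad(p2, cl, X, Y, 1L)$loss
      worst <- max(worst, abs((lp - lm) / (2 * eps) - g[i]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("forward passes are finite, probabilistic, and deterministic", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  for (s in 1:100) {
    y <- predictAccessibility(m, random_onehot(16, 1, seed = s), seed = s)
    expect_true(all(is.finite(y)))
    expect_true(all(y > 0 & y < 1))
  }
  # all-zero input stays finite (bias-only path)
  zero <- new("OneHotBatch",
              encoding = array(0.25, c(16, 4, 1)), ids = "z")
  expect_true(all(is.finite(predictAccessibility(m, zero))))
  b <- random_onehot(16, 3, seed = 5)
  expect_identical(predictAccessibility(m, b, seed = 2),
                   predictAccessibility(m, b, seed = 2))
  cfgS <- tiny_config(measureMode = "sampled")
  mS <- tiny_model(cfgS)
  expect_identical(predictAccessibility(mS, b, seed = 2),
                   predictAccessibility(mS, b, seed = 2))
})

test_that("degenerate weights reduce the forward pass to known values", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  # zero final layer: sigmoid(0) = 0.5 everywhere
  m@params$Wp[] <- 0
  m@params$bp[] <- 0
  y <- predictAccessibility(m, random_onehot(16, 2, seed = 3))
  expect_equal(unname(y), matrix(0.5, 2, 5))
  # saturating intercepts drive probabilities to the corresponding corner
  m@params$bp[] <- 30
  expect_true(all(predictAccessibility(m, random_onehot(16, 1, seed = 3)) >
                  0.999))
})

test_that("early stopping halts patience epochs after the best and caps at max", {
  # labels independent of sequence: validation cannot keep improving
  cfg <- modelConfig(nCells = 4, inputLength = 16, embedDim = 8, heads = 2,
                     layers = 1, ffDim = 8, stemKernel = 3, convKernel = 3,
                     headKernel = 3, headFilters = 2, embeddingSize = 4,
                     patience = 3, maxEpochs = 25, seed = 6,
                     measureMode = "exact", samplingFactor = 50)
  set.seed(6)
  batch <- random_onehot(16, 30, seed = 7)
  Y <- matrix(rbinom(30 * 4, 1, 0.5), 30, 4)
  m <- trainAccessModel(batch, Y, cfg, trainIdx = 1:24, valIdx = 25:30,
                        restarts = 0)
  h <- trainingHistory(m)
  expect_lte(nrow(h), 25)
  if (nrow(h) < 25) # early-stopped: exactly patience epochs past the best
    expect_equal(nrow(h), which.min(h$val_loss) + cfg@patience)
})

test_that("cell embeddings are the transposed predictor weights plus depths", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  e <- cellEmbeddings(m)
  expect_equal(dim(e), c(5L, 4L))
  expect_equal(unname(e), t(m@params$Wp))
  expect_identical(e, cellEmbeddings(m)) # pure re-extraction
  expect_equal(unname(cellDepth(m)), as.numeric(m@params$bp))
})

test_that("auROC follows the Mann-Whitney rank formulation", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(aurocScore(c(0.2, 0.3, 0.8), c(1, 1, 0)), 0)
  expect_equal(aurocScore(c(0.9, 0.1, 0.5, 0.4), c(1, 0, 0, 1)), 0.75)
  expect_true(is.na(aurocScore(c(0.1, 0.9), c(1, 1))))
  set.seed(3)
  s <- rnorm(50)
  l <- rbinom(50, 1, 0.4)
  expect_equal(aurocScore(s, l),
               as.numeric(wilcox.test(s[l == 1], s[l == 0],
                                      exact = FALSE)$statistic) /
                 (sum(l) * sum(1 - l)))
})
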