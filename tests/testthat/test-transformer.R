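test_that("model configuration enforces the head-divisibility contract", {
  expect_error(model_config(heads = 7, d_model = 72), "divisible")
  cfg <- model_config()
  expect_equal(cfg$d_model, 72)
  expect_equal(cfg$ff_dim, 144)
})

test_that("interaction matrix has the contracted shape and is deterministic", {
  cfg <- model_config(d_model = 72)
  m <- init_model(cfg, seed = 3)
  withr::local_seed(5)
  Ea <- matrix(rnorm(3 * 72), 3, 72)
  Eb <- matrix(rnorm(2 * 72), 2, 72)
  X <- encode_decode(m, Ea, Eb)
  expect_equal(dim(X), c(72, 2))
  expect_true(all(is.finite(X)))
  expect_identical(X, encode_decode(m, Ea, Eb))
  expect_error(encode_decode(m, Ea[, 1:10], Eb), "does not match d_model")
})

test_that("token order does not affect the prediction (no positional order)", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, seed = 11)
  withr::local_seed(13)
  Ea <- matrix(rnorm(6 * 16), 6, 16)
  Eb <- matrix(rnorm(4 * 16), 4, 16)
  base <- forward_pair(m, Ea, Eb)
  for (i in 1:5) {
    pa <- sample(6); pb <- sample(4)
    out <- forward_pair(m, Ea[pa, ], Eb[pb, ])
    expect_lt(abs(out$prob - base$prob), 1e-5)
    # decoder outputs are the same set, permuted with the B tokens
    expect_lt(max(abs(out$X[, order(pb)] - base$X)), 1e-5)
  }
})

test_that("padded positions cannot influence scores or pooling", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, seed = 17)
  withr::local_seed(19)
  Ea <- matrix(rnorm(5 * 16), 5, 16)
  Eb <- matrix(rnorm(3 * 16), 3, 16)
  base <- forward_pair(m, Ea, Eb)
  for (fill in c(0, 7, -123)) {
    Eb_pad <- rbind(Eb, matrix(fill, 2, 16))
    Ea_pad <- rbind(Ea, matrix(-fill, 3, 16))
    out <- forward_pair(m, Ea_pad, Eb_pad,
                        mask_a = c(rep(TRUE, 5), rep(FALSE, 3)),
                        mask_b = c(rep(TRUE, 3), rep(FALSE, 2)))
    expect_equal(out$s, base$s, tolerance = 1e-10)
    expect_equal(out$y_pool, base$y_pool, tolerance = 1e-10)
    expect_equal(out$prob, base$prob, tolerance = 1e-12)
    expect_equal(dim(out$X), dim(base$X))
  }
})

test_that("column scores follow the softmax of squared column norms", {
  expect_equal(column_scores(cbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  s <- column_scores(cbind(c(2, 0), c(0, 1)))
  expect_equal(s, c(exp(4), exp(1)) / (exp(4) + exp(1)), tolerance = 1e-12)
  X <- matrix(rnorm(5), 5, 3)   # identical columns recycled
  expect_equal(column_scores(cbind(X[, 1], X[, 1], X[, 1])), rep(1 / 3, 3))
  expect_error(column_scores(matrix(0, 3, 0)), "no columns")
})

test_that("weighted pooling matches the brute-force double loop", {
  expect_equal(weighted_pool(cbind(c(1, 0), c(0, 1)), c(0.5, 0.5)), c(0.5, 0.5))
  withr::local_seed(23)
  for (i in 1:20) {
    X <- matrix(rnorm(20), 5, 4)
    s <- column_scores(X)
    yp <- weighted_pool(X, s)
    oracle <- numeric(5)
    for (r in 1:5) for (j in 1:4) oracle[r] <- oracle[r] + s[j] * X[r, j]
    expect_lt(max(abs(yp - oracle)), 1e-12)
    # joint column permutation leaves the pooled vector unchanged
    p <- sample(4)
    expect_equal(weighted_pool(X[, p], column_scores(X[, p])), yp,
                 tolerance = 1e-12)
  }
})

test_that("head equivalence holds on random interaction matrices", {
  withr::local_seed(29)
  for (i in 1:100) {
    m <- sample(2:8, 1); n <- sample(1:8, 1)
    X <- matrix(rnorm(m * n), m, n)
    # literal formulas by nested loops
    cn <- numeric(n)
    for (j in 1:n) for (r in 1:m) cn[j] <- cn[j] + X[r, j]^2
    s_lit <- exp(cn - max(cn)); s_lit <- s_lit / sum(s_lit)
    y_lit <- numeric(m)
    for (r in 1:m) for (j in 1:n) y_lit[r] <- y_lit[r] + X[r, j] * s_lit[j]
    expect_lt(max(abs(column_scores(X) - s_lit)), 1e-10)
    expect_lt(max(abs(weighted_pool(X, column_scores(X)) - y_lit)), 1e-10)
    expect_lt(abs(sum(column_scores(X)) - 1), 1e-6)
  }
})

test_that("the linear read-out and its limits", {
  expect_equal(predict_logit(rnorm(5), rep(0, 5), 0)$prob, 0.5)
  p <- predict_logit(rep(0.1, 10), rep(1, 10), 0)
  expect_equal(p$logit, 1)
  expect_equal(p$prob, 1 / (1 + exp(-1)), tolerance = 1e-10)
  expect_gt(predict_logit(1e3, 1, 0)$prob, 1 - 1e-12)
})

test_that("binary cross-entropy closed forms", {
  expect_equal(bce_loss(0, 1), log(2))
  expect_lt(bce_loss(20, 1), 1e-8)
  expect_equal(bce_loss(c(0, 0), c(1, 0)), log(2))
  expect_error(bce_loss(c(0, 0), c(1, 2)), "labels")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, seed = 31)
  withr::local_seed(37)
  Ea <- matrix(rnorm(4 * 16), 4, 16)
  Eb <- matrix(rnorm(3 * 16), 3, 16)
  out <- tspe:::batch_loss_grad(m, list(Ea), list(Eb), 1, 0, 1)
  loss_at <- function(p) {
    mm <- m; mm$params <- p
    tspe:::batch_loss_grad(mm, list(Ea), list(Eb), 1, 0, 1)$loss
  }
  eps <- 1e-5
  # the full head block plus a random sample across all layers
  np <- length(m$params)
  head_idx <- (np - 16):np
  idx <- unique(c(head_idx, sort(sample(np, 40))))
  for (i in idx) {
    p1 <- m$params; p1[i] <- p1[i] + eps
    p2 <- m$params; p2[i] <- p2[i] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_lt(abs(num - out$grad[i]) / max(abs(num) + abs(out$grad[i]), 1e-4),
              1e-4)
  }
})

test_that("a zeroed head predicts 0.5 and the pair order matters", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, seed = 41)
  m$params[(length(m$params) - 16):length(m$params)] <- 0
  withr::local_seed(43)
  Ea <- matrix(rnorm(4 * 16), 4, 16)
  Eb <- matrix(rnorm(4 * 16), 4, 16)
  expect_equal(forward_pair(m, Ea, Eb)$prob, 0.5)

  m2 <- init_model(cfg, seed = 41)
  f_ab <- forward_pair(m2, Ea, Eb)$prob
  f_ba <- forward_pair(m2, Eb, Ea)$prob
  expect_false(isTRUE(all.equal(f_ab, f_ba, tolerance = 1e-8)))
})
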