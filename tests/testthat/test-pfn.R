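# Patch fusion network: linear transform, attention heads, block stacking,
# attention scores, replicate aggregation and the classifier head.

test_that("linear transform matches the loop oracle and handles edge cases", {
  expect_equal(linear_transform(diag(3), matrix(1:6, 3, 2)), matrix(1:6, 3, 2))
  expect_equal(linear_transform(matrix(rnorm(12), 4, 3), matrix(0, 3, 2)),
               matrix(0, 4, 2))
  set.seed(1)
  for (rep in 1:5) {
    H <- matrix(rnorm(20), 4, 5)
    W <- matrix(rnorm(10), 5, 2)
    expect_lt(max(abs(linear_transform(H, W) - oracle_matmul(H, W))), 1e-10)
  }
  expect_error(linear_transform(matrix(0, 2, 3), matrix(0, 4, 1)),
               "dimension mismatch")
})

test_that("single-column attention reduces to the theta-scaled column", {
  H <- matrix(c(0.3, -0.2, 0.9), 3, 1)
  theta <- c(2, -1, 0.5)
  res <- attention_head(H, theta_m = rep(1, 3), theta_value = theta)
  expect_equal(res$alpha, 0)
  expect_equal(res$alpha_hat, 1)
  expect_equal(res$output, as.vector(H) * theta)
})

test_that("two symmetric columns get uniform attention weights", {
  h1 <- c(1, 0.5, -0.3); h2 <- c(0.2, -0.1, 0.8)
  H <- cbind(h1, h2)
  res <- attention_head(H, theta_m = rep(1, 3), theta_value = rep(1, 3))
  expect_equal(unname(res$alpha), rep(sum(h1 * h2) / 2, 2))
  expect_equal(unname(res$alpha_hat), c(0.5, 0.5))
  expect_equal(res$output, unname(0.5 * (h1 + h2)))
})

test_that("attention head agrees with the literal loop oracle", {
  set.seed(2)
  for (rep in 1:20) {
    c_in <- sample(2:8, 1); c_out <- sample(2:8, 1)
    H <- matrix(rnorm(c_in * c_out), c_in, c_out)
    tm <- rnorm(c_in); tv <- rnorm(c_in)
    got <- attention_head(H, tm, tv)
    want <- oracle_attention_head(H, tm, tv)
    expect_lt(max_rel_err(got$output, want$output), 1e-6)
    expect_lt(max_rel_err(got$alpha, want$alpha, 1e-8), 1e-6)
    expect_lt(abs(sum(got$alpha_hat) - 1), 1e-8)
  }
})

test_that("attention head rejects non-finite input", {
  H <- matrix(c(1, NA, 0, 1), 2, 2)
  expect_error(attention_head(H, rep(1, 2), rep(1, 2)), "non-finite")
})

test_that("building block composes transform, tanh and heads", {
  set.seed(3)
  block <- list(W = matrix(rnorm(15), 5, 3),
                theta_heads = matrix(rnorm(8), 4, 2),
                theta_value = rnorm(4))
  H <- matrix(rnorm(20), 4, 5)
  expect_lt(max_rel_err(building_block(H, block),
                        oracle_building_block(H, block)), 1e-6)
  # zero input: tanh(0) = 0, every head output is zero
  z <- building_block(matrix(0, 4, 5), block)
  expect_equal(z, matrix(0, 4, 2))
  # M = 1 reduces to a single head on the tanh-ed transform
  b1 <- list(W = block$W, theta_heads = block$theta_heads[, 1, drop = FALSE],
             theta_value = block$theta_value)
  A <- tanh(H %*% block$W)
  expect_equal(as.vector(building_block(H, b1)),
               attention_head(A, block$theta_heads[, 1], block$theta_value)$output)
})

test_that("full forward matches a hand-stepped oracle on random instances", {
  set.seed(4)
  cfg <- pfn_config(n_patches = 6, feature_dim = 5, c_out1 = 4, heads1 = 3,
                    c_out2 = 3, heads2 = 2)
  for (rep in 1:20) {
    params <- list(blocks = list(
      list(W = matrix(rnorm(20), 5, 4), theta_heads = matrix(rnorm(18), 6, 3),
           theta_value = rnorm(6)),
      list(W = matrix(rnorm(18), 6, 3), theta_heads = matrix(rnorm(6), 3, 2),
           theta_value = rnorm(3))))
    H <- matrix(rnorm(30), 6, 5)
    got <- pfn_forward(H, params, cfg)
    expect_length(got, cfg$embed_dim)
    expect_lt(max_rel_err(got, oracle_pfn_forward(H, params, cfg)), 1e-6)
  }
})

test_that("forward is deterministic and default widths give a 32-dim embedding", {
  cfg <- pfn_config(n_patches = 10, feature_dim = 8)
  expect_equal(cfg$embed_dim, 32L)   # 8 heads x 4 heads
  set.seed(5)
  params <- patchfuse:::init_pfn(cfg)
  H <- matrix(rnorm(80), 10, 8)
  expect_identical(pfn_forward(H, params, cfg), pfn_forward(H, params, cfg))
})

test_that("bag row count must match the configured sample size", {
  cfg <- tiny_pfn_config()
  set.seed(6)
  params <- patchfuse:::init_pfn(cfg)
  expect_error(pfn_forward(matrix(0, 4, 5), params, cfg), "configured for 6")
})

test_that("value-scaler scaling propagates exactly linearly", {
  set.seed(7)
  block <- list(W = matrix(rnorm(15), 5, 3),
                theta_heads = matrix(rnorm(8), 4, 2), theta_value = rnorm(4))
  H <- matrix(rnorm(20), 4, 5)
  base <- building_block(H, block)
  block2 <- block
  block2$theta_value <- 3.5 * block$theta_value
  expect_equal(building_block(H, block2), 3.5 * base)
})

test_that("attention scores are a proper distribution and match the oracle", {
  set.seed(8)
  cfg <- tiny_pfn_config()
  params <- patchfuse:::init_pfn(cfg)
  params <- patchfuse:::tree_map(function(x) x + rnorm(length(x), 0, 0.2), params)
  for (rep in 1:20) {
    H <- matrix(rnorm(30), 6, 5)
    sc <- attention_scores(H, params, cfg)
    expect_lt(abs(sum(sc) - 1), 1e-8)
    expect_true(all(sc >= 0))
    expect_lt(max_rel_err(sc, oracle_attention_scores(H, params)), 1e-6)
  }
  # identical patches get uniform scores (at the all-ones value scaler, which
  # is the seeded initialization; a non-constant scaler weights patch slots)
  fresh <- patchfuse:::init_pfn(cfg)
  H_same <- matrix(rep(rnorm(5), each = 6), 6, 5)
  expect_equal(attention_scores(H_same, fresh, cfg), rep(1 / 6, 6))
})

test_that("replicate aggregation sums duplicates then averages over replicates", {
  # one replicate is the identity (after duplicate grouping)
  one <- list(c(a = 0.4, b = 0.6))
  out <- aggregate_attention(one)
  expect_equal(out$mean_score[out$patch_id == "b"], 0.6)
  # a patch drawn twice in a replicate contributes both softmax slots
  dup <- list(c(a = 0.2, a = 0.3, b = 0.5))
  out <- aggregate_attention(dup)
  expect_equal(out$mean_score[out$patch_id == "a"], 0.5)
  # cross-replicate mean over the replicates where the patch was sampled
  two <- list(c(a = 0.1, b = 0.9), c(a = 0.3, c = 0.7))
  out <- aggregate_attention(two)
  expect_equal(out$mean_score[out$patch_id == "a"], 0.2)
  expect_equal(out$n_replicates[out$patch_id == "b"], 1L)
  # never-sampled patches are absent, not zero
  expect_false("z" %in% out$patch_id)
  expect_error(aggregate_attention(list()), "no replicates")
})

test_that("classifier probabilities form a simplex and are shift invariant", {
  set.seed(9)
  W <- matrix(rnorm(8), 2, 4); b <- rnorm(2)
  h <- rnorm(4)
  p <- classify(h, W, b)
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_true(all(p > 0 & p < 1))
  expect_equal(classify(h, W, b + 5), p)          # shift invariance
  expect_equal(classify(h, matrix(0, 2, 4), c(0, 0)), c(0.5, 0.5))
})
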