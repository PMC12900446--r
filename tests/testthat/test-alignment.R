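# Alignment criteria: analytic zero/penalty cases, oracle equivalence,
# permutation invariance.

test_that("orthogonal-decomposition loss vanishes exactly on its zero set", {
  set.seed(1)
  for (rep in 1:10) {
    h <- rnorm(4)
    # e orthogonal to h with ||e||^2 = C
    e <- rnorm(4)
    e <- e - sum(e * h) / sum(h * h) * h
    C <- 0.8
    e <- e * sqrt(C) / sqrt(sum(e^2))
    z <- h + e
    expect_lt(aod_loss(matrix(h, 1), matrix(z, 1), delta = 0.1, C = C), 1e-8)
  }
})

test_that("exact alignment is penalized by delta C^2 / 2", {
  set.seed(2)
  H <- matrix(rnorm(20), 5, 4)
  expect_equal(aod_loss(H, H, delta = 0.1, C = 1), 0.05)
})

test_that("orthogonal-decomposition loss matches the per-element oracle", {
  set.seed(3)
  for (rep in 1:20) {
    H <- matrix(rnorm(20), 5, 4); Z <- matrix(rnorm(20), 5, 4)
    expect_lt(max_rel_err(aod_loss(H, Z, 0.3, 1.5),
                          oracle_aod(H, Z, 0.3, 1.5)), 1e-6)
  }
  expect_error(aod_loss(matrix(0, 2, 3), matrix(0, 2, 4)), "Z is")
})

test_that("gradient descent reaches the zero set of the relaxed decomposition", {
  set.seed(4)
  h <- rnorm(4)
  z <- rnorm(4)
  # decaying steps: the |.| term needs diminishing subgradient steps
  for (i in 1:8000) {
    fw <- patchfuse:::aod_forward(matrix(h, 1), matrix(z, 1), delta = 0.5, C = 1)
    z <- z - 0.2 / (1 + i)^0.6 * as.vector(fw$dZ)
  }
  final <- aod_loss(matrix(h, 1), matrix(z, 1), delta = 0.5, C = 1)
  expect_lt(final, 1e-6)
  e <- z - h
  expect_lt(abs(sum(h * e)), 1e-3)
  expect_lt(abs(sum(e^2) - 1), 1e-3)
})

test_that("bilinear fusion neutralizes and scales as expected", {
  set.seed(5)
  d <- 3; dh <- 4
  params <- list(Wg = matrix(rnorm(d * d), d, d), bg = rnorm(d),
                 Wi = matrix(rnorm(d * dh), d, dh), bi = rnorm(d))
  z <- rnorm(d); h <- rnorm(dh)
  # neutral image path: Wi = 0, bi = 1
  pn <- params; pn$Wi <- matrix(0, d, dh); pn$bi <- rep(1, d)
  expect_equal(apr_fuse(z, h, pn), as.vector(params$Wg %*% z + params$bg))
  # bilinearity in the image side when bi = 0
  p0 <- params; p0$bi <- rep(0, d)
  expect_equal(apr_fuse(z, 2.5 * h, p0), 2.5 * apr_fuse(z, h, p0))
  # element-wise loop oracle
  want <- (params$Wg %*% z + params$bg) * (params$Wi %*% h + params$bi)
  expect_lt(max_rel_err(apr_fuse(z, h, params), as.vector(want)), 1e-10)
  expect_error(apr_fuse(rnorm(2), h, params), "code width")
})

test_that("MSE alignment is the mean squared pair distance", {
  set.seed(6)
  H <- matrix(rnorm(12), 3, 4); Z <- matrix(rnorm(12), 3, 4)
  expect_equal(mse_align(H, H), 0)
  want <- mean(sapply(1:3, function(i) sum((H[i, ] - Z[i, ])^2)))
  expect_lt(max_rel_err(mse_align(H, Z), want), 1e-10)
  expect_gte(mse_align(H, Z), 0)
})

test_that("similarity consistency matches its oracle and vanishes on equality", {
  set.seed(7)
  H <- matrix(rnorm(16), 4, 4)
  expect_equal(simc_align(H, H, tau = 0.05), 0)
  for (rep in 1:20) {
    H <- matrix(rnorm(16), 4, 4); Z <- matrix(rnorm(16), 4, 4)
    expect_lt(max_rel_err(simc_align(H, Z, 0.3), oracle_simc(H, Z, 0.3)), 1e-6)
  }
  # each softmax row sums to one
  S <- patchfuse:::softmax_rows(tcrossprod(H) / 0.3)
  expect_equal(unname(rowSums(S)), rep(1, 4))
})

test_that("HSIC vanishes under a constant kernel and matches the trace oracle", {
  set.seed(8)
  B <- 6
  H <- matrix(rnorm(B * 3), B, 3)
  # constant Z batch -> constant kernel matrix -> centering annihilates
  Zc <- matrix(1, B, 3)
  expect_lt(abs(hsic_loss(H, Zc)), 1e-12)
  for (rep in 1:20) {
    H <- matrix(rnorm(B * 3), B, 3); Z <- matrix(rnorm(B * 3), B, 3)
    got <- hsic_loss(H, Z)
    expect_lt(max_rel_err(-got, oracle_hsic(H, Z), 1e-8), 1e-6)
    expect_gte(-got, 0)   # HSIC >= 0 for PSD kernels
  }
})

test_that("MMD vanishes on identical batches and matches the loop oracle", {
  set.seed(9)
  H <- matrix(rnorm(15), 5, 3)
  expect_equal(mmd_loss(H, H), 0)
  for (rep in 1:20) {
    H <- matrix(rnorm(15), 5, 3); Z <- matrix(rnorm(15), 5, 3)
    got <- mmd_loss(H, Z)
    expect_lt(max_rel_err(got, oracle_mmd(H, Z), 1e-8), 1e-6)
    expect_gte(got, 0)
  }
})

test_that("Gaussian-Wasserstein distance has the diagonal closed form", {
  set.seed(10)
  H <- matrix(rnorm(40), 10, 4)
  expect_lt(gwd_loss(H, H), 1e-10)
  # diagonal-covariance toy case: independent coordinates with different
  # scales; compare against sqrt-eigenvalue closed form
  n <- 400
  sda <- c(1, 2); sdb <- c(1.5, 0.5)
  A <- cbind(rnorm(n, 0, sda[1]), rnorm(n, 0, sda[2]))
  B <- cbind(rnorm(n, 0, sdb[1]), rnorm(n, 0, sdb[2]))
  got <- gwd_loss(A, B, shrink = 0)
  # near-diagonal covariances: the square roots are per-axis, so the
  # Frobenius term is the per-coordinate (sqrt(a_j) - sqrt(b_j))^2 sum
  closed <- sum((colMeans(A) - colMeans(B))^2) +
    sum((sqrt(diag(stats::cov(A))) - sqrt(diag(stats::cov(B))))^2)
  expect_lt(abs(got - closed) / closed, 0.05)
  # literal printed exponent: fourth root of the squared Frobenius norm
  got_lit <- gwd_loss(A, B, literal_exponent = TRUE, shrink = 0)
  cov_part <- got - sum((colMeans(A) - colMeans(B))^2)
  expect_equal(got_lit, sum((colMeans(A) - colMeans(B))^2) + cov_part^(1 / 4))
})

test_that("bandwidth rules average squared or unsquared pairwise distances", {
  X <- rbind(c(0, 0), c(2, 0))
  expect_equal(gaussian_bandwidth(X), 4)
  expect_equal(gaussian_bandwidth(X, "mean_dist"), 2)
  # degenerate pool falls back to 1
  expect_equal(gaussian_bandwidth(rbind(c(1, 1), c(1, 1))), 1)
  set.seed(11)
  X <- matrix(rnorm(10), 5, 2)
  expect_lt(max_rel_err(gaussian_bandwidth(X), oracle_bandwidth(X)), 1e-10)
})

test_that("every criterion is invariant to permuting the batch order", {
  set.seed(12)
  B <- 6
  H <- matrix(rnorm(B * 4), B, 4); Z <- matrix(rnorm(B * 4), B, 4)
  perm <- sample(B)
  expect_equal(aod_loss(H[perm, ], Z[perm, ]), aod_loss(H, Z))
  expect_equal(mse_align(H[perm, ], Z[perm, ]), mse_align(H, Z))
  expect_equal(simc_align(H[perm, ], Z[perm, ]), simc_align(H, Z))
  expect_equal(hsic_loss(H[perm, ], Z[perm, ]), hsic_loss(H, Z))
  expect_equal(mmd_loss(H[perm, ], Z[perm, ]), mmd_loss(H, Z))
  expect_equal(gwd_loss(H[perm, ], Z[perm, ]), gwd_loss(H, Z))
})
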