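# Masked transcriptomic autoencoder: masking, forward pass, masked
# reconstruction loss, projection head and the contrastive loss.

test_that("masking is Bernoulli with the configured rate and gates exactly", {
  set.seed(1)
  g <- abs(rnorm(2000)) + 0.1          # strictly positive
  mk <- mask_profile(g, 0.7)
  expect_true(all(mk$mask %in% c(0, 1)))
  expect_equal(mk$masked[mk$mask == 1], rep(0, sum(mk$mask)))
  expect_equal(mk$masked[mk$mask == 0], g[mk$mask == 0])
  # observed mask rate within 3 s.e. of 0.7 over many draws
  set.seed(2)
  n_draws <- 10000
  rates <- replicate(50, mean(mask_profile(g[1:400], 0.7)$mask))
  pooled <- mean(rates)
  se <- sqrt(0.7 * 0.3 / (50 * 400))
  expect_lt(abs(pooled - 0.7), 3 * se)
  expect_error(mask_profile(g, 0), "strictly between")
  expect_error(mask_profile(g, 1), "strictly between")
  # seeded reproducibility
  set.seed(42); a <- mask_profile(g, 0.7)
  set.seed(42); b <- mask_profile(g, 0.7)
  expect_identical(a, b)
})

test_that("autoencoder forward matches a hand-stepped toy oracle", {
  cfg <- mta_config(n_genes = 4, widths = c(3, 2, 3), code_index = 2,
                    proj_widths = c(3, 3))
  set.seed(3)
  params <- patchfuse:::init_mta(cfg)
  state <- patchfuse:::init_mta_state(cfg)
  X <- matrix(rnorm(12), 3, 4)
  got <- mta_forward(X, params, cfg, state, training = TRUE)
  # hand-step: linear -> batch norm (batch stats) -> tanh per hidden layer,
  # final layer linear
  cur <- X
  for (l in 1:4) {
    ly <- params$layers[[l]]
    U <- cur %*% t(ly$W) + matrix(ly$b, nrow(cur), length(ly$b), byrow = TRUE)
    if (l < 4) {
      mu <- colMeans(U); vr <- colMeans(U^2) - mu^2
      Xh <- sweep(sweep(U, 2, mu), 2, sqrt(vr + 1e-5), "/")
      cur <- tanh(sweep(sweep(Xh, 2, ly$gamma, "*"), 2, ly$beta, "+"))
      if (l == 2) expect_lt(max(abs(got$code - cur)), 1e-10)
      expect_true(all(abs(cur) < 1))   # tanh range
    } else {
      cur <- U
    }
  }
  expect_lt(max(abs(got$recon - cur)), 1e-10)
})

test_that("evaluation mode is deterministic and training needs a real batch", {
  cfg <- tiny_mta_config()
  set.seed(4)
  params <- patchfuse:::init_mta(cfg)
  state <- patchfuse:::init_mta_state(cfg)
  x <- abs(rnorm(10))
  a <- mta_forward(x, params, cfg, state, training = FALSE)
  b <- mta_forward(x, params, cfg, state, training = FALSE)
  expect_identical(a, b)
  expect_error(mta_forward(x, params, cfg, state, training = TRUE),
               "at least 2")
})

test_that("reconstruction loss is gated by the mask and matches the oracle", {
  set.seed(5)
  B <- 4; p <- 7
  recon <- matrix(rnorm(B * p), B, p)
  g <- matrix(rnorm(B * p), B, p)
  m <- matrix(rbinom(B * p, 1, 0.6), B, p)
  expect_equal(reconstruction_loss(g, g, m), 0)
  got <- reconstruction_loss(recon, g, m)
  expect_lt(max_rel_err(got, oracle_recon_loss(recon, g, m)), 1e-10)
  # perturbing unmasked coordinates leaves the loss unchanged
  recon2 <- recon + 100 * (1 - m)
  expect_equal(reconstruction_loss(recon2, g, m), got)
})

test_that("projection head is the documented two-layer map", {
  set.seed(6)
  proj <- list(W1 = matrix(rnorm(15), 5, 3), b1 = rnorm(5),
               W2 = matrix(rnorm(10), 2, 5), b2 = rnorm(2))
  z <- rnorm(3)
  want <- as.vector(proj$W2 %*% tanh(proj$W1 %*% z + proj$b1) + proj$b2)
  expect_lt(max_rel_err(project(z, proj), want), 1e-10)
  # zero weights give the zero map
  zero <- list(W1 = matrix(0, 5, 3), b1 = rep(0, 5),
               W2 = matrix(0, 2, 5), b2 = rep(0, 2))
  expect_equal(project(z, zero), c(0, 0))
  # scaling W2 scales the output minus b2
  proj2 <- proj; proj2$W2 <- 3 * proj$W2
  expect_equal(project(z, proj2) - proj2$b2, 3 * (project(z, proj) - proj$b2))
})

test_that("contrastive loss matches the anchor/positive/negative loop oracle", {
  set.seed(7)
  for (rep in 1:20) {
    B <- 6
    Z <- matrix(rnorm(B * 4), B, 4)
    pids <- rep(c("p1", "p2", "p3"), each = 2)
    got <- infonce_loss(Z, pids, tau = 0.05)
    expect_lt(max_rel_err(got, oracle_infonce(Z, pids, 0.05)), 1e-6)
    expect_gte(got, 0)
  }
})

test_that("a same-patient pair gives zero contrastive loss", {
  set.seed(8)
  Z <- matrix(rnorm(8), 2, 4)
  expect_equal(infonce_loss(Z, c("p", "p"), tau = 0.05), 0)
  expect_error(infonce_loss(Z, c("p", "q"), tau = 0.05), "positive")
})

test_that("raising within-patient similarity lowers the contrastive loss", {
  # two patients x two replicates on the unit circle; rotate one replicate
  # toward its sibling while keeping cross-patient geometry fixed
  make_batch <- function(angle) {
    rbind(c(cos(angle), sin(angle)), c(1, 0), c(-1, 0), c(-1, 0))
  }
  pids <- c("a", "a", "b", "b")
  tight <- infonce_loss(make_batch(0.1), pids, tau = 0.5)
  loose <- infonce_loss(make_batch(1.2), pids, tau = 0.5)
  expect_lt(tight, loose)
})

test_that("mask/forward/loss pipeline is reproducible under seed control", {
  cfg <- tiny_mta_config()
  set.seed(9)
  params <- patchfuse:::init_mta(cfg)
  state <- patchfuse:::init_mta_state(cfg)
  run <- function() {
    set.seed(123)
    g <- abs(rnorm(10))
    mk <- mask_profile(g, 0.7)
    fwd <- mta_forward(mk$masked, params, cfg, state, training = FALSE)
    reconstruction_loss(fwd$recon, matrix(g, 1), matrix(mk$mask, 1))
  }
  expect_identical(run(), run())
})
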