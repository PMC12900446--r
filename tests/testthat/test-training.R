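# Loss composition, smoothed cross-entropy, presets, determinism and the
# learning trend on a strong-signal cohort.

test_that("smoothed cross-entropy reduces to plain CE at alpha = 0", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(smoothed_cross_entropy(p, 2, alpha = 0), -log(0.5))
})

test_that("smoothing mixes the one-hot target as (1-alpha) + alpha/K", {
  p <- c(0.7, 0.3)
  # K = 2, alpha = 0.1, y = 1 -> targets (0.95, 0.05)
  want <- -(0.95 * log(0.7) + 0.05 * log(0.3))
  expect_equal(smoothed_cross_entropy(p, 1, alpha = 0.1), want)
})

test_that("the smoothed target minimizes the smoothed CE over the simplex", {
  alpha <- 0.2
  target <- c(0.9, 0.1)   # y = 1, K = 2 smoothed target
  grid <- seq(0.01, 0.99, by = 0.001)
  losses <- vapply(grid, function(q) {
    smoothed_cross_entropy(c(q, 1 - q), 1, alpha = alpha)
  }, numeric(1))
  expect_equal(grid[which.min(losses)], target[1], tolerance = 1e-3)
})

test_that("the report total equals the configured combination per variant", {
  batch <- tiny_batch(n = 6, n_patients = 3)
  lambda <- 0.37
  for (variant in c("image_only", "aod", "apr", "aod_apr", "mse", "mta_only")) {
    tm <- tiny_model(variant = variant, seed = 3, lambda = lambda)
    rep <- total_loss(tm$model, batch, tm$cfg, tm$pcfg, tm$mcfg)
    want <- switch(variant,
      image_only = rep$ce,
      aod = rep$ce + lambda * rep$align + rep$con + rep$recon,
      apr = rep$ce + lambda * rep$con + rep$recon,
      aod_apr = rep$ce + lambda * (rep$align + rep$con) + rep$recon,
      mse = rep$ce + lambda * rep$align + rep$con + rep$recon,
      mta_only = rep$con + rep$recon)
    expect_lt(abs(rep$total - want), 1e-6)
    if (variant == "image_only") {
      expect_equal(rep$align + rep$con + rep$recon, 0)
    }
  }
})

test_that("missing configs for a variant raise a config error", {
  batch <- tiny_batch(n = 4)
  tm <- tiny_model("aod", seed = 4)
  expect_error(total_loss(tm$model, batch, tm$cfg, pfn_cfg = tm$pcfg,
                          mta_cfg = NULL), "mta_config")
  expect_error(total_loss(tm$model, batch, tm$cfg, pfn_cfg = NULL,
                          mta_cfg = tm$mcfg), "pfn_config")
})

test_that("code width must match the embedding width when aligning", {
  pcfg <- tiny_pfn_config()                     # embed_dim 4
  mcfg <- mta_config(n_genes = 10, widths = c(6, 5, 6), code_index = 2)
  cfg <- train_config(variant = "aod", epochs = 1, seed = 1)
  expect_error(patchfuse:::init_model(pcfg, mcfg, cfg), "must equal")
})

test_that("training presets carry the reference settings", {
  crc <- training_preset("crc", "aod")
  expect_equal(crc$epochs, 15L)
  expect_equal(crc$label_smoothing, 0.05)
  expect_equal(crc$learning_rate, 1e-3)
  expect_equal(crc$batch_size, 2048L)
  stad_aod <- training_preset("stad", "aod")
  stad_apr <- training_preset("stad", "apr")
  expect_equal(stad_aod$epochs, 15L)
  expect_equal(stad_apr$epochs, 25L)
  expect_equal(stad_apr$label_smoothing, 0.1)
  gbm_aod <- training_preset("gbm", "aod")
  gbm_apr <- training_preset("gbm", "aod_apr")
  expect_equal(gbm_aod$epochs, 50L)
  expect_equal(gbm_aod$learning_rate, 1e-3)
  expect_equal(gbm_apr$learning_rate, 5e-3)
  expect_equal(gbm_apr$label_smoothing, 0.01)
})

test_that("training is bit-reproducible under a fixed seed", {
  cohort <- tiny_cohort(n_per_class = 4, seed = 5)
  cohort$expression <- preprocess_expression(cohort$expression, n_top = 20)
  aug <- build_augmented(cohort, n_patches = 8, n_replicates = 2,
                         mask_ratio = 0.5, seed = 6)
  pcfg <- pfn_config(n_patches = 8, feature_dim = 6, c_out1 = 6, heads1 = 2,
                     c_out2 = 4, heads2 = 2)
  mcfg <- mta_config(n_genes = 20, widths = c(8, 4, 8), code_index = 2,
                     proj_widths = c(6, 6))
  cfg <- train_config(variant = "aod", epochs = 2, batch_size = 8, seed = 7)
  f1 <- train_patchfuse(aug, cfg, pcfg, mcfg)
  f2 <- train_patchfuse(aug, cfg, pcfg, mcfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$variant, "aod")
})

test_that("training loss trends downward on a strong-signal cohort", {
  cohort <- tiny_cohort(n_per_class = 8, seed = 8)
  cohort$expression <- preprocess_expression(cohort$expression, n_top = 20)
  aug <- build_augmented(cohort, n_patches = 10, n_replicates = 3,
                         mask_ratio = 0.5, seed = 9)
  pcfg <- pfn_config(n_patches = 10, feature_dim = 6, c_out1 = 8, heads1 = 2,
                     c_out2 = 6, heads2 = 2)
  cfg <- train_config(variant = "image_only", epochs = 12, batch_size = 16,
                      seed = 10)
  fit <- train_patchfuse(aug, cfg, pcfg)
  ep <- tidy(fit) |> dplyr::filter(.data$component == "total")
  first3 <- mean(ep$value[1:3])
  last3 <- mean(ep$value[(nrow(ep) - 2):nrow(ep)])
  expect_lt(last3, first3)
  # trend, not just endpoints: late-epoch mean below the early median
  expect_lt(last3, stats::median(ep$value))
})
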