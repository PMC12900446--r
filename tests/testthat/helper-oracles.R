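# Independent brute-force oracles used across the suite. All are literal
# nested-loop or closed-form implementations, kept free of any code shared
# with the package internals they check.

# triple-loop matrix product
oracle_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# literal attention head: scaled inner products with self-pair excluded,
# softmax, weighted sum of theta-scaled columns
oracle_attention_head <- function(H_out, theta_m, theta_value) {
  c_out <- ncol(H_out)
  alpha <- numeric(c_out)
  for (i in seq_len(c_out)) {
    for (j in seq_len(c_out)) {
      if (j != i) {
        alpha[i] <- alpha[i] +
          sum((H_out[, i] * theta_m) * (H_out[, j] * theta_m)) / c_out
      }
    }
  }
  e <- exp(alpha - max(alpha))
  w <- e / sum(e)
  out <- rep(0, nrow(H_out))
  for (i in seq_len(c_out)) out <- out + w[i] * (H_out[, i] * theta_value)
  list(output = out, alpha = alpha, alpha_hat = w)
}

oracle_building_block <- function(H, block) {
  A <- tanh(oracle_matmul(H, block$W))
  M <- ncol(block$theta_heads)
  out <- matrix(0, nrow(A), M)
  for (m in seq_len(M)) {
    tv <- if (is.matrix(block$theta_value)) block$theta_value[, m] else block$theta_value
    out[, m] <- oracle_attention_head(A, block$theta_heads[, m], tv)$output
  }
  out
}

oracle_pfn_forward <- function(H, params, config) {
  B1 <- oracle_building_block(H, params$blocks[[1]])
  B2 <- oracle_building_block(t(B1), params$blocks[[2]])
  out <- numeric(0)
  for (r in seq_len(nrow(B2))) out <- c(out, B2[r, ])   # row-major flatten
  out
}

oracle_attention_scores <- function(H, params) {
  B1 <- oracle_building_block(H, params$blocks[[1]])
  Ht <- t(B1)
  n <- ncol(Ht)
  logits <- numeric(n)
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(Ht))) logits[k] <- logits[k] + abs(Ht[r, k])
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

oracle_recon_loss <- function(recon, g, mask) {
  total <- 0
  for (i in seq_len(nrow(recon))) {
    for (j in seq_len(ncol(recon))) {
      total <- total + (recon[i, j] * mask[i, j] - g[i, j] * mask[i, j])^2
    }
  }
  total / nrow(recon)
}

oracle_infonce <- function(Z, pids, tau, reduction = "mean") {
  B <- nrow(Z)
  Zh <- Z / (sqrt(rowSums(Z^2)) + 1e-12)
  loss <- 0
  n_anchor <- 0
  for (k in seq_len(B)) {
    pos <- setdiff(which(pids == pids[k]), k)
    if (length(pos) == 0) next
    n_anchor <- n_anchor + 1
    denom <- 0
    for (a in setdiff(seq_len(B), k)) denom <- denom + exp(sum(Zh[k, ] * Zh[a, ]) / tau)
    acc <- 0
    for (p in pos) acc <- acc + log(exp(sum(Zh[k, ] * Zh[p, ]) / tau) / denom)
    loss <- loss - acc / length(pos)
  }
  if (reduction == "mean") loss / n_anchor else loss
}

oracle_aod <- function(H, Z, delta, C) {
  total <- 0
  for (i in seq_len(nrow(H))) {
    h <- H[i, ]; z <- Z[i, ]
    total <- total + abs(sum(h * (h - z))) + delta / 2 * (sum((z - h)^2) - C)^2
  }
  total / nrow(H)
}

oracle_simc <- function(H, Z, tau) {
  B <- nrow(H)
  smat <- function(X) {
    S <- matrix(0, B, B)
    for (i in seq_len(B)) {
      nums <- numeric(B)
      for (j in seq_len(B)) nums[j] <- exp(sum(X[i, ] * X[j, ]) / tau)
      S[i, ] <- nums / sum(nums)
    }
    S
  }
  sqrt(sum((smat(H) - smat(Z))^2))
}

oracle_gaussian_kernel <- function(x, y, bw) exp(-sum((x - y)^2) / bw)

oracle_bandwidth <- function(X, rule = "mean_sq_dist") {
  n <- nrow(X)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- sum((X[i, ] - X[j, ])^2)
      vals <- c(vals, if (rule == "mean_sq_dist") d2 else sqrt(d2))
    }
  }
  if (length(vals) == 0 || mean(vals) <= 1e-12) 1 else mean(vals)
}

oracle_hsic <- function(H, Z) {
  B <- nrow(H)
  bwH <- oracle_bandwidth(H); bwZ <- oracle_bandwidth(Z)
  KH <- matrix(0, B, B); KZ <- matrix(0, B, B)
  for (i in seq_len(B)) for (j in seq_len(B)) {
    KH[i, j] <- oracle_gaussian_kernel(H[i, ], H[j, ], bwH)
    KZ[i, j] <- oracle_gaussian_kernel(Z[i, ], Z[j, ], bwZ)
  }
  L <- diag(B) - matrix(1 / B, B, B)
  P <- KH %*% L %*% KZ %*% L
  tr <- 0
  for (i in seq_len(B)) tr <- tr + P[i, i]
  tr / (B - 1)^2
}

oracle_mmd <- function(H, Z) {
  B <- nrow(H)
  bw <- oracle_bandwidth(rbind(H, Z))
  t1 <- 0; t2 <- 0; t3 <- 0
  for (i in seq_len(B)) for (j in seq_len(B)) {
    t1 <- t1 + oracle_gaussian_kernel(H[i, ], H[j, ], bw)
    t2 <- t2 + oracle_gaussian_kernel(H[i, ], Z[j, ], bw)
    t3 <- t3 + oracle_gaussian_kernel(Z[i, ], Z[j, ], bw)
  }
  sqrt(max((t1 - 2 * t2 + t3) / B^2, 0))
}

oracle_auc <- function(scores, labels) {
  labels <- as.integer(labels == max(labels))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# central finite-difference gradient of f at the flattened parameter tree
fd_gradient <- function(f, tree, eps = 1e-5, indices = NULL) {
  v0 <- patchfuse:::tree_flatten(tree)
  if (is.null(indices)) indices <- seq_along(v0)
  vapply(indices, function(i) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    (f(patchfuse:::tree_unflatten(tree, vp)) -
       f(patchfuse:::tree_unflatten(tree, vm))) / (2 * eps)
  }, numeric(1))
}

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# small random fixtures -------------------------------------------------------

tiny_pfn_config <- function(...) {
  pfn_config(n_patches = 6, feature_dim = 5, c_out1 = 4, heads1 = 2,
             c_out2 = 3, heads2 = 2, n_classes = 2, ...)
}

tiny_mta_config <- function(...) {
  mta_config(n_genes = 10, widths = c(6, 4, 6), code_index = 2,
             proj_widths = c(5, 5), ...)
}

# randomized parameters (thetas perturbed off the all-ones symmetric point)
tiny_model <- function(variant = "aod_apr", seed = 1, pcfg = tiny_pfn_config(),
                       mcfg = tiny_mta_config(), ...) {
  cfg <- train_config(variant = variant, epochs = 1, batch_size = 4,
                      seed = seed, ...)
  set.seed(seed)
  model <- patchfuse:::init_model(pcfg, mcfg, cfg)
  model$params <- patchfuse:::tree_map(
    function(x) x + stats::rnorm(length(x), 0, 0.1), model$params)
  list(model = model, cfg = cfg, pcfg = pcfg, mcfg = mcfg)
}

tiny_batch <- function(n = 4, n_genes = 10, n_patients = 2, seed = 99,
                       pcfg = tiny_pfn_config()) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    g <- abs(stats::rnorm(n_genes))
    m <- as.numeric(stats::runif(n_genes) < 0.5)
    pid <- paste0("pt", 1 + (i - 1) %% n_patients)
    list(H = matrix(stats::rnorm(pcfg$n_patches * pcfg$feature_dim),
                    pcfg$n_patches, pcfg$feature_dim),
         g = g, g_masked = g * (1 - m), mask = m,
         y = 1 + (i - 1) %% 2, patient_id = pid,
         replicate = i)
  })
}

# small synthetic cohort for integration-style tests
tiny_cohort <- function(n_per_class = 8, seed = 7, ...) {
  generate_cohort(sim_config(n_per_class = n_per_class,
                             n_patches_range = c(8, 12), feature_dim = 6,
                             n_genes = 30, n_signal_genes = 8,
                             missing_rate = 0.01, ...), seed = seed)
}
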