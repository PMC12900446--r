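# Masked transcriptomic autoencoder: an MLP that reconstructs Bernoulli-masked
# log-expression profiles. Hidden layers apply linear -> batch norm -> tanh;
# the output layer is linear (log(1+x) targets exceed the tanh range; a
# `final_tanh` switch restores the fully saturated reading). The middle-layer
# output is the latent code z used for cross-modal alignment; a two-layer
# projection head feeds the patient-grouped InfoNCE contrastive loss.

#' Configure the masked transcriptomic autoencoder
#'
#' @param n_genes Input/output width `p` (genes after preprocessing;
#'   reference cohorts use 2000).
#' @param widths Inner layer widths. The default `c(512, 128, 32, 128, 1024)`
#'   gives the stack `p-512-128-32-128-1024-p` with a 32-wide code at the
#'   middle layer.
#' @param code_index Which inner layer is the latent code (default the
#'   middle, 3rd, layer).
#' @param proj_widths Projection head widths (code -> 64 -> 128 by default).
#' @param mask_ratio Bernoulli masking probability `xi` (default 0.7).
#' @param tau Contrastive temperature (default 0.05).
#' @param final_tanh Apply tanh (and batch norm) to the output layer as well.
#' @param bn_momentum Running-statistics momentum for batch norm.
#' @return A list of class `mta_config`.
#' @export
mta_config <- function(n_genes = 2000, widths = c(512, 128, 32, 128, 1024),
                       code_index = 3, proj_widths = c(64, 128),
                       mask_ratio = 0.7, tau = 0.05, final_tanh = FALSE,
                       bn_momentum = 0.1) {
  stopifnot(n_genes >= 1, length(widths) >= 1, code_index >= 1,
            code_index <= length(widths), tau > 0)
  if (mask_ratio <= 0 || mask_ratio >= 1) {
    stop("mask_ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), widths = as.integer(widths),
    code_index = as.integer(code_index),
    proj_widths = as.integer(proj_widths),
    mask_ratio = mask_ratio, tau = tau,
    final_tanh = isTRUE(final_tanh), bn_momentum = bn_momentum,
    code_dim = as.integer(widths[code_index])
  ), class = "mta_config")
}

init_mta <- function(config) {
  dims <- c(config$n_genes, config$widths, config$n_genes)
  n_layers <- length(dims) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    layer <- list(W = init_matrix(dims[l + 1L], dims[l]), b = rep(0, dims[l + 1L]))
    hidden <- l < n_layers || config$final_tanh
    if (hidden) {
      layer$gamma <- rep(1, dims[l + 1L])
      layer$beta <- rep(0, dims[l + 1L])
    }
    layers[[l]] <- layer
  }
  pw <- c(config$code_dim, config$proj_widths)
  proj <- list(W1 = init_matrix(pw[2], pw[1]), b1 = rep(0, pw[2]),
               W2 = init_matrix(pw[3], pw[2]), b2 = rep(0, pw[3]))
  list(layers = layers, proj = proj)
}

# Running batch-norm statistics, kept outside the trainable parameter tree.
init_mta_state <- function(config) {
  dims <- c(config$widths, if (config$final_tanh) config$n_genes)
  lapply(dims, function(d) list(mean = rep(0, d), var = rep(1, d)))
}

#' Bernoulli-mask an expression profile
#'
#' Draws an i.i.d. Bernoulli(`mask_ratio`) mask (1 = masked) and zeroes the
#' masked coordinates: `g_masked = g * (1 - m)`.
#'
#' @param g Numeric expression vector (log scale).
#' @param mask_ratio Masking probability in (0, 1).
#' @return List with `masked` (the gated profile) and `mask` (0/1 vector).
#' @export
mask_profile <- function(g, mask_ratio = 0.7) {
  if (mask_ratio <= 0 || mask_ratio >= 1) {
    stop("mask_ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- as.numeric(stats::runif(length(g)) < mask_ratio)
  list(masked = g * (1 - m), mask = m)
}

bn_eps <- 1e-5

# Batch-norm forward for one layer. U: B x d pre-activation. In training mode
# the batch statistics are used (biased variance, the batch-norm convention);
# in eval mode the running statistics.
bn_forward <- function(U, gamma, beta, running, training) {
  B <- nrow(U)
  if (training) {
    if (B < 2) {
      stop("batch normalization needs a batch of at least 2 in training mode; ",
           "got 1 row. Use training = FALSE for single profiles.", call. = FALSE)
    }
    mu <- colMeans(U)
    vr <- colMeans(U^2) - mu^2
  } else {
    mu <- running$mean
    vr <- running$var
  }
  inv_sd <- 1 / sqrt(vr + bn_eps)
  X_hat <- (U - matrix(mu, B, ncol(U), byrow = TRUE)) *
    matrix(inv_sd, B, ncol(U), byrow = TRUE)
  Y <- X_hat * matrix(gamma, B, ncol(U), byrow = TRUE) +
    matrix(beta, B, ncol(U), byrow = TRUE)
  list(Y = Y, X_hat = X_hat, mu = mu, var = vr, inv_sd = inv_sd)
}

bn_backward <- function(cache, gamma, dY) {
  B <- nrow(dY)
  d_gamma <- colSums(dY * cache$X_hat)
  d_beta <- colSums(dY)
  dX_hat <- dY * matrix(gamma, B, ncol(dY), byrow = TRUE)
  inv_sd <- matrix(cache$inv_sd, B, ncol(dY), byrow = TRUE)
  # standard batch-norm backward through the batch statistics
  sum_dxhat <- matrix(colSums(dX_hat), B, ncol(dY), byrow = TRUE)
  sum_dxhat_x <- matrix(colSums(dX_hat * cache$X_hat), B, ncol(dY), byrow = TRUE)
  dU <- inv_sd / B * (B * dX_hat - sum_dxhat - cache$X_hat * sum_dxhat_x)
  list(dU = dU, d_gamma = d_gamma, d_beta = d_beta)
}

# Full autoencoder forward. X: B x p masked profiles. Returns reconstruction,
# code, and caches for backprop. `fuse` optionally transforms the code before
# the decoder (partial-reconstruction alignment); it receives the B x code
# matrix and must return list(Z_fused, cache).
mta_forward_cache <- function(X, params, config, state, training = TRUE,
                              fuse = NULL) {
  n_layers <- length(params$layers)
  caches <- vector("list", n_layers)
  cur <- X
  code <- NULL
  code_pre_fuse <- NULL
  fuse_cache <- NULL
  for (l in seq_len(n_layers)) {
    layer <- params$layers[[l]]
    U <- cur %*% t(layer$W) + matrix(layer$b, nrow(cur), length(layer$b), byrow = TRUE)
    hidden <- !is.null(layer$gamma)
    if (hidden) {
      bn <- bn_forward(U, layer$gamma, layer$beta, state[[l]], training)
      A <- tanh(bn$Y)
      caches[[l]] <- list(input = cur, U = U, bn = bn, A = A, hidden = TRUE)
      cur <- A
    } else {
      caches[[l]] <- list(input = cur, U = U, hidden = FALSE)
      cur <- U
    }
    if (l == config$code_index) {
      code_pre_fuse <- cur
      if (!is.null(fuse)) {
        fused <- fuse(cur)
        cur <- fused$Z_fused
        fuse_cache <- fused$cache
      }
      code <- code_pre_fuse
    }
  }
  list(recon = cur, code = code, caches = caches, fuse_cache = fuse_cache)
}

#' Autoencoder forward pass
#'
#' Runs the masked profile(s) through the encoder-decoder stack and returns
#' the reconstruction and the middle-layer latent code.
#'
#' @param X Matrix of masked profiles, one row per sample (a single profile
#'   vector is accepted).
#' @param params Autoencoder parameter list (see [init_model()]).
#' @param config An [mta_config()].
#' @param state Batch-norm running statistics (from [init_model()] /
#'   training).
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return List with `recon` (B x p) and `code` (B x code_dim).
#' @export
mta_forward <- function(X, params, config, state, training = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  out <- mta_forward_cache(X, params, config, state, training = training)
  list(recon = out$recon, code = out$code)
}

# Backward through the autoencoder. d_recon: B x p gradient w.r.t. the
# reconstruction; d_code: optional B x code gradient (alignment and
# contrastive paths attach here, at the pre-fusion code). fuse_backward, if
# given, maps the gradient at the fused code to list(dZ, extra gradients).
mta_backward <- function(fwd, params, config, d_recon, d_code = NULL,
                         fuse_backward = NULL) {
  n_layers <- length(params$layers)
  grads <- vector("list", n_layers)
  d_cur <- d_recon
  d_fuse_extra <- NULL
  for (l in rev(seq_len(n_layers))) {
    cache <- fwd$caches[[l]]
    if (l == config$code_index) {
      if (!is.null(fuse_backward)) {
        fb <- fuse_backward(d_cur, fwd$fuse_cache)
        d_cur <- fb$dZ
        d_fuse_extra <- fb$grads
      }
      if (!is.null(d_code)) d_cur <- d_cur + d_code
    }
    if (cache$hidden) {
      dY <- d_cur * (1 - cache$A^2)
      bnb <- bn_backward(cache$bn, params$layers[[l]]$gamma, dY)
      dU <- bnb$dU
      grads[[l]] <- list(W = crossprod(dU, cache$input), b = colSums(dU),
                         gamma = bnb$d_gamma, beta = bnb$d_beta)
    } else {
      dU <- d_cur
      grads[[l]] <- list(W = crossprod(dU, cache$input), b = colSums(dU))
    }
    d_cur <- dU %*% params$layers[[l]]$W
  }
  list(layers = grads, d_input = d_cur, fuse = d_fuse_extra)
}

# Update running batch-norm statistics from a training forward pass.
update_bn_state <- function(state, fwd, momentum) {
  idx <- 0L
  for (l in seq_along(fwd$caches)) {
    cache <- fwd$caches[[l]]
    if (isTRUE(cache$hidden)) {
      idx <- idx + 1L
      state[[idx]]$mean <- (1 - momentum) * state[[idx]]$mean + momentum * cache$bn$mu
      state[[idx]]$var <- (1 - momentum) * state[[idx]]$var + momentum * cache$bn$var
    }
  }
  state
}

#' Masked reconstruction loss
#'
#' Mean over the batch of the squared error restricted to masked positions:
#' `mean_i || (recon_i - g_i) * m_i ||^2`. Unmasked coordinates never
#' contribute.
#'
#' @param recon Reconstruction matrix (B x p) or vector.
#' @param g Target profiles, same shape.
#' @param mask 0/1 mask, same shape (1 = masked).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(recon, g, mask) {
  recon <- rbind(recon); g <- rbind(g); mask <- rbind(mask)
  stopifnot(all(dim(recon) == dim(g)), all(dim(g) == dim(mask)))
  diff <- (recon - g) * mask
  sum(diff^2) / nrow(recon)
}

reconstruction_loss_backward <- function(recon, g, mask) {
  recon <- rbind(recon); g <- rbind(g); mask <- rbind(mask)
  2 * (recon - g) * mask / nrow(recon)
}

#' Projection head
#'
#' Maps the latent code through `W2 %*% tanh(W1 z + b1) + b2`.
#'
#' @param z Code vector or B x code matrix.
#' @param proj Projection parameters `W1`, `b1`, `W2`, `b2`.
#' @return Projected matrix (B x output width) or vector.
#' @export
project <- function(z, proj) {
  vec <- !is.matrix(z)
  Z <- if (vec) matrix(z, nrow = 1) else z
  A <- tanh(Z %*% t(proj$W1) + matrix(proj$b1, nrow(Z), length(proj$b1), byrow = TRUE))
  out <- A %*% t(proj$W2) + matrix(proj$b2, nrow(Z), length(proj$b2), byrow = TRUE)
  if (vec) as.vector(out) else out
}

project_cache <- function(Z, proj) {
  A <- tanh(Z %*% t(proj$W1) + matrix(proj$b1, nrow(Z), length(proj$b1), byrow = TRUE))
  out <- A %*% t(proj$W2) + matrix(proj$b2, nrow(Z), length(proj$b2), byrow = TRUE)
  list(out = out, A = A, Z = Z)
}

project_backward <- function(cache, proj, d_out) {
  dA <- d_out %*% proj$W2
  dW2 <- crossprod(d_out, cache$A)
  db2 <- colSums(d_out)
  dPre <- dA * (1 - cache$A^2)
  dW1 <- crossprod(dPre, cache$Z)
  db1 <- colSums(dPre)
  dZ <- dPre %*% proj$W1
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dZ = dZ)
}

norm_eps <- 1e-12

#' Patient-grouped InfoNCE contrastive loss
#'
#' Projected codes are L2-normalized; for each anchor the positives are the
#' other batch members from the same patient, the denominator runs over all
#' other batch members, and the anchor itself is excluded. Anchors without
#' positives are skipped; the loss is averaged over contributing anchors by
#' default (`reduction = "sum"` gives the plain summed form).
#'
#' @param Z_proj Matrix of projected codes, one row per sample.
#' @param patient_ids Character/integer vector, one id per row.
#' @param tau Temperature (> 0).
#' @param reduction `"mean"` (default) or `"sum"` over anchors.
#' @return Scalar loss (>= 0).
#' @export
infonce_loss <- function(Z_proj, patient_ids, tau = 0.05, reduction = c("mean", "sum")) {
  infonce_forward(Z_proj, patient_ids, tau, match.arg(reduction))$loss
}

infonce_forward <- function(Z_proj, patient_ids, tau = 0.05, reduction = "mean") {
  stopifnot(tau > 0)
  B <- nrow(Z_proj)
  if (B < 2) stop("contrastive loss needs a batch of at least 2", call. = FALSE)
  norms <- sqrt(rowSums(Z_proj^2)) + norm_eps
  Zh <- Z_proj / norms
  S <- tcrossprod(Zh)
  loss <- 0
  n_anchor <- 0L
  dS <- matrix(0, B, B)
  for (k in seq_len(B)) {
    pos <- which(patient_ids == patient_ids[k])
    pos <- pos[pos != k]
    if (length(pos) == 0) next
    n_anchor <- n_anchor + 1L
    others <- setdiff(seq_len(B), k)
    logits <- S[k, others] / tau
    lse <- log_sum_exp(logits)
    loss <- loss - mean(S[k, pos] / tau - lse)
    # gradient bookkeeping (scaled by per-anchor count later)
    q <- exp(logits - lse)
    dS[k, pos] <- dS[k, pos] - 1 / (tau * length(pos))
    dS[k, others] <- dS[k, others] + q / tau
  }
  if (n_anchor == 0L) {
    stop("no anchor has a positive: every patient occurs once in the batch",
         call. = FALSE)
  }
  scale <- if (reduction == "mean") 1 / n_anchor else 1
  list(loss = loss * scale, dS = dS * scale, Zh = Zh, norms = norms,
       n_anchor = n_anchor)
}

infonce_backward <- function(fwd) {
  dZh <- (fwd$dS + t(fwd$dS)) %*% fwd$Zh
  inner <- rowSums(fwd$Zh * dZh)
  (dZh - fwd$Zh * inner) / fwd$norms
}
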