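# Cross-modal alignment criteria between slide embeddings h and
# transcriptomic codes z, matched per augmented replicate. The two native
# strategies are deliberately inexact: a relaxed orthogonal decomposition
# (AOD) that keeps a fixed nonzero gap between the modalities, and a bilinear
# fusion of the slide embedding into the decoder (APR) so the reconstruction
# loss backpropagates into the image branch. Five standard criteria (MSE,
# similarity consistency, HSIC, MMD, Gaussian-Wasserstein) are provided for
# ablation. Every criterion has a hand-derived gradient; all are checked
# against finite differences in the test suite.

#' Relaxed orthogonal-decomposition alignment loss
#'
#' For each pair the loss is `|h' (h - z)| + delta/2 * (||z - h||^2 - C)^2`,
#' averaged over the batch. Its zero set is exactly `z = h + e` with `e`
#' orthogonal to `h` and `||e||^2 = C`: alignment is forced to remain inexact
#' by the margin `C`.
#'
#' @param H Matrix of slide embeddings (B x d).
#' @param Z Matrix of transcriptomic codes (B x d).
#' @param delta Scale-balancing weight of the gap term (default 0.1).
#' @param C Target squared gap (default 1).
#' @return Scalar loss.
#' @export
aod_loss <- function(H, Z, delta = 0.1, C = 1) {
  aod_forward(H, Z, delta, C)$loss
}

aod_forward <- function(H, Z, delta = 0.1, C = 1) {
  H <- rbind(H); Z <- rbind(Z)
  if (!all(dim(H) == dim(Z))) {
    stop(sprintf("H is %dx%d but Z is %dx%d", nrow(H), ncol(H), nrow(Z), ncol(Z)),
         call. = FALSE)
  }
  B <- nrow(H)
  inner <- rowSums(H * (H - Z))
  gap <- rowSums((Z - H)^2)
  loss <- mean(abs(inner) + delta / 2 * (gap - C)^2)
  # gradients (subgradient sign(0) = 0 at the kink)
  s <- sign(inner)
  dH <- (s * (2 * H - Z) - delta * (gap - C) * 2 * (Z - H)) / B
  dZ <- (-s * H + delta * (gap - C) * 2 * (Z - H)) / B
  list(loss = loss, dH = dH, dZ = dZ)
}

#' Bilinear fusion for partial-reconstruction alignment
#'
#' Computes `(W_G z + b_G) * (W_I h + b_I)` element-wise. During training the
#' fused code replaces `z` as the decoder input, so the reconstruction loss
#' backpropagates into the patch fusion network.
#'
#' @param z Code vector or B x code matrix.
#' @param h Slide embedding vector or B x d matrix.
#' @param params List with `Wg`, `bg`, `Wi`, `bi`.
#' @return Fused code, same shape as `z`'s mapped width.
#' @export
apr_fuse <- function(z, h, params) {
  vec <- !is.matrix(z)
  Z <- if (vec) matrix(z, nrow = 1) else z
  Hm <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  out <- apr_fuse_cache(Z, Hm, params)$Z_fused
  if (vec) as.vector(out) else out
}

apr_fuse_cache <- function(Z, Hm, params) {
  if (ncol(Z) != ncol(params$Wg)) {
    stop(sprintf("code width %d does not match Wg input width %d",
                 ncol(Z), ncol(params$Wg)), call. = FALSE)
  }
  if (ncol(Hm) != ncol(params$Wi)) {
    stop(sprintf("embedding width %d does not match Wi input width %d",
                 ncol(Hm), ncol(params$Wi)), call. = FALSE)
  }
  G <- Z %*% t(params$Wg) + matrix(params$bg, nrow(Z), length(params$bg), byrow = TRUE)
  I <- Hm %*% t(params$Wi) + matrix(params$bi, nrow(Hm), length(params$bi), byrow = TRUE)
  list(Z_fused = G * I, cache = list(Z = Z, H = Hm, G = G, I = I))
}

apr_fuse_backward <- function(d_out, cache, params) {
  dG <- d_out * cache$I
  dI <- d_out * cache$G
  list(
    grads = list(Wg = crossprod(dG, cache$Z), bg = colSums(dG),
                 Wi = crossprod(dI, cache$H), bi = colSums(dI)),
    dZ = dG %*% params$Wg,
    dH = dI %*% params$Wi
  )
}

#' Mean-squared-error alignment loss
#'
#' Exact alignment criterion: `mean_i ||h_i - z_i||^2`.
#' @inheritParams aod_loss
#' @return Scalar loss.
#' @export
mse_align <- function(H, Z) mse_align_forward(H, Z)$loss

mse_align_forward <- function(H, Z) {
  H <- rbind(H); Z <- rbind(Z)
  stopifnot(all(dim(H) == dim(Z)))
  B <- nrow(H)
  diff <- H - Z
  list(loss = sum(diff^2) / B, dH = 2 * diff / B, dZ = -2 * diff / B)
}

#' Similarity-consistency alignment loss
#'
#' Builds row-softmax similarity matrices from the scaled within-source inner
#' products (the diagonal is included in the softmax sums) and returns the
#' Frobenius norm of their difference.
#'
#' @inheritParams aod_loss
#' @param tau Softmax temperature (default 0.05).
#' @return Scalar loss.
#' @export
simc_align <- function(H, Z, tau = 0.05) simc_forward(H, Z, tau)$loss

simc_forward <- function(H, Z, tau = 0.05) {
  H <- rbind(H); Z <- rbind(Z)
  B <- nrow(H)
  if (B < 2) stop("similarity consistency needs a batch of at least 2", call. = FALSE)
  SH <- softmax_rows(tcrossprod(H) / tau)
  SZ <- softmax_rows(tcrossprod(Z) / tau)
  D <- SH - SZ
  loss <- sqrt(sum(D^2))
  if (loss < 1e-12) {
    return(list(loss = loss, dH = H * 0, dZ = Z * 0))
  }
  dSH <- D / loss
  dSZ <- -D / loss
  dH <- simc_grad_side(H, SH, dSH, tau)
  dZ <- simc_grad_side(Z, SZ, dSZ, tau)
  list(loss = loss, dH = dH, dZ = dZ)
}

# Backward through row-softmax of tcrossprod(X)/tau.
simc_grad_side <- function(X, S, dS, tau) {
  B <- nrow(X)
  dGram <- matrix(0, B, B)
  for (i in seq_len(B)) {
    dGram[i, ] <- softmax_backward(S[i, ], dS[i, ]) / tau
  }
  (dGram + t(dGram)) %*% X
}

#' Gaussian kernel bandwidth from pooled pairwise distances
#'
#' Default rule: the mean of pairwise *squared* Euclidean distances over the
#' pooled batch (matching the `exp(-||.||^2 / delta)` kernel exponent);
#' `rule = "mean_dist"` uses the mean unsquared distance. Degenerate pools
#' (all points identical) fall back to bandwidth 1.
#'
#' @param X Matrix of pooled points (rows).
#' @param rule `"mean_sq_dist"` (default) or `"mean_dist"`.
#' @return Positive scalar bandwidth.
#' @export
gaussian_bandwidth <- function(X, rule = c("mean_sq_dist", "mean_dist")) {
  rule <- match.arg(rule)
  X <- rbind(X)
  D2 <- pairwise_sq_dists(X, X)
  vals <- D2[upper.tri(D2)]
  if (length(vals) == 0) return(1)
  bw <- if (rule == "mean_sq_dist") mean(vals) else mean(sqrt(vals))
  if (!is.finite(bw) || bw <= 1e-12) 1 else bw
}

pairwise_sq_dists <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

# Bandwidth plus its gradient path: returns the scalar bandwidth and a
# closure mapping dL/dbw to dL/dX (zero at the degenerate fallback).
bandwidth_with_grad <- function(X, rule = "mean_sq_dist") {
  X <- rbind(X)
  n <- nrow(X)
  D2 <- pairwise_sq_dists(X, X)
  vals <- D2[upper.tri(D2)]
  degenerate <- length(vals) == 0 ||
    (if (rule == "mean_sq_dist") mean(vals) else mean(sqrt(vals))) <= 1e-12
  if (degenerate) {
    return(list(bw = 1, grad = function(dbw) X * 0))
  }
  npairs <- n * (n - 1) / 2
  if (rule == "mean_sq_dist") {
    bw <- mean(vals)
    grad <- function(dbw) {
      # d mean_{i<j} ||x_i - x_j||^2 / dx_i = 2 (n x_i - sum x) / npairs
      dbw * 2 * (n * X - matrix(colSums(X), n, ncol(X), byrow = TRUE)) / npairs
    }
  } else {
    Dm <- sqrt(D2)
    bw <- mean(Dm[upper.tri(Dm)])
    grad <- function(dbw) {
      Dm_safe <- Dm
      Dm_safe[Dm_safe < 1e-12] <- Inf     # coincident pairs contribute 0
      Wm <- 1 / Dm_safe
      out <- (rowSums(Wm) * X - Wm %*% X) / npairs
      dbw * out
    }
  }
  list(bw = bw, grad = grad)
}

gaussian_kernel <- function(A, B, bw) {
  exp(-pairwise_sq_dists(A, B) / bw)
}

# Gradient helper: given dK (same shape as K = gaussian_kernel(A, B, bw),
# bandwidth treated as constant), accumulate gradients on A-rows.
gaussian_kernel_grad_A <- function(A, B, K, dK, bw) {
  W <- dK * K * (2 / bw)
  # dA_i = sum_j W_ij * (B_j - A_i)
  W %*% B - rowSums(W) * A
}

#' Negative HSIC alignment loss
#'
#' The empirical Hilbert-Schmidt independence criterion
#' `trace(K_H L K_Z L) / (B - 1)^2` with centering matrix
#' `L = I - 11'/B` and Gaussian kernels (bandwidth from
#' [gaussian_bandwidth()] on each source). Independence gives HSIC = 0, so
#' the returned loss is `-HSIC`: minimizing it maximizes cross-modal
#' dependence.
#'
#' @inheritParams aod_loss
#' @param bandwidth_rule Passed to [gaussian_bandwidth()].
#' @return Scalar loss (`-HSIC`, so usually <= 0).
#' @export
hsic_loss <- function(H, Z, bandwidth_rule = "mean_sq_dist") {
  hsic_forward(H, Z, bandwidth_rule)$loss
}

hsic_forward <- function(H, Z, bandwidth_rule = "mean_sq_dist") {
  H <- rbind(H); Z <- rbind(Z)
  B <- nrow(H)
  if (B < 2) stop("HSIC needs a batch of at least 2", call. = FALSE)
  bwH <- bandwidth_with_grad(H, bandwidth_rule)
  bwZ <- bandwidth_with_grad(Z, bandwidth_rule)
  KH <- gaussian_kernel(H, H, bwH$bw)
  KZ <- gaussian_kernel(Z, Z, bwZ$bw)
  L <- diag(B) - matrix(1 / B, B, B)
  M <- L %*% KZ %*% L
  hsic <- sum(KH * t(M)) / (B - 1)^2   # trace(KH %*% M)
  dKH <- -t(M) / (B - 1)^2
  NH <- L %*% KH %*% L
  dKZ <- -t(NH) / (B - 1)^2
  D2H <- pairwise_sq_dists(H, H)
  D2Z <- pairwise_sq_dists(Z, Z)
  dH <- gaussian_kernel_grad_A(H, H, KH, dKH + t(dKH), bwH$bw) +
    bwH$grad(sum(dKH * KH * D2H) / bwH$bw^2)
  dZ <- gaussian_kernel_grad_A(Z, Z, KZ, dKZ + t(dKZ), bwZ$bw) +
    bwZ$grad(sum(dKZ * KZ * D2Z) / bwZ$bw^2)
  list(loss = -hsic, hsic = hsic, dH = dH, dZ = dZ)
}

#' Maximum mean discrepancy alignment loss
#'
#' Biased estimator: the square root of
#' `mean k(h, h') - 2 mean k(h, z) + mean k(z, z')` under a Gaussian kernel
#' with a shared bandwidth from the pooled batch. The bracket is clamped at
#' zero before the root.
#'
#' @inheritParams hsic_loss
#' @return Scalar loss (>= 0).
#' @export
mmd_loss <- function(H, Z, bandwidth_rule = "mean_sq_dist") {
  mmd_forward(H, Z, bandwidth_rule)$loss
}

mmd_forward <- function(H, Z, bandwidth_rule = "mean_sq_dist") {
  H <- rbind(H); Z <- rbind(Z)
  B <- nrow(H)
  bwp <- bandwidth_with_grad(rbind(H, Z), bandwidth_rule)
  bw <- bwp$bw
  KHH <- gaussian_kernel(H, H, bw)
  KHZ <- gaussian_kernel(H, Z, bw)
  KZZ <- gaussian_kernel(Z, Z, bw)
  V <- mean(KHH) - 2 * mean(KHZ) + mean(KZZ)
  Vc <- max(V, 0)
  loss <- sqrt(Vc)
  if (Vc < 1e-12) {
    return(list(loss = loss, dH = H * 0, dZ = Z * 0))
  }
  dV <- 1 / (2 * loss)
  B2 <- B^2
  dKHH <- matrix(dV / B2, B, B)
  dKHZ <- matrix(-2 * dV / B2, B, B)
  dKZZ <- matrix(dV / B2, B, B)
  dH <- gaussian_kernel_grad_A(H, H, KHH, dKHH + t(dKHH), bw) +
    gaussian_kernel_grad_A(H, Z, KHZ, dKHZ, bw)
  dZ <- gaussian_kernel_grad_A(Z, Z, KZZ, dKZZ + t(dKZZ), bw) +
    gaussian_kernel_grad_A(Z, H, t(KHZ), t(dKHZ), bw)
  # bandwidth path (the pooled-mean bandwidth depends on both batches)
  dbw <- sum(dKHH * KHH * pairwise_sq_dists(H, H)) / bw^2 +
    sum(dKHZ * KHZ * pairwise_sq_dists(H, Z)) / bw^2 +
    sum(dKZZ * KZZ * pairwise_sq_dists(Z, Z)) / bw^2
  d_pool <- bwp$grad(dbw)
  dH <- dH + d_pool[seq_len(B), , drop = FALSE]
  dZ <- dZ + d_pool[B + seq_len(B), , drop = FALSE]
  list(loss = loss, dH = dH, dZ = dZ)
}

# Symmetric matrix square root with shrinkage, plus eigendecomposition for
# the Frechet-derivative backward.
sym_sqrtm <- function(Sigma, shrink = 1e-4) {
  Sigma <- (Sigma + t(Sigma)) / 2 + shrink * diag(nrow(Sigma))
  eig <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  S <- eig$vectors %*% (sqrt(vals) * t(eig$vectors))
  list(S = S, vectors = eig$vectors, values = vals)
}

# Given dL/dS for S = sqrtm(Sigma), return dL/dSigma via the symmetric
# Frechet derivative: (U' dS U)_ij / (sqrt(l_i) + sqrt(l_j)).
sqrtm_backward <- function(decomp, dS) {
  U <- decomp$vectors
  r <- sqrt(decomp$values)
  M <- t(U) %*% ((dS + t(dS)) / 2) %*% U
  denom <- outer(r, r, "+")
  denom[denom < 1e-12] <- 1e-12
  U %*% (M / denom) %*% t(U)
}

#' Gaussian-Wasserstein alignment loss (commuting form)
#'
#' Treats each source batch as a Gaussian and computes
#' `||m_H - m_Z||^2 + ||Sigma_H^{1/2} - Sigma_Z^{1/2}||_F^q` under the
#' commuting-covariance simplification, with `q = 2` by default (the
#' squared-Frobenius Bures form) and `q = 1/2` when
#' `literal_exponent = TRUE`. A small diagonal shrinkage keeps the
#' covariances positive semi-definite for small batches.
#'
#' @inheritParams aod_loss
#' @param literal_exponent Use the 1/2 power on the Frobenius norm instead of
#'   the square.
#' @param shrink Diagonal shrinkage added to each covariance.
#' @return Scalar loss (>= 0).
#' @export
gwd_loss <- function(H, Z, literal_exponent = FALSE, shrink = 1e-4) {
  gwd_forward(H, Z, literal_exponent, shrink)$loss
}

gwd_forward <- function(H, Z, literal_exponent = FALSE, shrink = 1e-4) {
  H <- rbind(H); Z <- rbind(Z)
  B <- nrow(H)
  if (B < 2) stop("Gaussian-Wasserstein needs a batch of at least 2", call. = FALSE)
  mH <- colMeans(H); mZ <- colMeans(Z)
  Hc <- sweep(H, 2, mH); Zc <- sweep(Z, 2, mZ)
  SigH <- crossprod(Hc) / (B - 1)
  SigZ <- crossprod(Zc) / (B - 1)
  sqH <- sym_sqrtm(SigH, shrink)
  sqZ <- sym_sqrtm(SigZ, shrink)
  Dm <- mH - mZ
  DS <- sqH$S - sqZ$S
  fro2 <- sum(DS^2)
  cov_term <- if (literal_exponent) fro2^(1 / 4) else fro2
  loss <- sum(Dm^2) + cov_term
  # gradient
  d_fro2 <- if (literal_exponent) {
    if (fro2 < 1e-12) 0 else (1 / 4) * fro2^(-3 / 4)
  } else 1
  dSqH <- 2 * DS * d_fro2
  dSqZ <- -dSqH
  dSigH <- sqrtm_backward(sqH, dSqH)
  dSigZ <- sqrtm_backward(sqZ, dSqZ)
  dH <- matrix(2 * Dm / B, B, ncol(H), byrow = TRUE) +
    2 * (Hc %*% dSigH) / (B - 1)
  dZ <- matrix(-2 * Dm / B, B, ncol(Z), byrow = TRUE) +
    2 * (Zc %*% dSigZ) / (B - 1)
  list(loss = loss, dH = dH, dZ = dZ)
}

# Dispatch an ablation alignment criterion by name; returns loss + gradients.
align_forward <- function(method, H, Z, opts) {
  switch(method,
    aod = aod_forward(H, Z, delta = opts$delta, C = opts$C),
    mse = mse_align_forward(H, Z),
    simc = simc_forward(H, Z, tau = opts$tau_sim),
    hsic = hsic_forward(H, Z, opts$bandwidth_rule),
    mmd = mmd_forward(H, Z, opts$bandwidth_rule),
    gwd = gwd_forward(H, Z, literal_exponent = isTRUE(opts$gwd_literal)),
    stop(sprintf("unknown alignment method '%s'", method), call. = FALSE)
  )
}
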