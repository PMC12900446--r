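# Patch fusion network: stacked multi-head dot-product attention that maps a
# fixed-size matrix of patch features to a low-dimensional slide embedding.
#
# One building block applies, in order, a linear column transform, an
# element-wise tanh, and M attention heads. Each head scores the columns of
# the transformed matrix by their scaled pairwise inner products (diagonal
# excluded, divisor c_out as defined -- not sqrt(c_out)), softmax-normalizes
# the scores, and returns a weighted combination of element-wise scaled
# columns. Stacking two blocks with a transpose in between and flattening the
# final output row-major yields the slide embedding h of length M1 * M2.

#' Configure a patch fusion network
#'
#' Shape choices for the two-block patch fusion network: the bag sample size
#' `n_patches`, the patch feature dimension `feature_dim`, per-block output
#' widths and head counts, and the classifier. The embedding length is
#' `heads1 * heads2`; when transcriptomic alignment is active this must equal
#' the autoencoder code width.
#'
#' @param n_patches Number of patches resampled per bag (rows of the input).
#' @param feature_dim Dimension of each patch feature vector.
#' @param c_out1,c_out2 Linear-transform output widths of blocks 1 and 2.
#' @param heads1,heads2 Attention head counts of blocks 1 and 2.
#' @param n_classes Number of subtype classes.
#' @param per_head_value If `TRUE`, each head has its own value scaler
#'   \eqn{\theta}; the default shares one value scaler per block (the literal
#'   reading of the block definition).
#' @param hidden_classifier Width of an optional tanh hidden layer in the
#'   classifier head; `0` (default) keeps the linear classifier.
#' @return A list of class `pfn_config`.
#' @export
pfn_config <- function(n_patches = 200, feature_dim = 512,
                       c_out1 = 64, heads1 = 8,
                       c_out2 = 64, heads2 = 4,
                       n_classes = 2, per_head_value = FALSE,
                       hidden_classifier = 0) {
  stopifnot(n_patches >= 1, feature_dim >= 1, c_out1 >= 1, c_out2 >= 1,
            heads1 >= 1, heads2 >= 1, n_classes >= 2)
  structure(list(
    n_patches = as.integer(n_patches), feature_dim = as.integer(feature_dim),
    c_out1 = as.integer(c_out1), heads1 = as.integer(heads1),
    c_out2 = as.integer(c_out2), heads2 = as.integer(heads2),
    n_classes = as.integer(n_classes),
    per_head_value = isTRUE(per_head_value),
    hidden_classifier = as.integer(hidden_classifier),
    embed_dim = as.integer(heads1 * heads2)
  ), class = "pfn_config")
}

# Initialize parameters of one building block. theta scalers start at
# all-ones so that initial attention reflects raw column similarities.
init_block <- function(c_in, p, c_out, heads, per_head_value = FALSE) {
  list(
    W = init_matrix(p, c_out),
    theta_heads = matrix(1, c_in, heads),
    theta_value = if (per_head_value) matrix(1, c_in, heads) else rep(1, c_in)
  )
}

init_pfn <- function(config) {
  d <- config$embed_dim
  params <- list(
    blocks = list(
      init_block(config$n_patches, config$feature_dim, config$c_out1,
                 config$heads1, config$per_head_value),
      init_block(config$heads1, config$n_patches, config$c_out2,
                 config$heads2, config$per_head_value)
    )
  )
  if (config$hidden_classifier > 0) {
    params$clf <- list(W1 = init_matrix(config$hidden_classifier, d),
                       b1 = rep(0, config$hidden_classifier),
                       W = init_matrix(config$n_classes, config$hidden_classifier),
                       b = rep(0, config$n_classes))
  } else {
    params$clf <- list(W = init_matrix(config$n_classes, d),
                       b = rep(0, config$n_classes))
  }
  params
}

#' Linear column transform of a feature matrix
#'
#' Computes `H_in %*% W`, the dimensionality-reducing linear map applied at
#' the start of each fusion block.
#'
#' @param H_in Numeric matrix, `c_in x p`.
#' @param W Numeric matrix, `p x c_out`.
#' @return The `c_in x c_out` product matrix.
#' @export
linear_transform <- function(H_in, W) {
  H_in <- as.matrix(H_in); W <- as.matrix(W)
  if (ncol(H_in) != nrow(W)) {
    stop(sprintf("dimension mismatch: H_in is %dx%d but W is %dx%d",
                 nrow(H_in), ncol(H_in), nrow(W), ncol(W)), call. = FALSE)
  }
  H_in %*% W
}

#' One dot-product attention head
#'
#' Scores the columns of `H_out` by the mean of their inner products with the
#' other columns after element-wise scaling by `theta_m` (the self-pair is
#' excluded and the sum is divided by the column count), softmax-normalizes
#' the scores, and returns the weighted sum of columns scaled element-wise by
#' `theta_value`.
#'
#' @param H_out Numeric matrix `c_in x c_out` (block input after the linear
#'   transform and tanh).
#' @param theta_m Similarity scaler, length `c_in`.
#' @param theta_value Value scaler, length `c_in`.
#' @return List with `output` (length `c_in`), the raw scores `alpha` and the
#'   normalized weights `alpha_hat` (both length `c_out`).
#' @export
attention_head <- function(H_out, theta_m, theta_value) {
  H_out <- as.matrix(H_out)
  check_finite(H_out, "attention head input")
  c_out <- ncol(H_out)
  S <- H_out * theta_m               # columns scaled element-wise by theta_m
  # row sums of the Gram matrix G = S'S without forming it:
  # sum_j G_ij = (S' rowSums(S))_i and G_ii = colSums(S^2)
  alpha <- (as.vector(crossprod(S, rowSums(S))) - colSums(S * S)) / c_out
  alpha_hat <- softmax(alpha)
  output <- as.vector((H_out * theta_value) %*% alpha_hat)
  list(output = output, alpha = alpha, alpha_hat = alpha_hat)
}

# Forward pass of one building block with cached intermediates for backprop.
block_forward <- function(H, block) {
  Z <- linear_transform(H, block$W)
  A <- tanh(Z)
  heads <- ncol(block$theta_heads)
  per_head <- is.matrix(block$theta_value)
  out <- matrix(0, nrow(A), heads)
  weights <- vector("list", heads)
  for (m in seq_len(heads)) {
    tv <- if (per_head) block$theta_value[, m] else block$theta_value
    head <- attention_head(A, block$theta_heads[, m], tv)
    out[, m] <- head$output
    weights[[m]] <- head$alpha_hat
  }
  list(output = out, H = H, A = A, weights = weights)
}

#' Apply one fusion building block
#'
#' The composition: linear transform, element-wise tanh, then the block's
#' attention heads. Column `m` of the output is head `m`'s combined vector.
#'
#' @param H Numeric matrix `c_in x p`.
#' @param block Block parameter list with `W`, `theta_heads` (matrix
#'   `c_in x M`) and `theta_value`.
#' @return Numeric matrix `c_in x M`.
#' @export
building_block <- function(H, block) {
  block_forward(H, block)$output
}

# Backward pass of one building block. d_out: c_in x M gradient of the loss
# w.r.t. the block output. Returns gradients for the block parameters and the
# block input.
block_backward <- function(cache, block, d_out) {
  A <- cache$A
  H <- cache$H
  heads <- ncol(block$theta_heads)
  per_head <- is.matrix(block$theta_value)
  c_out <- ncol(A)
  dA <- matrix(0, nrow(A), ncol(A))
  d_theta_heads <- matrix(0, nrow(A), heads)
  d_theta_value <- if (per_head) matrix(0, nrow(A), heads) else rep(0, nrow(A))
  for (m in seq_len(heads)) {
    w <- cache$weights[[m]]
    tv <- if (per_head) block$theta_value[, m] else block$theta_value
    tm <- block$theta_heads[, m]
    dout_m <- d_out[, m]
    V <- A * tv
    dV <- outer(dout_m, w)                       # c_in x c_out
    dw <- as.vector(crossprod(V, dout_m))        # c_out
    dA <- dA + dV * tv
    dtv <- rowSums(dV * A)
    if (per_head) d_theta_value[, m] <- dtv else d_theta_value <- d_theta_value + dtv
    d_alpha <- softmax_backward(w, dw)
    # alpha_i sums row i of G = S'S (diagonal excluded): dG_ij = d_alpha_i /
    # c_out for j != i. The pullback dS = S (dG + dG') expands to the three
    # rank-structured terms below (no c_out x c_out matrix is formed).
    S <- A * tm
    Sd <- as.vector(S %*% d_alpha)
    dS <- (outer(Sd, rep(1, c_out)) + outer(rowSums(S), d_alpha) -
             2 * sweep(S, 2, d_alpha, "*")) / c_out
    dA <- dA + dS * tm
    d_theta_heads[, m] <- rowSums(dS * A)
  }
  dZ <- dA * (1 - A * A)
  dW <- crossprod(H, dZ)
  dH <- dZ %*% t(block$W)
  list(grads = list(W = dW, theta_heads = d_theta_heads,
                    theta_value = d_theta_value),
       dH = dH)
}

# Full PFN forward with caches (two blocks, transpose in between, row-major
# flatten of the final block output).
pfn_forward_cache <- function(H, params, config) {
  if (nrow(H) != config$n_patches) {
    stop(sprintf(
      "bag has %d rows but the network was configured for %d patches (second-block W has %d rows)",
      nrow(H), config$n_patches, config$n_patches), call. = FALSE)
  }
  c1 <- block_forward(H, params$blocks[[1]])        # N x M1
  T1 <- t(c1$output)                                # M1 x N
  c2 <- block_forward(T1, params$blocks[[2]])       # M1 x M2
  h <- as.vector(t(c2$output))                      # row-major flatten
  list(h = h, c1 = c1, c2 = c2)
}

#' Slide embedding from a bag of patch features
#'
#' Runs the two stacked fusion blocks on a resampled bag and returns the
#' row-major flattened embedding of length `heads1 * heads2`.
#'
#' @param H Numeric matrix `n_patches x feature_dim`.
#' @param params PFN parameter list (see [init_model()]).
#' @param config A [pfn_config()].
#' @return Numeric vector of length `config$embed_dim`.
#' @export
pfn_forward <- function(H, params, config) {
  pfn_forward_cache(as.matrix(H), params, config)$h
}

# Backward from d_h (length M1*M2) through both blocks; returns gradients for
# both blocks (input gradient is discarded -- features are fixed).
pfn_backward <- function(cache, params, config, d_h) {
  dB2 <- matrix(d_h, config$heads1, config$heads2, byrow = TRUE)
  b2 <- block_backward(cache$c2, params$blocks[[2]], dB2)
  dB1 <- t(b2$dH)
  b1 <- block_backward(cache$c1, params$blocks[[1]], dB1)
  list(blocks = list(b1$grads, b2$grads))
}

#' Patch attention scores from the first fusion block
#'
#' The per-patch score is the softmax, over patches, of the summed absolute
#' first-block head outputs: with `Ht = t(block1(H))` (heads x patches),
#' `score_k = softmax_k( sum_r |Ht[r, k]| )`. Scores are nonnegative and sum
#' to one.
#'
#' @inheritParams pfn_forward
#' @return Numeric vector of length `nrow(H)` summing to 1.
#' @export
attention_scores <- function(H, params, config) {
  H <- as.matrix(H)
  B1 <- building_block(H, params$blocks[[1]])   # N x M1
  Ht <- t(B1)                                   # M1 x N
  softmax(colSums(abs(Ht)))
}

#' Aggregate patch attention scores across bag replicates
#'
#' Patch bags are resampled with replacement, so a patch may occupy several
#' slots of one replicate and may be absent from others. Within a replicate
#' the scores of duplicate slots are summed (a patch drawn twice carried
#' twice the softmax mass in that forward pass); across replicates the
#' per-replicate scores are averaged over the replicates in which the patch
#' was sampled. Patches never sampled are absent from the result.
#'
#' @param per_replicate_scores List over replicates; each element is a named
#'   numeric vector of scores, names are patch ids (one name per sampled
#'   slot; duplicates allowed).
#' @return A tibble with columns `patch_id`, `mean_score`, `n_replicates`,
#'   sorted by decreasing `mean_score`.
#' @export
aggregate_attention <- function(per_replicate_scores) {
  if (length(per_replicate_scores) == 0) {
    stop("no replicates supplied", call. = FALSE)
  }
  per_rep <- purrr::imap_dfr(per_replicate_scores, function(sc, rep_idx) {
    if (is.null(names(sc))) {
      stop("replicate scores must be named by patch id", call. = FALSE)
    }
    tibble::tibble(replicate = rep_idx, patch_id = names(sc), score = as.numeric(sc)) |>
      dplyr::group_by(.data$replicate, .data$patch_id) |>
      dplyr::summarise(score = sum(.data$score), .groups = "drop")
  })
  per_rep |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(mean_score = mean(.data$score),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$patch_id)
}

# Classifier head forward: probabilities over classes. h may be a vector or a
# B x d matrix (rows are samples).
classifier_forward <- function(h, clf) {
  Hm <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  if (!is.null(clf$W1)) {
    Hm <- tanh(Hm %*% t(clf$W1) + matrix(clf$b1, nrow(Hm), length(clf$b1), byrow = TRUE))
  }
  logits <- Hm %*% t(clf$W) + matrix(clf$b, nrow(Hm), length(clf$b), byrow = TRUE)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, hidden = if (!is.null(clf$W1)) Hm else NULL)
}

#' Class probabilities for a slide embedding
#'
#' Applies the linear classifier head and a softmax: `softmax(W h + b)`.
#'
#' @param h Slide embedding vector (or matrix with one embedding per row).
#' @param W_c Classifier weight matrix, `n_classes x d`.
#' @param b_c Classifier bias, length `n_classes`.
#' @return Probability vector (or matrix), entries in (0, 1) summing to 1.
#' @export
classify <- function(h, W_c, b_c) {
  out <- classifier_forward(h, list(W = W_c, b = b_c))$probs
  if (!is.matrix(h)) as.vector(out) else out
}
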