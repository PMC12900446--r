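# Model assembly: joins the patch fusion network, the masked transcriptomic
# autoencoder and an alignment criterion into one trainable parameter tree,
# and computes the total loss of a mini-batch together with its hand-derived
# gradients. Training variants:
#
#   image_only : CE                                 (no transcriptomic branch)
#   aod        : CE + lambda * L_align + L_con + L_recon   (plain decoder)
#   apr        : CE + lambda * L_con + L_recon             (fused decoder)
#   aod_apr    : CE + lambda * (L_align + L_con) + L_recon (fused decoder)
#   mse/simc/hsic/mmd/gwd : CE + lambda * L_crit + L_con + L_recon
#   mta_only   : L_recon + L_con                    (autoencoder pretraining)

model_variants <- c("image_only", "aod", "apr", "aod_apr",
                    "mse", "simc", "hsic", "mmd", "gwd", "mta_only")

variant_uses_image <- function(variant) variant != "mta_only"
variant_uses_rna <- function(variant) variant != "image_only"
variant_fused <- function(variant) variant %in% c("apr", "aod_apr")
variant_align_method <- function(variant) {
  switch(variant, aod = "aod", aod_apr = "aod", mse = "mse", simc = "simc",
         hsic = "hsic", mmd = "mmd", gwd = "gwd", NULL)
}

# Per-variant weights of the loss components.
variant_weights <- function(variant, lambda) {
  switch(variant,
    image_only = list(ce = 1, align = 0, con = 0, recon = 0),
    aod = list(ce = 1, align = lambda, con = 1, recon = 1),
    apr = list(ce = 1, align = 0, con = lambda, recon = 1),
    aod_apr = list(ce = 1, align = lambda, con = lambda, recon = 1),
    mta_only = list(ce = 0, align = 0, con = 1, recon = 1),
    # ablation criteria follow the orthogonal-decomposition composition
    list(ce = 1, align = lambda, con = 1, recon = 1)
  )
}

#' Training configuration
#'
#' @param variant One of `"image_only"` (no transcriptomic guidance),
#'   `"aod"`, `"apr"`, `"aod_apr"`, an ablation criterion (`"mse"`,
#'   `"simc"`, `"hsic"`, `"mmd"`, `"gwd"`), or `"mta_only"` (autoencoder
#'   alone).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate AdamW learning rate (default 1e-3).
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param lambda Alignment/contrastive weight in the total loss (default
#'   0.5).
#' @param delta Gap-term weight of the orthogonal-decomposition loss
#'   (default 0.1).
#' @param C Target squared gap of the orthogonal-decomposition loss.
#' @param tau_con Contrastive temperature (default 0.05).
#' @param tau_sim Similarity-consistency temperature (defaults to
#'   `tau_con`).
#' @param label_smoothing Label-smoothing weight alpha in \[0, 1\].
#' @param bandwidth_rule Gaussian bandwidth rule for HSIC/MMD.
#' @param gwd_literal Use the printed 1/2 exponent in the
#'   Gaussian-Wasserstein covariance term.
#' @param seed Integer seed driving initialization and batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(variant = "aod_apr", epochs = 15, batch_size = 2048,
                         learning_rate = 1e-3, weight_decay = 1e-2,
                         lambda = 0.5, delta = 0.1, C = 1, tau_con = 0.05,
                         tau_sim = NULL, label_smoothing = 0.05,
                         bandwidth_rule = "mean_sq_dist",
                         gwd_literal = FALSE, seed = 1L) {
  variant <- match.arg(variant, model_variants)
  stopifnot(epochs >= 1, lambda >= 0, label_smoothing >= 0,
            label_smoothing <= 1, delta > 0, C > 0)
  structure(list(
    variant = variant, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    weight_decay = weight_decay, lambda = lambda, delta = delta, C = C,
    tau_con = tau_con, tau_sim = if (is.null(tau_sim)) tau_con else tau_sim,
    label_smoothing = label_smoothing, bandwidth_rule = bandwidth_rule,
    gwd_literal = isTRUE(gwd_literal), seed = as.integer(seed)
  ), class = "train_config")
}

#' Named training presets from the reference cohorts
#'
#' Epoch counts, label smoothing and learning rates used for the reference
#' TCGA cohorts: colorectal (15 epochs, alpha 0.05), stomach (15 epochs for
#' the orthogonal-decomposition variant, 25 for the partial-reconstruction
#' variants, alpha 0.1) and glioblastoma (50 epochs, alpha 0.01, learning
#' rate 5e-3 for the partial-reconstruction variants). Batch size 2048
#' throughout.
#'
#' @param cohort `"crc"`, `"stad"` or `"gbm"`.
#' @param variant Training variant (see [train_config()]).
#' @param seed Seed forwarded to the config.
#' @return A [train_config()].
#' @export
training_preset <- function(cohort = c("crc", "stad", "gbm"),
                            variant = "aod_apr", seed = 1L) {
  cohort <- match.arg(cohort)
  variant <- match.arg(variant, model_variants)
  apr_like <- variant %in% c("apr", "aod_apr")
  epochs <- switch(cohort,
    crc = 15L,
    stad = if (apr_like) 25L else 15L,
    gbm = 50L
  )
  alpha <- switch(cohort, crc = 0.05, stad = 0.1, gbm = 0.01)
  lr <- if (cohort == "gbm" && apr_like) 5e-3 else 1e-3
  train_config(variant = variant, epochs = epochs, batch_size = 2048,
               learning_rate = lr, label_smoothing = alpha, seed = seed)
}

# Initialize the full parameter tree + batch-norm state for a variant.
init_model <- function(pfn_cfg, mta_cfg, config) {
  params <- list()
  if (variant_uses_image(config$variant)) {
    pfn <- init_pfn(pfn_cfg)
    params$pfn <- list(blocks = pfn$blocks)
    params$clf <- pfn$clf
  }
  state <- NULL
  if (variant_uses_rna(config$variant)) {
    if (variant_uses_image(config$variant) &&
        mta_cfg$code_dim != pfn_cfg$embed_dim) {
      stop(sprintf(
        "autoencoder code width (%d) must equal the slide embedding width heads1*heads2 (%d) when alignment is active",
        mta_cfg$code_dim, pfn_cfg$embed_dim), call. = FALSE)
    }
    params$mta <- init_mta(mta_cfg)
    state <- init_mta_state(mta_cfg)
    if (variant_fused(config$variant)) {
      # the image-side gate starts near-neutral (b_I = 1, small W_I) so the
      # fused decoder begins close to the plain autoencoder and the bilinear
      # modulation grows during training
      d <- mta_cfg$code_dim
      params$apr <- list(Wg = init_matrix(d, d), bg = rep(0, d),
                         Wi = 0.1 * init_matrix(d, pfn_cfg$embed_dim),
                         bi = rep(1, d))
    }
  }
  list(params = params, state = state)
}

#' Smoothed cross-entropy loss
#'
#' `-sum_k ytilde_k log yhat_k` averaged over the batch, with
#' `ytilde_k = onehot_k (1 - alpha) + alpha / K`. Zero probabilities are
#' clamped before the log.
#'
#' @param y_hat Probability vector, or matrix with one sample per row.
#' @param y Integer class label(s) in `1..K`.
#' @param alpha Label-smoothing weight in \[0, 1\].
#' @return Scalar loss.
#' @export
smoothed_cross_entropy <- function(y_hat, y, alpha = 0) {
  P <- rbind(y_hat)
  K <- ncol(P)
  stopifnot(all(y >= 1), all(y <= K), alpha >= 0, alpha <= 1)
  Yt <- matrix(alpha / K, nrow(P), K)
  Yt[cbind(seq_len(nrow(P)), y)] <- Yt[cbind(seq_len(nrow(P)), y)] + (1 - alpha)
  -mean(rowSums(Yt * log(pmax(P, 1e-12))))
}

# Forward + backward of the whole model on one batch of augmented samples.
# Returns loss components, the total, and the full gradient tree. Pure
# function of (params, batch): batch-norm uses batch statistics; the updated
# running stats are returned for the caller to apply.
batch_loss <- function(params, batch, config, pfn_cfg, mta_cfg, state,
                       compute_grads = TRUE) {
  variant <- config$variant
  w <- variant_weights(variant, config$lambda)
  B <- length(batch)
  use_img <- variant_uses_image(variant)
  use_rna <- variant_uses_rna(variant)
  align_method <- variant_align_method(variant)

  # ---- forward: image branch ----
  Hmat <- NULL; pfn_caches <- NULL
  if (use_img) {
    d <- pfn_cfg$embed_dim
    Hmat <- matrix(0, B, d)
    pfn_caches <- vector("list", B)
    for (b in seq_len(B)) {
      cc <- pfn_forward_cache(batch[[b]]$H, params$pfn, pfn_cfg)
      Hmat[b, ] <- cc$h
      pfn_caches[[b]] <- cc
    }
    y <- vapply(batch, function(s) as.integer(s$y), integer(1))
    clf <- classifier_forward(Hmat, params$clf)
    K <- pfn_cfg$n_classes
    alpha <- config$label_smoothing
    Yt <- matrix(alpha / K, B, K)
    Yt[cbind(seq_len(B), y)] <- Yt[cbind(seq_len(B), y)] + (1 - alpha)
    loss_ce <- -mean(rowSums(Yt * log(pmax(clf$probs, 1e-12))))
  } else {
    loss_ce <- 0
  }

  # ---- forward: transcriptomic branch ----
  loss_recon <- 0; loss_con <- 0; loss_align <- 0
  mta_fwd <- NULL; proj_fwd <- NULL; con_fwd <- NULL; align_fwd <- NULL
  G <- NULL; Gm <- NULL; Mmask <- NULL
  if (use_rna) {
    G <- do.call(rbind, lapply(batch, function(s) s$g))
    Gm <- do.call(rbind, lapply(batch, function(s) s$g_masked))
    Mmask <- do.call(rbind, lapply(batch, function(s) s$mask))
    pids <- vapply(batch, function(s) as.character(s$patient_id), character(1))
    fuse <- NULL
    if (variant_fused(variant)) {
      fuse <- function(Z) apr_fuse_cache(Z, Hmat, params$apr)
    }
    mta_fwd <- mta_forward_cache(Gm, params$mta, mta_cfg, state,
                                 training = TRUE, fuse = fuse)
    loss_recon <- reconstruction_loss(mta_fwd$recon, G, Mmask)
    proj_fwd <- project_cache(mta_fwd$code, params$mta$proj)
    con_fwd <- tryCatch(
      infonce_forward(proj_fwd$out, pids, tau = config$tau_con),
      error = function(e) NULL)
    loss_con <- if (is.null(con_fwd)) 0 else con_fwd$loss
    if (!is.null(align_method) && use_img) {
      align_fwd <- align_forward(align_method, Hmat, mta_fwd$code,
                                 list(delta = config$delta, C = config$C,
                                      tau_sim = config$tau_sim,
                                      bandwidth_rule = config$bandwidth_rule,
                                      gwd_literal = config$gwd_literal))
      loss_align <- align_fwd$loss
    }
  }

  total <- w$ce * loss_ce + w$align * loss_align + w$con * loss_con +
    w$recon * loss_recon
  components <- list(ce = loss_ce, align = loss_align, con = loss_con,
                     recon = loss_recon, total = total)
  if (!compute_grads) {
    return(list(components = components,
                new_state = if (use_rna) update_bn_state(state, mta_fwd, mta_cfg$bn_momentum) else state))
  }

  # ---- backward ----
  grads <- tree_zeros_like(params)
  dH_total <- if (use_img) matrix(0, B, pfn_cfg$embed_dim) else NULL

  if (use_img && w$ce > 0) {
    dlogits <- w$ce * (clf$probs - Yt) / B
    if (!is.null(params$clf$W1)) {
      Hd <- clf$hidden
      grads$clf$W <- crossprod(dlogits, Hd)
      grads$clf$b <- colSums(dlogits)
      dHd <- dlogits %*% params$clf$W
      dPre <- dHd * (1 - Hd^2)
      grads$clf$W1 <- crossprod(dPre, Hmat)
      grads$clf$b1 <- colSums(dPre)
      dH_total <- dH_total + dPre %*% params$clf$W1
    } else {
      grads$clf$W <- crossprod(dlogits, Hmat)
      grads$clf$b <- colSums(dlogits)
      dH_total <- dH_total + dlogits %*% params$clf$W
    }
  }

  if (use_rna) {
    d_recon <- w$recon * reconstruction_loss_backward(mta_fwd$recon, G, Mmask)
    # contrastive path attaches at the (pre-fusion) code via the projection
    d_code <- NULL
    if (!is.null(con_fwd) && w$con > 0) {
      d_proj_out <- w$con * infonce_backward(con_fwd)
      pb <- project_backward(proj_fwd, params$mta$proj, d_proj_out)
      grads$mta$proj <- pb$grads
      d_code <- pb$dZ
    }
    if (!is.null(align_fwd) && w$align > 0) {
      add <- w$align * align_fwd$dZ
      d_code <- if (is.null(d_code)) add else d_code + add
      dH_total <- dH_total + w$align * align_fwd$dH
    }
    fuse_backward <- NULL
    if (variant_fused(variant)) {
      fuse_env <- new.env()
      fuse_backward <- function(d_out, cache) {
        fb <- apr_fuse_backward(d_out, cache, params$apr)
        fuse_env$dH <- fb$dH
        fuse_env$grads <- fb$grads
        list(dZ = fb$dZ, grads = fb$grads)
      }
    }
    mb <- mta_backward(mta_fwd, params$mta, mta_cfg, d_recon,
                       d_code = d_code, fuse_backward = fuse_backward)
    for (l in seq_along(mb$layers)) grads$mta$layers[[l]] <- mb$layers[[l]]
    if (variant_fused(variant)) {
      grads$apr <- fuse_env$grads
      dH_total <- dH_total + fuse_env$dH
    }
  }

  if (use_img) {
    for (b in seq_len(B)) {
      pg <- pfn_backward(pfn_caches[[b]], params$pfn, pfn_cfg, dH_total[b, ])
      grads$pfn$blocks <- tree_map2(`+`, grads$pfn$blocks, pg$blocks)
    }
  }

  list(components = components, grads = grads,
       new_state = if (use_rna) update_bn_state(state, mta_fwd, mta_cfg$bn_momentum) else state,
       embeddings = Hmat)
}
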