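# Seeded mini-batch AdamW training over the augmented sample set, plus
# prediction and embedding extraction from a fitted model.

#' Compute the total loss of a mini-batch
#'
#' Evaluates the configured combination of cross-entropy, alignment,
#' contrastive and masked-reconstruction losses for one batch of augmented
#' samples, without updating parameters. The report's `total` is exactly the
#' weighted sum of the components.
#'
#' @param model A model list with `params` and `state` (from a fit, or
#'   internal initialization).
#' @param batch List of augmented samples (elements of
#'   `augmented_set$samples`).
#' @param config A [train_config()].
#' @param pfn_cfg A [pfn_config()] (required unless the variant is
#'   `"mta_only"`).
#' @param mta_cfg An [mta_config()] (required unless the variant is
#'   `"image_only"`).
#' @return A one-row tibble with columns `ce`, `align`, `con`, `recon`,
#'   `total`.
#' @export
total_loss <- function(model, batch, config, pfn_cfg = NULL, mta_cfg = NULL) {
  check_variant_configs(config, pfn_cfg, mta_cfg)
  out <- batch_loss(model$params, batch, config, pfn_cfg, mta_cfg,
                    model$state, compute_grads = FALSE)
  tibble::as_tibble(out$components)
}

check_variant_configs <- function(config, pfn_cfg, mta_cfg) {
  if (variant_uses_image(config$variant) && is.null(pfn_cfg)) {
    stop(sprintf("variant '%s' needs a pfn_config", config$variant), call. = FALSE)
  }
  if (variant_uses_rna(config$variant) && is.null(mta_cfg)) {
    stop(sprintf("variant '%s' needs an mta_config", config$variant), call. = FALSE)
  }
}

#' Train a model on an augmented sample set
#'
#' Runs seeded mini-batch AdamW over the configured total loss. All
#' randomness (parameter initialization, batch shuffling) derives from
#' `config$seed`; two runs with identical inputs are bit-identical. Training
#' aborts with the last finite state if the loss diverges.
#'
#' @param augmented An `augmented_set` from [build_augmented()].
#' @param config A [train_config()].
#' @param pfn_cfg A [pfn_config()] matching the augmented bags (ignored for
#'   `"mta_only"`).
#' @param mta_cfg An [mta_config()] matching the gene count (ignored for
#'   `"image_only"`).
#' @param verbose Print per-epoch mean losses.
#' @return A `patchfuse_fit` object: parameter tree, batch-norm state,
#'   configs and a per-batch `history` tibble.
#' @export
train_patchfuse <- function(augmented, config, pfn_cfg = NULL, mta_cfg = NULL,
                            verbose = FALSE) {
  check_variant_configs(config, pfn_cfg, mta_cfg)
  samples <- augmented$samples
  n <- length(samples)
  set.seed(config$seed)
  model <- init_model(pfn_cfg, mta_cfg, config)
  params <- model$params
  state <- model$state
  opt <- adamw_init(params)
  history <- vector("list", 0)
  bs <- min(config$batch_size, n)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = bs)
    for (si in seq_along(starts)) {
      idx <- perm[starts[si]:min(starts[si] + bs - 1, n)]
      if (length(idx) < 2) next   # batch norm / contrastive need >= 2
      batch <- samples[idx]
      out <- batch_loss(params, batch, config, pfn_cfg, mta_cfg, state)
      if (!is.finite(out$components$total)) {
        warning("non-finite loss; stopping at the last finite state",
                call. = FALSE)
        return(new_patchfuse_fit(params, state, config, pfn_cfg, mta_cfg,
                                 dplyr::bind_rows(history)))
      }
      step <- adamw_step(params, out$grads, opt, lr = config$learning_rate,
                         weight_decay = config$weight_decay)
      params <- step$params
      opt <- step$state
      state <- out$new_state
      history[[length(history) + 1]] <- tibble::tibble(
        epoch = epoch, step = si, ce = out$components$ce,
        align = out$components$align, con = out$components$con,
        recon = out$components$recon, total = out$components$total)
    }
    if (verbose) {
      ep <- dplyr::bind_rows(history) |> dplyr::filter(.data$epoch == !!epoch)
      message(sprintf("epoch %d: total %.4f", epoch, mean(ep$total)))
    }
  }
  new_patchfuse_fit(params, state, config, pfn_cfg, mta_cfg,
                    dplyr::bind_rows(history))
}

new_patchfuse_fit <- function(params, state, config, pfn_cfg, mta_cfg, history) {
  structure(list(params = params, state = state, config = config,
                 pfn_config = pfn_cfg, mta_config = mta_cfg,
                 history = history),
            class = "patchfuse_fit")
}

#' @export
print.patchfuse_fit <- function(x, ...) {
  cat(sprintf("<patchfuse_fit> variant '%s', %d epochs, %d training steps\n",
              x$config$variant, x$config$epochs, nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- dplyr::slice_tail(x$history, n = 1)
    cat(sprintf("  final batch loss: total %.4f (ce %.4f, align %.4f, con %.4f, recon %.4f)\n",
                last$total, last$ce, last$align, last$con, last$recon))
  }
  invisible(x)
}

#' Per-replicate class probabilities for augmented samples
#'
#' Image-only inference: each augmented bag is embedded by the patch fusion
#' network and classified; no transcriptomic input is used.
#'
#' @param object A `patchfuse_fit` whose variant includes the image branch.
#' @param augmented An `augmented_set` (test-time augmentation mirrors
#'   training).
#' @param ... Unused.
#' @return A tibble with `patient_id`, `replicate`, `label`, one `prob_<k>`
#'   column per class, and the argmax `pred`.
#' @export
predict.patchfuse_fit <- function(object, augmented, ...) {
  if (!variant_uses_image(object$config$variant)) {
    stop("this fit has no image branch; it cannot classify bags", call. = FALSE)
  }
  samples <- augmented$samples
  emb <- embed_bags(object, augmented)
  probs <- classifier_forward(emb, object$params$clf)$probs
  K <- ncol(probs)
  out <- tibble::tibble(
    patient_id = vapply(samples, function(s) as.character(s$patient_id), character(1)),
    replicate = vapply(samples, function(s) as.integer(s$replicate), integer(1)),
    label = vapply(samples, function(s) as.integer(s$y), integer(1))
  )
  for (k in seq_len(K)) out[[paste0("prob_", k)]] <- probs[, k]
  out$pred <- max.col(probs, ties.method = "first")
  out
}

#' Slide embeddings for augmented samples
#'
#' @param fit A `patchfuse_fit` with an image branch.
#' @param augmented An `augmented_set`.
#' @return Numeric matrix, one embedding row per augmented sample.
#' @export
embed_bags <- function(fit, augmented) {
  samples <- augmented$samples
  d <- fit$pfn_config$embed_dim
  emb <- matrix(0, length(samples), d)
  for (b in seq_along(samples)) {
    emb[b, ] <- pfn_forward(samples[[b]]$H, fit$params$pfn, fit$pfn_config)
  }
  emb
}

#' Masked-reconstruction error per patient
#'
#' Draws fresh masks for each patient's profile, reconstructs with the
#' fitted autoencoder in evaluation mode, and reports the mean squared error
#' on masked positions together with the variance of the masked entries
#' (the mean-predictor baseline).
#'
#' @param fit A `patchfuse_fit` whose variant includes the transcriptomic
#'   branch.
#' @param expression Genes x patients matrix (preprocessed, log scale).
#' @param n_replicates Fresh masks per patient.
#' @param mask_ratio Mask probability (defaults to the fit's).
#' @return Tibble with `patient_id`, `mse` (masked positions), and
#'   `baseline_var` (variance of the same masked entries around their mean).
#' @export
masked_mse <- function(fit, expression, n_replicates = 10, mask_ratio = NULL) {
  if (!variant_uses_rna(fit$config$variant)) {
    stop("this fit has no transcriptomic branch", call. = FALSE)
  }
  cfg <- fit$mta_config
  if (is.null(mask_ratio)) mask_ratio <- cfg$mask_ratio
  ids <- colnames(expression)
  rows <- lapply(ids, function(pid) {
    g <- expression[, pid]
    errs <- numeric(n_replicates)
    base <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      mk <- mask_profile(g, mask_ratio)
      fwd <- mta_forward(matrix(mk$masked, nrow = 1), fit$params$mta, cfg,
                         fit$state, training = FALSE)
      masked_idx <- which(mk$mask == 1)
      errs[r] <- mean((fwd$recon[1, masked_idx] - g[masked_idx])^2)
      mu <- mean(g[masked_idx])
      base[r] <- mean((g[masked_idx] - mu)^2)
    }
    tibble::tibble(patient_id = pid, mse = mean(errs),
                   baseline_var = mean(base))
  })
  dplyr::bind_rows(rows)
}
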