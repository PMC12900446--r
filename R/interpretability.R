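# Template-based patch similarity and top-k attention patch selection.

#' Exponential cosine similarity between two patches
#'
#' `exp(cos(r_i, r_j) / tau)`: ranges over `[exp(-1/tau), exp(1/tau)]`,
#' equals 1 for orthogonal patches.
#'
#' @param r_i,r_j Nonzero feature vectors.
#' @param tau Temperature (default 0.07).
#' @return Scalar similarity.
#' @export
patch_similarity <- function(r_i, r_j, tau = 0.07) {
  stopifnot(tau > 0)
  ni <- sqrt(sum(r_i^2)); nj <- sqrt(sum(r_j^2))
  if (ni == 0 || nj == 0) stop("patch vectors must be nonzero", call. = FALSE)
  exp(sum(r_i * r_j) / (ni * nj) / tau)
}

#' Subtype-specific similarity score of a patch
#'
#' Mean of [patch_similarity()] between the patch and each template of the
#' subtype.
#'
#' @param patch Feature vector.
#' @param templates Matrix of template feature vectors (rows), e.g. the
#'   top-20 attention patches of an exemplar slide.
#' @param tau Temperature (default 0.07).
#' @return Scalar score.
#' @export
subtype_score <- function(patch, templates, tau = 0.07) {
  templates <- rbind(templates)
  if (nrow(templates) == 0) stop("template set is empty", call. = FALSE)
  mean(apply(templates, 1L, function(tpl) patch_similarity(patch, tpl, tau)))
}

#' Top-k patches by aggregated attention score
#'
#' @param attention Tibble from [aggregate_attention()] (columns `patch_id`,
#'   `mean_score`).
#' @param k Number of patches to keep (default 20); ties and equal scores
#'   break stably by patch id.
#' @return Tibble of the `k` highest-scoring patches, descending.
#' @export
top_k_patches <- function(attention, k = 20) {
  attention |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$patch_id) |>
    dplyr::slice_head(n = k)
}

#' Attention table for one patient across bag replicates
#'
#' Resamples the patient's bag `n_replicates` times, computes per-replicate
#' attention scores from the first fusion block, and aggregates duplicates
#' and replicates via [aggregate_attention()].
#'
#' @param fit A `patchfuse_fit` with an image branch.
#' @param bag Patch feature matrix with patch ids as row names.
#' @param n_replicates Bag resamples (reference protocol: 100).
#' @return Tibble with `patch_id`, `mean_score`, `n_replicates`.
#' @export
patient_attention <- function(fit, bag, n_replicates = 100) {
  cfg <- fit$pfn_config
  per_rep <- lapply(seq_len(n_replicates), function(r) {
    H <- sample_bag(bag, cfg$n_patches)
    sc <- attention_scores(H, fit$params$pfn, cfg)
    names(sc) <- rownames(H)
    sc
  })
  aggregate_attention(per_rep)
}
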