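# Patient-level evaluation: replicate aggregation by majority voting,
# rank-based AUC with patient-level bootstrap confidence intervals, the
# cross-source representation-gap diagnostic, and the one-sided rank test
# comparing masked-reconstruction errors.

#' Aggregate replicate predictions per patient
#'
#' `vote_fraction` is the fraction of a patient's replicates whose argmax is
#' the positive class (the continuous extension of majority voting, used as
#' the default AUC score); `mean_probability` is the mean positive-class
#' probability.
#'
#' @param predictions Tibble from [predict.patchfuse_fit()].
#' @param positive_class Integer class treated as positive (default 2).
#' @return Tibble with one row per patient: `patient_id`, `label`,
#'   `n_replicates`, `vote_fraction`, `mean_probability`, `majority_vote`.
#' @export
aggregate_patients <- function(predictions, positive_class = 2L) {
  prob_col <- paste0("prob_", positive_class)
  predictions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      label = dplyr::first(.data$label),
      n_replicates = dplyr::n(),
      vote_fraction = mean(.data$pred == positive_class),
      mean_probability = mean(.data[[prob_col]]),
      .groups = "drop") |>
    dplyr::mutate(majority_vote = as.integer(.data$vote_fraction > 0.5))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from pairwise comparisons, ties counted
#' one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; the larger value is the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels == max(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)                  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Patient-level bootstrap of the AUC
#'
#' Resamples patients with replacement `n_boot` times; resamples with a
#' single class are redrawn. Reports the median and the 2.5/97.5 percentile
#' interval.
#'
#' @param patient_scores Tibble from [aggregate_patients()] (or any tibble
#'   with the score and label columns).
#' @param score_col Score column name (default `"vote_fraction"`).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @return One-row tibble: `auc`, `median`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_auc <- function(patient_scores, score_col = "vote_fraction",
                          n_boot = 1000) {
  scores <- patient_scores[[score_col]]
  labels <- patient_scores$label
  n <- length(scores)
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) > 1) break
    }
    aucs[b] <- auc_score(scores[idx], labels[idx])
  }
  qs <- stats::quantile(aucs, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(auc = auc_score(scores, labels), median = qs[2],
                 ci_low = qs[1], ci_high = qs[3], n_boot = n_boot)
}

cosine_distance_matrix <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  1 - tcrossprod(An, Bn)
}

#' Representation gap between two embedding sources
#'
#' Projects the pooled embeddings of both sources onto their first three
#' principal components (one shared basis, so distances are comparable),
#' then reports, per subtype, the mean cosine distance between all
#' cross-source pairs divided by the mean within-reference cosine distance
#' (self-pairs excluded). A ratio below 1 means cross-source representations
#' are closer than representations within the reference source.
#'
#' @param emb_a Embeddings of the evaluation source (rows).
#' @param emb_b Embeddings of the reference source (rows).
#' @param labels_a,labels_b Subtype labels for the rows of each source.
#' @param n_components Number of principal components (default 3).
#' @return Tibble with one row per subtype: `subtype`, `cross_mean`,
#'   `within_ref_mean`, `gap_ratio`.
#' @export
representation_gap <- function(emb_a, emb_b, labels_a, labels_b,
                               n_components = 3) {
  stopifnot(nrow(emb_a) == length(labels_a), nrow(emb_b) == length(labels_b))
  pooled <- rbind(emb_a, emb_b)
  k <- min(n_components, ncol(pooled))
  pca <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  proj <- pca$x[, seq_len(k), drop = FALSE]
  Pa <- proj[seq_len(nrow(emb_a)), , drop = FALSE]
  Pb <- proj[nrow(emb_a) + seq_len(nrow(emb_b)), , drop = FALSE]
  subtypes <- sort(unique(c(labels_a, labels_b)))
  rows <- lapply(subtypes, function(st) {
    A <- Pa[labels_a == st, , drop = FALSE]
    B <- Pb[labels_b == st, , drop = FALSE]
    if (nrow(A) == 0 || nrow(B) < 2) {
      stop(sprintf("subtype %s needs samples in both sources (>= 2 in the reference)", st),
           call. = FALSE)
    }
    cross <- mean(cosine_distance_matrix(A, B))
    DB <- cosine_distance_matrix(B, B)
    within <- mean(DB[upper.tri(DB)])
    tibble::tibble(subtype = st, cross_mean = cross,
                   within_ref_mean = within, gap_ratio = cross / within)
  })
  dplyr::bind_rows(rows)
}

#' One-sided rank test on masked-reconstruction errors
#'
#' Mann-Whitney U test of whether the errors of model A are stochastically
#' smaller than those of model B.
#'
#' @param mse_a,mse_b Numeric error vectors.
#' @return Tibble with `statistic` (U) and `p_value` (one-sided, A < B).
#' @export
compare_masked_mse <- function(mse_a, mse_b) {
  ht <- stats::wilcox.test(mse_a, mse_b, alternative = "less", exact = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Evaluate a fit at patient level
#'
#' Convenience wrapper: predicts on an augmented test set, aggregates per
#' patient and bootstraps the AUC.
#'
#' @param fit A `patchfuse_fit`.
#' @param augmented_test Test-time `augmented_set`.
#' @param score_col Patient score: `"vote_fraction"` (default) or
#'   `"mean_probability"`.
#' @param n_boot Bootstrap resamples.
#' @return List with `patients` (per-patient tibble) and `auc` (one-row
#'   bootstrap summary).
#' @export
evaluate_patients <- function(fit, augmented_test,
                              score_col = "vote_fraction", n_boot = 1000) {
  preds <- stats::predict(fit, augmented_test)
  patients <- aggregate_patients(preds)
  list(patients = patients,
       auc = bootstrap_auc(patients, score_col = score_col, n_boot = n_boot))
}
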