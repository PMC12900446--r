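# Expression preprocessing, patch-bag resampling and construction of the
# augmented training set: each patient contributes R replicates, each pairing
# a fresh with-replacement bag sample of N patches with a fresh Bernoulli
# gene mask; the expression profile and label are copied from the patient.

#' Drop genes with excessive missingness and impute the rest
#'
#' Genes whose missing fraction exceeds `max_missing` (strictly) are removed;
#' remaining `NA`s in the surviving genes are imputed with the gene's
#' cohort mean.
#'
#' @param expr Numeric matrix, genes in rows, patients in columns; `NA`
#'   encodes missing values.
#' @param max_missing Maximum tolerated missing fraction (default 0.2).
#' @return The filtered (and imputed) matrix.
#' @export
filter_genes <- function(expr, max_missing = 0.2) {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0 || ncol(expr) == 0) {
    stop("expression matrix is empty", call. = FALSE)
  }
  frac_na <- rowMeans(is.na(expr))
  keep <- frac_na <= max_missing
  if (!any(keep)) stop("all genes exceed the missingness threshold", call. = FALSE)
  out <- expr[keep, , drop = FALSE]
  na_idx <- which(is.na(out), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    gene_means <- rowMeans(out, na.rm = TRUE)
    out[na_idx] <- gene_means[na_idx[, 1]]
  }
  out
}

#' Keep the most variable genes
#'
#' Ranks genes by variance (on the values as given, i.e. before any log
#' transform unless `expr` is already transformed) and keeps the top `k`,
#' preserving the original row order. Ties are broken stably by input order.
#'
#' @param expr Numeric matrix, genes in rows.
#' @param k Number of genes to keep.
#' @return Matrix with `k` rows.
#' @export
select_top_variable <- function(expr, k = 2000) {
  expr <- as.matrix(expr)
  if (k > nrow(expr)) {
    stop(sprintf("k = %d exceeds the gene count %d", k, nrow(expr)), call. = FALSE)
  }
  v <- apply(expr, 1L, stats::var)
  ord <- order(-v, seq_along(v))      # stable: ties keep input order
  keep <- sort(ord[seq_len(k)])
  expr[keep, , drop = FALSE]
}

#' Log-transform expression values
#'
#' Element-wise `log(1 + x)`; negative inputs are rejected.
#'
#' @param expr Numeric matrix or vector of nonnegative values.
#' @return Transformed object of the same shape.
#' @export
log_transform <- function(expr) {
  if (any(expr < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative for log(1+x)", call. = FALSE)
  }
  log1p(expr)
}

#' Standard expression preprocessing pipeline
#'
#' Missingness filter, top-variable-gene selection (on the pre-log scale by
#' default) and `log(1+x)`, in that order.
#'
#' @inheritParams filter_genes
#' @param n_top Number of variable genes to keep (capped at the gene count).
#' @param rank_post_log Rank variance on the log scale instead of the raw
#'   scale.
#' @return Preprocessed matrix (genes x patients, log scale).
#' @export
preprocess_expression <- function(expr, max_missing = 0.2, n_top = 2000,
                                  rank_post_log = FALSE) {
  out <- filter_genes(expr, max_missing)
  k <- min(n_top, nrow(out))
  if (rank_post_log) {
    out <- log_transform(out)
    out <- select_top_variable(out, k)
  } else {
    out <- select_top_variable(out, k)
    out <- log_transform(out)
  }
  out
}

#' Resample a patch bag to fixed size
#'
#' Draws `n` rows i.i.d. uniformly with replacement from the bag (so bags
#' smaller than `n` are valid).
#'
#' @param bag Numeric matrix, one patch feature vector per row.
#' @param n Sample size (default 200).
#' @return An `n x m` matrix; row names carry the sampled patch ids.
#' @export
sample_bag <- function(bag, n = 200) {
  bag <- as.matrix(bag)
  if (nrow(bag) == 0) stop("patch bag is empty", call. = FALSE)
  idx <- sample.int(nrow(bag), n, replace = TRUE)
  out <- bag[idx, , drop = FALSE]
  ids <- rownames(bag)
  rownames(out) <- if (is.null(ids)) as.character(idx) else ids[idx]
  out
}

#' Build the augmented multimodal training set
#'
#' For every patient, draws `n_replicates` fresh bag samples (each of
#' `n_patches` rows, with replacement) and pairs each with a freshly drawn
#' Bernoulli gene mask. The expression profile and the label are copied from
#' the patient, so the augmented set has exactly
#' `n_replicates * n_patients` samples.
#'
#' @param cohort A cohort list with elements `features` (named list of patch
#'   matrices), `expression` (genes x patients, already preprocessed /
#'   log scale) and `labels` (tibble with `patient_id`, `label`).
#' @param n_patches Bag sample size N (default 200).
#' @param n_replicates Replicates R per patient (default 100).
#' @param mask_ratio Bernoulli mask probability (default 0.7).
#' @param seed Optional integer seed; when given, the sample stream is
#'   reproducible.
#' @return List of class `augmented_set`: `samples` (list of per-replicate
#'   lists with `H`, `g`, `mask`, `y`, `patient_id`, `replicate`) and
#'   `manifest` (tibble of settings).
#' @export
build_augmented <- function(cohort, n_patches = 200, n_replicates = 100,
                            mask_ratio = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- cohort$labels$patient_id
  if (anyDuplicated(ids)) stop("patient ids must be unique", call. = FALSE)
  missing_feat <- setdiff(ids, names(cohort$features))
  missing_expr <- setdiff(ids, colnames(cohort$expression))
  if (length(missing_feat) > 0 || length(missing_expr) > 0) {
    stop(sprintf("patients missing a modality: %s",
                 paste(union(missing_feat, missing_expr), collapse = ", ")),
         call. = FALSE)
  }
  samples <- vector("list", length(ids) * n_replicates)
  k <- 0L
  for (pid in ids) {
    g <- cohort$expression[, pid]
    y <- cohort$labels$label[match(pid, ids)]
    bag <- cohort$features[[pid]]
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      H <- sample_bag(bag, n_patches)
      mk <- mask_profile(g, mask_ratio)
      samples[[k]] <- list(H = H, g = g, g_masked = mk$masked, mask = mk$mask,
                           y = y, patient_id = pid, replicate = r)
    }
  }
  structure(list(
    samples = samples,
    manifest = tibble::tibble(
      n_patients = length(ids), n_replicates = n_replicates,
      n_patches = n_patches, mask_ratio = mask_ratio,
      n_genes = nrow(cohort$expression),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  ), class = "augmented_set")
}

#' @export
print.augmented_set <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<augmented_set> %d samples (%d patients x %d replicates), N = %d, mask ratio = %.2f\n",
              length(x$samples), m$n_patients, m$n_replicates, m$n_patches,
              m$mask_ratio))
  invisible(x)
}

#' Split a cohort at patient level
#'
#' Randomly assigns patients to train/test, stratified by label, with no
#' patient in both sets.
#'
#' @param cohort A cohort list (see [build_augmented()]).
#' @param test_fraction Fraction of patients per class held out.
#' @return The cohort with `labels$split` set to `"train"`/`"test"`.
#' @export
split_cohort <- function(cohort, test_fraction = 1 / 3) {
  labs <- cohort$labels
  split <- rep("train", nrow(labs))
  for (cl in unique(labs$label)) {
    idx <- which(labs$label == cl)
    n_test <- round(length(idx) * test_fraction)
    split[sample(idx, n_test)] <- "test"
  }
  cohort$labels$split <- split
  cohort
}

#' Extract one split of a cohort
#'
#' @param cohort A cohort list whose `labels$split` is set (see
#'   [split_cohort()]).
#' @param which_split `"train"` or `"test"`.
#' @return The cohort restricted to the requested patients.
#' @export
subset_cohort <- function(cohort, which_split) {
  keep <- cohort$labels$split == which_split
  ids <- cohort$labels$patient_id[keep]
  list(features = cohort$features[ids],
       expression = cohort$expression[, ids, drop = FALSE],
       labels = cohort$labels[keep, , drop = FALSE])
}
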