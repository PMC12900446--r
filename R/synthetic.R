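# Synthetic multimodal cohort generator. Each patient carries a latent
# factor u ~ Normal(class mean, 1) with class means 0 and 2 (two latent-SD
# separation). A fraction of patches is informative and shifted in a fixed
# block of feature dimensions by Delta_img * (rho * u + (1 - rho) * v_img);
# a block of signal genes is shifted by Delta_rna * (rho * u + (1 - rho) *
# v_rna), where v_img and v_rna are independent modality-specific factors
# drawn from the same class-mean law. rho therefore controls how much of the
# subtype signal is shared across modalities -- the structure the alignment
# losses exploit. Expression is emitted on an FPKM-like scale (exp of the
# latent log values) so the standard preprocessing path (missingness filter,
# top-variable selection, log(1+x)) is exercised end to end.

#' Configure the synthetic cohort generator
#'
#' @param n_per_class Patients per class (two classes).
#' @param n_patches_range Range of per-patient bag sizes (inclusive).
#' @param feature_dim Patch feature dimension m.
#' @param n_genes Number of genes p.
#' @param n_signal_genes Genes carrying the subtype shift.
#' @param informative_fraction Fraction of a patient's patches carrying the
#'   image shift.
#' @param delta_img,delta_rna Effect sizes of the image and expression
#'   shifts.
#' @param rho Shared-latent weight in \[0, 1\]: fraction of each modality's
#'   signal driven by the common per-patient factor.
#' @param noise_sd_img,noise_sd_rna Gaussian noise SDs.
#' @param missing_rate Element-wise missingness rate injected into the
#'   expression matrix.
#' @param dropout_gene_fraction Fraction of genes given heavy (30%)
#'   missingness, to exercise the missingness filter.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 60, n_patches_range = c(40, 60),
                       feature_dim = 32, n_genes = 200, n_signal_genes = 40,
                       informative_fraction = 0.3, delta_img = 2,
                       delta_rna = 2, rho = 0.8, noise_sd_img = 1,
                       noise_sd_rna = 1, missing_rate = 0.01,
                       dropout_gene_fraction = 0.05) {
  stopifnot(rho >= 0, rho <= 1, informative_fraction >= 0,
            informative_fraction <= 1, missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

# class means of the latent factor (two latent-SD separation)
latent_class_means <- c(0, 2)

#' Generate a synthetic multimodal cohort
#'
#' Draws patch-feature bags, an FPKM-like expression matrix with injected
#' missingness, and binary labels under the planted shared-latent model
#' described in [sim_config()]. With `delta_img = delta_rna = 0` the labels
#' carry no information (null cohort).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for full reproducibility.
#' @return A cohort list: `features` (named list of bag matrices with patch
#'   ids as row names), `expression` (genes x patients, FPKM-like, with
#'   `NA`s), `labels` (tibble with `patient_id`, `label`, `source`, `split`),
#'   and `truth` (tibble of per-patient latent factors).
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * config$n_per_class
  labels <- rep(1:2, each = config$n_per_class)
  ids <- sprintf("P%03d", seq_len(n))
  m <- config$feature_dim
  p <- config$n_genes
  signal_dims <- seq_len(max(1L, floor(m / 4)))
  signal_genes <- seq_len(config$n_signal_genes)

  u <- stats::rnorm(n, latent_class_means[labels], 1)
  v_img <- stats::rnorm(n, latent_class_means[labels], 1)
  v_rna <- stats::rnorm(n, latent_class_means[labels], 1)
  s_img <- config$delta_img * (config$rho * u + (1 - config$rho) * v_img)
  s_rna <- config$delta_rna * (config$rho * u + (1 - config$rho) * v_rna)

  features <- vector("list", n)
  names(features) <- ids
  for (i in seq_len(n)) {
    n_k <- sample(config$n_patches_range[1]:config$n_patches_range[2], 1)
    bag <- matrix(stats::rnorm(n_k * m, 0, config$noise_sd_img), n_k, m)
    n_inf <- round(config$informative_fraction * n_k)
    if (n_inf > 0 && config$delta_img != 0) {
      inf_idx <- sample.int(n_k, n_inf)
      bag[inf_idx, signal_dims] <- bag[inf_idx, signal_dims] + s_img[i]
    }
    rownames(bag) <- sprintf("%s_patch%04d", ids[i], seq_len(n_k))
    features[[i]] <- bag
  }

  base_log <- stats::rnorm(p, 2, 1)          # gene-level baseline, log scale
  log_expr <- matrix(base_log, p, n) +
    matrix(stats::rnorm(p * n, 0, config$noise_sd_rna), p, n)
  if (config$delta_rna != 0 && length(signal_genes) > 0) {
    log_expr[signal_genes, ] <- log_expr[signal_genes, ] +
      matrix(s_rna, length(signal_genes), n, byrow = TRUE)
  }
  expr <- exp(log_expr)                      # FPKM-like nonnegative scale
  rownames(expr) <- sprintf("gene%04d", seq_len(p))
  colnames(expr) <- ids

  n_drop <- round(config$dropout_gene_fraction * p)
  if (n_drop > 0) {
    drop_genes <- sample.int(p, n_drop)
    for (gi in drop_genes) {
      expr[gi, stats::runif(n) < 0.3] <- NA
    }
  }
  if (config$missing_rate > 0) {
    hit <- stats::runif(length(expr)) < config$missing_rate
    expr[hit] <- NA
  }

  list(
    features = features,
    expression = expr,
    labels = tibble::tibble(patient_id = ids, label = labels,
                            source = "A", split = NA_character_),
    truth = tibble::tibble(patient_id = ids, u = u, s_img = s_img,
                           s_rna = s_rna),
    config = config
  )
}

#' Derive a distribution-shifted second source from a cohort
#'
#' Applies an affine perturbation (per-dimension scaling drift and offset)
#' plus extra Gaussian noise to every patch feature matrix, while keeping
#' labels, expression and the shared per-patient latent intact. Emulates a
#' tissue-preservation (e.g. FFPE vs snap-frozen) source shift for the
#' transfer and representation-gap analyses. `shift = 0` reproduces the
#' source distribution (new noise draws only).
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param shift Magnitude of the affine perturbation (0 = none).
#' @param extra_noise_sd Additional per-entry Gaussian noise SD.
#' @param seed Optional integer seed.
#' @return A cohort list with perturbed `features` and `source = "B"`.
#' @export
generate_shifted_source <- function(cohort, shift = 0.5, extra_noise_sd = 0.2,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(cohort$features[[1]])
  scale_vec <- 1 + shift * stats::runif(m, -0.5, 0.5)
  offset <- shift * stats::rnorm(m)
  features <- lapply(cohort$features, function(bag) {
    out <- sweep(sweep(bag, 2, scale_vec, "*"), 2, offset, "+")
    if (extra_noise_sd > 0 && shift > 0) {
      out <- out + matrix(stats::rnorm(length(out), 0, extra_noise_sd),
                          nrow(out), ncol(out))
    }
    rownames(out) <- rownames(bag)
    out
  })
  out <- cohort
  out$features <- features
  out$labels$source <- "B"
  out
}

# ---- plain-text cohort round-trip -----------------------------------------

#' Write a cohort to plain-text files
#'
#' Layout: `expression.tsv` (genes x patients, patient ids as header),
#' `labels.csv`, one `features/<patient>.tsv` per patient (patch ids in the
#' first column), and `manifest.json`-style TSV of settings.
#'
#' @param cohort Cohort list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE, showWarnings = FALSE)
  expr_df <- tibble::as_tibble(cohort$expression, rownames = "gene_id")
  readr::write_tsv(expr_df, file.path(dir, "expression.tsv"))
  readr::write_csv(cohort$labels, file.path(dir, "labels.csv"))
  for (pid in names(cohort$features)) {
    bag <- cohort$features[[pid]]
    df <- tibble::as_tibble(bag, rownames = "patch_id", .name_repair = "minimal")
    names(df) <- c("patch_id", sprintf("f%03d", seq_len(ncol(bag))))
    readr::write_tsv(df, file.path(dir, "features", paste0(pid, ".tsv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A cohort list (`features`, `expression`, `labels`).
#' @export
read_cohort <- function(dir) {
  expr_df <- readr::read_tsv(file.path(dir, "expression.tsv"),
                             show_col_types = FALSE)
  expr <- as.matrix(expr_df[, -1])
  rownames(expr) <- expr_df[[1]]
  labels <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  files <- list.files(file.path(dir, "features"), pattern = "\\.tsv$",
                      full.names = TRUE)
  features <- lapply(files, function(f) {
    df <- readr::read_tsv(f, show_col_types = FALSE)
    bag <- as.matrix(df[, -1])
    rownames(bag) <- df[[1]]
    bag
  })
  names(features) <- sub("\\.tsv$", "", basename(files))
  features <- features[labels$patient_id]
  list(features = features, expression = expr, labels = labels)
}
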