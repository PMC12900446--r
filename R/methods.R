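# Tidiers and plots for fitted models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#'
#' One row per epoch and loss component, with the per-epoch mean of the
#' per-batch values.
#'
#' @param x A `patchfuse_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `component`, `value`.
#' @method tidy patchfuse_fit
#' @export
tidy.patchfuse_fit <- function(x, ...) {
  x$history |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(dplyr::across(c("ce", "align", "con", "recon", "total"),
                                   mean), .groups = "drop") |>
    tidyr::pivot_longer(-"epoch", names_to = "component", values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x A `patchfuse_fit`.
#' @param ... Unused.
#' @return Tibble with the variant, epoch/step counts and final-epoch mean
#'   losses.
#' @method glance patchfuse_fit
#' @export
glance.patchfuse_fit <- function(x, ...) {
  last <- x$history |> dplyr::filter(.data$epoch == max(.data$epoch))
  tibble::tibble(
    variant = x$config$variant,
    epochs = x$config$epochs,
    n_steps = nrow(x$history),
    final_total = mean(last$total),
    final_ce = mean(last$ce),
    final_recon = mean(last$recon)
  )
}

#' Plot training loss curves
#'
#' @param object A `patchfuse_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean loss components.
#' @method autoplot patchfuse_fit
#' @export
autoplot.patchfuse_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean batch loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-patient scores against labels
#'
#' @param patients Tibble from [aggregate_patients()].
#' @return A ggplot jitter plot of vote fractions by class.
#' @export
plot_patient_scores <- function(patients) {
  patients |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$label),
                                 y = .data$vote_fraction)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "subtype", y = "positive vote fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @keywords internal
NULL
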