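#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection result
#'
#' @param x An `aic_selection`.
#' @param ... Unused.
#' @return One row per selection step: `step`, `feature_id`, `aic` (exact AIC
#'   of the selection after the step) and one `nmi_<target>` column per target.
#' @export
tidy.aic_selection <- function(x, ...) {
  base <- tibble::tibble(step = seq_along(x$selected),
                         feature_id = x$selected,
                         aic = x$aic_trace)
  wide <- tidyr::pivot_wider(x$per_target_trace, names_from = "target_id",
                             values_from = "norm_mi", names_prefix = "nmi_")
  dplyr::left_join(base, wide, by = "step")
}

#' @rdname tidy.aic_selection
#' @export
glance.aic_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    final_aic = x$aic_trace[length(x$aic_trace)],
    method = x$config$method,
    subsample_size = x$config$subsample_size %||% NA_integer_,
    seed = x$config$seed
  )
}

#' Plot the information growth of a selection
#'
#' Per-target normalized MI after each selection step (thin lines) with the
#' AIC mean overlaid (thick line).
#'
#' @param object An `aic_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aic_selection <- function(object, ...) {
  tr <- object$per_target_trace
  mean_tr <- tibble::tibble(step = seq_along(object$aic_trace),
                            aic = object$aic_trace)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$norm_mi,
                                   colour = .data$target_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_line(data = mean_tr,
                       ggplot2::aes(x = .data$step, y = .data$aic),
                       inherit.aes = FALSE, linewidth = 1) +
    ggplot2::labs(x = "bits selected", y = "normalized mutual information",
                  colour = "target") +
    ggplot2::ylim(0, 1)
}

#' Tidy cross-validation results
#'
#' @param x An `aic_cv`.
#' @param ... Unused.
#' @return The per-fold tibble (`target_id`, `fold`, `n_bits`, `mcc`,
#'   `norm_mi`).
#' @export
tidy.aic_cv <- function(x, ...) x$folds

#' @rdname tidy.aic_cv
#' @export
glance.aic_cv <- function(x, ...) {
  tibble::tibble(
    k = x$config$k,
    n_bits = x$config$n_select,
    mean_mcc = mean(x$folds$mcc),
    mean_norm_mi = mean(x$folds$norm_mi),
    seed = x$config$seed
  )
}

#' Plot per-target cross-validated scores
#'
#' @param object An `aic_cv`.
#' @param metric `"mcc"` or `"norm_mi"`.
#' @param ... Unused.
#' @return A ggplot object (one box of fold scores per target).
#' @export
autoplot.aic_cv <- function(object, metric = c("mcc", "norm_mi"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$target_id, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "target", y = metric)
}

#' Plot an information curve
#'
#' @param curve Output of [information_curve()].
#' @return A ggplot object.
#' @export
plot_information_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_bits, y = .data$norm_mi,
                                      colour = .data$target_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$aic), colour = "black",
                       linewidth = 1) +
    ggplot2::labs(x = "bits selected", y = "normalized mutual information",
                  colour = "target") +
    ggplot2::ylim(0, 1)
}
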