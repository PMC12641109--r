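#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decision curve
#'
#' Net benefit of the model, treat-all and treat-none policies across the
#' threshold-probability grid.
#'
#' @param object a `dca_curve` from [decision_curve()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot dca_curve
#' @export
autoplot.dca_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::starts_with("net_benefit_"),
                              names_to = "policy",
                              names_prefix = "net_benefit_",
                              values_to = "net_benefit")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                     y = .data$net_benefit,
                                     colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fold-level cross-validation metrics
#'
#' @param object a `cv_report`
#' @param ... unused
#' @return a ggplot (one box per metric over the fold values)
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              cols = c("auc", "precision", "recall",
                                       "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "fold value") +
    ggplot2::theme_minimal()
}

#' Average modality attention weights
#'
#' Bar chart of the mean per-branch attention weight across a report's
#' folds: the modality-importance view of the fusion model.
#'
#' @param report a fusion `cv_report`
#' @return a ggplot
#' @export
plot_attention_weights <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  if (is.null(report$attention)) stop("report carries no attention weights")
  avg <- dplyr::group_by(report$attention, .data$branch) |>
    dplyr::summarise(sem = if (dplyr::n() > 1) compute_sem(.data$mean_alpha)
                           else 0,
                     mean_alpha = mean(.data$mean_alpha), .groups = "drop")
  avg$branch <- factor(avg$branch, levels = mgmt_branches())
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$branch,
                                    y = .data$mean_alpha)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_alpha - .data$sem,
                                        ymax = .data$mean_alpha + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = "branch", y = "mean attention weight") +
    ggplot2::theme_minimal()
}
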