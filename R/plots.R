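#' Muller-style stacked-area plot of lineage trajectories
#'
#' Plots each lineage's exclusive frequency as a stacked area over time; the
#' grey band on top is the residual — population diversity not represented by
#' any tracked lineage ("white space" in the field's usual rendering).
#'
#' @param object a `lineage_trajectories` tibble.
#' @param ... unused.
#' @return a `ggplot` object.
#' @export
autoplot.lineage_trajectories <- function(object, ...) {
  excl <- exclusive_frequencies(object)
  res <- dplyr::distinct(excl, .data$timepoint, .data$residual)
  layers <- dplyr::bind_rows(
    dplyr::transmute(excl,
      timepoint = .data$timepoint, lineage = .data$lineage,
      fraction = .data$exclusive
    ),
    dplyr::transmute(res,
      timepoint = .data$timepoint, lineage = "(untracked)",
      fraction = .data$residual
    )
  )
  layers$lineage <- stats::relevel(factor(layers$lineage), ref = "(untracked)")
  ggplot2::ggplot(
    layers,
    ggplot2::aes(.data$timepoint, .data$fraction, fill = .data$lineage)
  ) +
    ggplot2::geom_area(position = "stack", color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c("(untracked)" = "grey85",
        stats::setNames(
          scales_hue(nlevels(layers$lineage) - 1),
          setdiff(levels(layers$lineage), "(untracked)")
        )
      )
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1.001), expand = c(0, 0)) +
    ggplot2::labs(
      x = "days since season start", y = "population fraction",
      fill = "lineage"
    ) +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) grDevices::hcl(h = seq(15, 375, length.out = n + 1)[-(n + 1)], c = 100, l = 65)

#' @rdname autoplot.lineage_trajectories
#' @export
plot_trajectories <- function(object, ...) autoplot.lineage_trajectories(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname infer_trajectories
#' @param x a `lineage_trajectories` tibble.
#' @param ... passed on.
#' @export
tidy.lineage_trajectories <- function(x, ...) {
  exclusive_frequencies(x)
}

#' @rdname infer_trajectories
#' @export
glance.lineage_trajectories <- function(x, ...) {
  per_t <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$timepoint),
    loglik = dplyr::first(.data$loglik),
    converged = all(.data$converged),
    residual = dplyr::first(.data$residual),
    .groups = "drop"
  )
  tibble::tibble(
    n_timepoints = nrow(per_t),
    n_lineages = length(unique(x$lineage)),
    all_converged = all(per_t$converged),
    mean_residual = mean(per_t$residual),
    total_loglik = sum(per_t$loglik)
  )
}
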