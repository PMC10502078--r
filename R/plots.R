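#' Forest plot of stratified food effects
#'
#' Point estimates with 95% CIs of each food's effect on the outcome within
#' the low and high genetic-risk groups, one facet row per food. Requires
#' ggplot2.
#'
#' @param stratifiedList named list of [stratifiedEffects()] results (names =
#'   foods).
#' @return A ggplot object.
#' @export
plotStratifiedEffects <- function(stratifiedList) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- do.call(rbind, lapply(names(stratifiedList), function(food) {
    cbind(food = food, stratifiedList[[food]]$by_group)
  }))
  df$group <- factor(df$group, levels = c("low", "high"))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$b, y = .data$group, xmin = .data$ci_low, xmax = .data$ci_high)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$food)) +
    ggplot2::labs(
      x = "effect of weekly food frequency on BMIz (b, 95% CI)",
      y = "genetic-risk group"
    ) +
    ggplot2::theme_bw()
}
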