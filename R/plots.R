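#' Scatter of SWB against a standardized volume with the fitted curve
#'
#' One point per person, colored by study, with the quadratic curve implied
#' by the mixed-model linear and quadratic coefficients overlaid (covariates
#' held at their means).
#'
#' @param cohort Cohort tibble.
#' @param region Region name.
#' @param hemisphere `"l"` or `"r"`.
#' @return A ggplot object.
#' @export
plot_swb_volume <- function(cohort, region = "hippocampus",
                            hemisphere = c("l", "r")) {
  hemisphere <- match.arg(hemisphere)
  vc <- paste0("volume_", region, "_", hemisphere)
  fit <- fit_region_model(cohort, vc)
  z <- zscore(cohort[[vc]])
  b <- fit$beta
  grid <- tibble::tibble(z = seq(min(z), max(z), length.out = 200))
  # curve centered at the covariate-adjusted mean outcome
  base <- mean(cohort$swb) - b[["vol_lin"]] * mean(z) - b[["vol_quad"]] * mean(z^2)
  grid$fit <- base + b[["vol_lin"]] * grid$z + b[["vol_quad"]] * grid$z^2
  df <- tibble::tibble(z = z, swb = cohort$swb, study = factor(cohort$study))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$swb)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$study), alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$z, y = .data$fit),
                       linewidth = 1, inherit.aes = FALSE) +
    ggplot2::labs(x = paste0("Z-scored ", region, " volume (",
                             toupper(hemisphere), ")"),
                  y = "SWB", color = "Study") +
    ggplot2::theme_minimal()
}

#' Forest-style display of an association scan
#'
#' @param object An [association_scan()] result.
#' @param term `"linear"` or `"quadratic"`.
#' @param ... Unused.
#' @return A ggplot object with one estimate and 95% interval per
#'   region x hemisphere, significant rows highlighted.
#' @method autoplot swb_assoc_scan
#' @export
autoplot.swb_assoc_scan <- function(object, term = c("linear", "quadratic"), ...) {
  term <- match.arg(term)
  est <- if (term == "linear") object$lin_est else object$quad_est
  se <- if (term == "linear") object$lin_se else object$quad_se
  sig <- if (term == "linear") object$lin_sig else object$quad_sig
  df <- tibble::tibble(
    label = paste(object$region, object$hemisphere),
    est = est, lo = est - 1.96 * se, hi = est + 1.96 * se,
    sig = factor(ifelse(sig, "significant", "ns"),
                 levels = c("ns", "significant"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$label,
                                   color = .data$sig)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::scale_color_manual(values = c(ns = "grey40", significant = "firebrick")) +
    ggplot2::labs(x = paste(term, "term estimate"), y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
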