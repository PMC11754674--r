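#' Plot methods
#'
#' ggplot2 visualizations of the package's result objects: a SNP-effect
#' scatter with the fitted slope for univariable MR fits, posterior bars for
#' a colocalization result, an h4 tile map for a sensitivity grid, and a
#' forest-style UVMR-versus-MVMR comparison for a mediation call.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name protscreen-plots
NULL

#' @rdname protscreen-plots
#' @export
autoplot.mr_result <- function(object, ...) {
  h <- object$data
  ggplot2::ggplot(h, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                   ymax = .data$beta_out + .data$se_out),
      linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                   xmax = .data$beta_exp + .data$se_exp),
      linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(intercept = 0, slope = object$estimate,
                         colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("SNP effect on %s", object$exposure),
      y = sprintf("SNP effect on %s", object$outcome),
      title = sprintf("%s: %.3f (95%% CI %.3f to %.3f)", object$method,
                      object$estimate, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' @rdname protscreen-plots
#' @export
autoplot.coloc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability",
                  title = sprintf("%s vs %s (%d variants)", object$trait1,
                                  object$trait2, object$n_variants)) +
    ggplot2::theme_minimal()
}

#' @rdname protscreen-plots
#' @export
autoplot.coloc_grid <- function(object, ...) {
  d <- as_tibble(object)
  d$priors <- sprintf("p12 = %.0e", d$p12)
  d$window <- factor(sprintf("%g kb", d$window_bp / 1000),
                     levels = sprintf("%g kb", sort(unique(d$window_bp)) / 1000))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$priors,
                                  fill = .data$h4)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$h4)),
                       colour = "white") +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "grey30",
                                 high = "firebrick") +
    ggplot2::labs(x = "window", y = "prior set",
                  title = sprintf("h4 sensitivity grid (robust: %s)",
                                  attr(object, "robust"))) +
    ggplot2::theme_minimal()
}

#' @rdname protscreen-plots
#' @export
autoplot.mediation_call <- function(object, ...) {
  d <- tibble(
    model = factor(c("UVMR", "MVMR (adjusted)"),
                   levels = c("MVMR (adjusted)", "UVMR")),
    estimate = c(object$uvmr_estimate, object$mvmr_estimate),
    lo = c(object$uvmr_ci[1], object$mvmr_ci[1]),
    hi = c(object$uvmr_ci[2], object$mvmr_ci[2])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log odds ratio per SD", y = NULL,
                  title = sprintf("mediation flag: %s", object$mediation_flag)) +
    ggplot2::theme_minimal()
}
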