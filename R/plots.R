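#' Plot a PCoA ordination
#'
#' @param object A `pcoa_ord` from [pcoa()].
#' @param colour Optional vector (one per sample) mapped to point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_ord <- function(object, colour = NULL, ...) {
  df <- object$points
  pe <- object$prop_explained
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, 100 * pe[i])
  if (!is.null(colour)) df$.colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$.colour), size = 2) +
      ggplot2::labs(colour = NULL)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Occupancy-abundance plot of a neutral-model fit
#'
#' Observed occurrence frequencies against log10 mean relative abundance,
#' with the fitted neutral expectation and its confidence band; points are
#' coloured by their above/neutral/below state.
#'
#' @param object An `ncm_fit` from [fit_ncm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  df <- dplyr::arrange(object$taxa, .data$mean_rel_abundance)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_rel_abundance))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_frequency)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_frequency,
                                     colour = .data$state), size = 1.2) +
    ggplot2::scale_colour_manual(values = c(above = "#2166ac",
                                            neutral = "grey40",
                                            below = "#b2182b")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  colour = NULL,
                  subtitle = sprintf("m = %.3g, Nm = %.3g, R2 = %.2f",
                                     object$m_hat, object$Nm, object$r2)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of colonization calls
#'
#' Prevalence change (AD - JU) against -log10 binomial p, coloured by class.
#'
#' @param calls Output of [classify_colonization()].
#' @param alpha Significance level drawn as a horizontal reference.
#' @return A ggplot.
#' @export
plot_colonization <- function(calls, alpha = 0.1) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$delta, y = .data$neg_log10_p,
                                      colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(early = "#b2182b",
                                            persistent = "grey50",
                                            late = "#2166ac")) +
    ggplot2::labs(x = "prevalence change (AD - JU)", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Trajectory-divergence plot
#'
#' Per-feature prevalence change in the exposed group (x) against the control
#' group (y) with the y = x reference diagonal; points above the diagonal are
#' taxa whose development is accelerated in the exposed group.
#'
#' @param object A `trajectory_comparison` from [compare_trajectories()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_comparison <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$x_exposed, y = .data$y_control,
                               colour = .data$interpretation)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$y_control - .data$x_exposed)),
                        alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 4), guide = "none") +
    ggplot2::labs(x = "prevalence change, exposed (AD - JU, %)",
                  y = "prevalence change, control (AD - JU, %)",
                  colour = NULL,
                  subtitle = sprintf("paired signed-rank p = %.3g; %.0f%% above diagonal",
                                     object$paired_wilcoxon_p,
                                     100 * object$fraction_above_diagonal)) +
    ggplot2::theme_minimal()
}

#' Stacked assembly-process fractions
#'
#' @param object An `assembly_classification` from [classify_processes()],
#'   or a named list of them (one bar per name).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_classification <- function(object, ...) {
  df <- dplyr::mutate(object$fractions, contrast = "all pairs")
  plot_process_fractions(df)
}

#' @rdname autoplot.assembly_classification
#' @param classifications Named list of `assembly_classification` objects.
#' @export
plot_assembly_processes <- function(classifications) {
  df <- dplyr::bind_rows(lapply(names(classifications), function(nm) {
    dplyr::mutate(classifications[[nm]]$fractions, contrast = nm)
  }))
  plot_process_fractions(df)
}

plot_process_fractions <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
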