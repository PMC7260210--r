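#' Plot PCA coordinates of a GRM
#'
#' Scatter of two principal components colored by subpopulation (and shaped
#' by coat color when present), with variance proportions in the axis
#' labels.
#'
#' @param object A `subpop_pca`.
#' @param components Length-2 integer vector of components to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subpop_pca
#' @export
autoplot.subpop_pca <- function(object, components = c(1L, 2L), ...) {
  cc <- object$coordinates
  xs <- paste0("PC", components[1]); ys <- paste0("PC", components[2])
  lab <- function(k) sprintf("PC%d (%.2f%%)", k,
                             100 * object$variance_proportions[k])
  ggplot2::ggplot(cc, ggplot2::aes(.data[[xs]], .data[[ys]],
                                   color = .data$subpop)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(components[1]), y = lab(components[2]),
                  color = "subpopulation") +
    ggplot2::theme_minimal()
}

#' Plot LD decay curves
#'
#' Mean r-squared per distance bin, one line per subpopulation.
#'
#' @param decay Tibble from [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  d <- decay[!is.na(decay$mean_r2), ]
  d$mid_kb <- (d$bin_lo + d$bin_hi) / 2e3
  ggplot2::ggplot(d, ggplot2::aes(.data$mid_kb, .data$mean_r2,
                                  color = .data$subpop)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "inter-marker distance (kb)",
                  y = expression(mean ~ r^2), color = "subpopulation") +
    ggplot2::theme_minimal()
}

#' Plot persistence of phase across distance bins
#'
#' @param phase Tibble from [phase_persistence()].
#' @return A ggplot object.
#' @export
plot_phase_persistence <- function(phase) {
  d <- phase[!is.na(phase$phase_corr), ]
  d$mid_mb <- (d$bin_lo + d$bin_hi) / 2e6
  ggplot2::ggplot(d, ggplot2::aes(.data$mid_mb, .data$phase_corr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "inter-marker distance (Mb)",
                  y = "correlation of signed r between subpopulations") +
    ggplot2::theme_minimal()
}

#' Genome-wide score track plot
#'
#' Manhattan-style display of a per-SNP or per-window score with an
#' optional horizontal threshold line. Works for autozygosity tracks
#' (`score` column), varLD tracks (`std_score`) and F_ST windows
#' (`theta`).
#'
#' @param track A tibble with `chrom`, a position column and a score
#'   column.
#' @param score Name of the score column.
#' @param pos Name of the position column (default `"pos_bp"`, falling
#'   back to `"start_bp"`).
#' @param threshold Optional horizontal cutoff to draw.
#' @return A ggplot object.
#' @export
plot_score_track <- function(track, score, pos = NULL, threshold = NULL) {
  if (is.null(pos)) pos <- if ("pos_bp" %in% names(track)) "pos_bp" else
    "start_bp"
  d <- track
  d$chrom <- factor(d$chrom, levels = unique(d$chrom))
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data[[pos]] / 1e6,
                                        .data[[score]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = score) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = threshold,
                                   color = "red", linetype = 2)
  }
  gg
}
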