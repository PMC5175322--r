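#' Plot an observed mSFS
#'
#' Bar chart of class counts over the segregating epiallelic classes.
#'
#' @param object An [msfs()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msfs <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$b, y = .data$count)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "number of unmethylated accessions (b)",
      y = "segregating sites",
      title = sprintf("mSFS (n = %d)", msfs_n(object))
    )
}

#' Plot observed versus fitted mSFS class frequencies
#'
#' Side-by-side bars of the observed class frequencies and the fitted
#' conditional spectrum `q_{n,b}`.
#'
#' @param object An `msfs_fit` from [fit_msfs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msfs_fit <- function(object, ...) {
  counts <- msfs_counts(object$msfs)
  df <- tibble::tibble(
    b = rep(seq_len(object$n - 1L), 2),
    frequency = c(counts / sum(counts), object$fitted_q$q[2:object$n]),
    source = rep(c("observed", "fitted"), each = object$n - 1L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$frequency,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(observed = "firebrick",
                                          fitted = "pink")) +
    ggplot2::labs(
      x = "number of unmethylated accessions (b)",
      y = "frequency among segregating sites",
      title = sprintf("mSFS fit (n = %d, %s model)", object$n,
                      object$selected_model)
    )
}

#' Plot a windowed methylation diversity track
#'
#' @param object A `diversity_track` from [windowed_diversity()] or
#'   [predict_regional_diversity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diversity_track <- function(object, ...) {
  df <- object[!is.na(object$diversity), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$diversity
  )) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)",
                  y = "mean pairwise methylation diversity")
}

#' Plot expected methylome divergence over time
#'
#' Draws the closed-form divergence curve [divergence_curve()] and its
#' saturation asymptote for one or more rate sets.
#'
#' @param rates An [epimutation_rates()] object or a named list of them.
#' @param t_max Number of generations to draw.
#' @return A ggplot.
#' @export
plot_divergence_curve <- function(rates, t_max = 5000) {
  rate_list <- if (inherits(rates, "epi_rates")) {
    setNames(list(rates), rates$annotation_class %||% "rates")
  } else {
    rates
  }
  t <- seq(0, t_max, length.out = 400)
  df <- purrr::imap_dfr(rate_list, function(rr, nm) {
    tibble::tibble(class = nm, t = t, divergence = divergence_curve(rr, t))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$divergence,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generations since common founder",
                  y = "expected pairwise divergence")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
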