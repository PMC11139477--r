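#' @export
autoplot.metaprofile <- function(object, ...) {
  p <- attr(object, "params")
  d <- as_tibble(object)
  body_start <- p$n_flank_bins + 0.5
  body_end <- p$n_flank_bins + p$n_body_bins + 0.5
  ylab <- if (p$signal == "methylation") "methylation level" else "mean signal"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean_signal)) +
    ggplot2::annotate("rect", xmin = body_start, xmax = body_end,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin (5' flank | scaled body | 3' flank)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cooccurrence_matrix <- function(object, ...) {
  d <- tidy(object) |>
    mutate(set_a = factor(.data$set_a, levels = object$leaf_order),
           set_b = factor(.data$set_b, levels = object$leaf_order)) |>
    filter(!is.na(.data$set_a), !is.na(.data$set_b))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set_a, y = .data$set_b,
                                  fill = log2(pmax(.data$fold, 2^-6)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "log2 obs/exp") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a chromosomal window profile
#'
#' One panel per chromosome, pericentromeric windows shaded gray.
#'
#' @param profile Output of [chromosomal_profile()].
#' @param genome The `genome_model` or `sim_genome` the profile was built on.
#' @return A ggplot object.
#' @export
plot_chromosomal_profile <- function(profile, genome) {
  gm <- as_genome_model(genome)
  pc <- gm$pericentromeres[gm$pericentromeres$chrom %in% unique(profile$chrom), ,
                           drop = FALSE]
  d <- mutate(profile, mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$value))
  if (nrow(pc) > 0) {
    p <- p + ggplot2::geom_rect(
      data = pc,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "gray85", inherit.aes = FALSE
    )
  }
  if ("context" %in% names(d)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$context))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "windowed value") +
    ggplot2::theme_minimal()
}

#' Density plot of per-feature methylation differences
#'
#' Kernel-density view of the per-feature level differences from
#' [methylation_difference_density()], optionally split by a class column.
#'
#' @param diffs Output of [methylation_difference_density()].
#' @param by Optional class column to color by (e.g. `"class"`).
#' @return A ggplot object.
#' @export
plot_methylation_difference <- function(diffs, by = NULL) {
  d <- filter(diffs, !is.na(.data$diff))
  if (!is.null(by)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$diff, color = .data[[by]])) +
      ggplot2::geom_density() +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "methylation difference (A - B)", y = "density") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$diff)) +
      ggplot2::geom_density() +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "methylation difference (A - B)", y = "density") +
      ggplot2::theme_minimal()
  }
}
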