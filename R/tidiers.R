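#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PCO ordination into per-taxon scores
#'
#' @param x A [pco()] result.
#' @param ... Unused.
#' @return Tibble with `taxon`, score columns `PC1..PCk`, and any group
#'   labels attached to the ordination.
#' @export
tidy.pco <- function(x, ...) {
  out <- dplyr::bind_cols(tibble(taxon = x$taxa), as_tibble(x$scores))
  if (!is.null(x$groups)) out <- dplyr::left_join(out, x$groups, by = "taxon")
  out
}

#' One-row summary of a PCO ordination
#'
#' @inheritParams tidy.pco
#' @return Tibble with axis counts and leading variance fractions (as
#'   percentages of the positive-eigenvalue variance).
#' @export
glance.pco <- function(x, ...) {
  vf <- x$variance_fraction
  tibble(n_taxa = base::length(x$taxa),
         n_axes = ncol(x$scores),
         n_negative_eigenvalues = x$n_negative,
         pc1_pct = 100 * vf[1],
         pc2_pct = 100 * if (base::length(vf) > 1) vf[2] else NA_real_,
         pc3_pct = 100 * if (base::length(vf) > 2) vf[3] else NA_real_)
}

#' Tidy a permutational MANOVA result
#'
#' @param x An [npmanova()] result.
#' @param ... Unused.
#' @return One-row tibble with `statistic` (pseudo-F), `p_value`, `n_perm`,
#'   `method`.
#' @export
tidy.npmanova <- function(x, ...) {
  tibble(statistic = x$F, p_value = x$p, n_perm = x$n_perm, method = x$method)
}

#' @rdname tidy.npmanova
#' @export
glance.npmanova <- function(x, ...) tidy.npmanova(x)

#' Per-element von Mises stresses as a tibble
#'
#' @param x A `solution_field` from [solve_static()].
#' @param ... Unused.
#' @return Tibble with `element` and `von_mises_MPa`.
#' @export
tidy.solution_field <- function(x, ...) {
  tibble(element = seq_along(x$von_mises), von_mises_MPa = x$von_mises)
}

#' Functionspace scatter of taxa on two PCO axes
#'
#' @param object A [pco()] result.
#' @param axes Two axes to plot.
#' @param colour Optional group column name (from the attached groups) to
#'   colour by; defaults to the first group label if present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pco <- function(object, axes = c(1, 2), colour = NULL, ...) {
  df <- tidy.pco(object)
  vf <- 100 * object$variance_fraction
  ax <- colnames(object$scores)[axes]
  colour <- colour %||% (if (!is.null(object$groups)) setdiff(names(object$groups), "taxon")[1] else NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", ax[1], vf[axes[1]]),
                  y = sprintf("%s (%.1f%%)", ax[2], vf[axes[2]])) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Phylomorphospace plot from projected edge segments
#'
#' Draws the time-scaled phylogeny inside the functionspace: one segment per
#' branch, tips at their observed scores.
#'
#' @param segments Result of [project_phylomorphospace()].
#' @return A ggplot.
#' @export
plot_phylomorphospace <- function(segments) {
  ggplot2::ggplot(segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$parent_x, y = .data$parent_y,
                                       xend = .data$child_x, yend = .data$child_y),
                          colour = "grey50") +
    ggplot2::geom_point(data = segments[segments$child_is_tip, ],
                        ggplot2::aes(x = .data$child_x, y = .data$child_y), size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Stress comparison bar chart
#'
#' @param object A `craniomech_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot of min/mean/max element von Mises stress per model.
#' @export
autoplot.craniomech_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("model", "min_vm_MPa", "mean_vm_MPa", "max_vm_MPa")],
                            -"model", names_to = "summary", values_to = "MPa")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$summary, y = .data$MPa, fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "element von Mises stress (MPa)",
                  subtitle = paste(attr(object, "mode"), "comparison")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
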