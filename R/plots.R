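# ggplot2 views of the main result types.

#' Plot per-locus diversity
#'
#' Bar panel of nucleotide diversity and polymorphic-site counts per locus
#' (the concatenated row is dropped).
#'
#' @param object A `mlst_diversity` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mlst_diversity
#' @export
autoplot.mlst_diversity <- function(object, ...) {
  df <- object |>
    filter(.data$locus != "concatenated") |>
    select("locus", pi = "pi", `polymorphic sites` = "n_polymorphic_sites") |>
    tidyr::pivot_longer(-"locus", names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-locus diversity") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of the index of association
#'
#' Histogram of permuted `V_D` values with the observed `V_D` marked;
#' requires a fit computed with `n_perm > 0`.
#'
#' @param object A `mlst_linkage` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mlst_linkage
#' @export
autoplot.mlst_linkage <- function(object, ...) {
  if (length(object$permuted_v_d) == 0) {
    rlang::abort("no permutation null stored; rerun with n_perm > 0")
  }
  ggplot2::ggplot(
    tibble(v_d = object$permuted_v_d),
    ggplot2::aes(x = .data$v_d)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$v_d, linewidth = 1) +
    ggplot2::labs(
      x = "permuted V_D", y = "count",
      title = sprintf(
        "I_A = %.4f, I_A^S = %.4f, P = %.3f",
        object$i_a, object$i_a_s, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a minimum spanning tree of sequence types
#'
#' Nodes are STs sized by isolate count (coloured by dominant source when
#' available); edge line types follow the allelic-distance display classes.
#'
#' @param mst An `mlst_mst` object.
#' @param seed Layout seed (Fruchterman-Reingold).
#' @return A ggplot object.
#' @export
plot_mst <- function(mst, seed = 1L) {
  g <- mst_igraph(mst)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- bind_cols(mst$nodes, tibble(x = xy[, 1], y = xy[, 2]))
  edges <- mst$edges |>
    left_join(select(nodes, st = "st", x0 = "x", y0 = "y"), by = c(from = "st")) |>
    left_join(select(nodes, st = "st", x1 = "x", y1 = "y"), by = c(to = "st"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = filter(edges, .data$link_class != "suppressed"),
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linetype = .data$link_class
      )
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y, size = .data$n_isolates,
        colour = .data$source
      )
    ) +
    ggplot2::scale_linetype_manual(
      values = c(bold = "solid", thin = "solid", dotted = "dotted")
    ) +
    ggplot2::labs(title = "Minimum spanning tree of allelic profiles") +
    ggplot2::theme_void()
}
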