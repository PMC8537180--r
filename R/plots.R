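#' Heatmap of the correlated-mutation score matrix
#'
#' @param object A `cma_result`.
#' @param min_score Only pairs at or above this score are drawn (keeps the
#'   raster readable for wide alignments). Default 0 draws everything.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cma_result <- function(object, min_score = 0, ...) {
  pairs <- tidy(object)
  pairs <- pairs[pairs$score >= min_score, ]
  both <- dplyr::bind_rows(pairs,
                           dplyr::rename(pairs, column_i = "column_j",
                                         column_j = "column_i"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$column_i, y = .data$column_j,
                                     fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "score") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "alignment column", y = "alignment column",
                  title = "Correlated-mutation scores") +
    ggplot2::theme_minimal()
}

#' Plot the co-evolution network
#'
#' Positions on a circle, edges weighted by score, the highest-degree
#' position highlighted.
#'
#' @param object A `coevolution_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coevolution_network <- function(object, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty co-evolution network") +
             ggplot2::theme_void())
  }
  theta <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
  nodes$x <- cos(theta); nodes$y <- sin(theta)
  lookup <- setNames(seq_len(nrow(nodes)), nodes$column)
  edges <- object$edges
  seg <- tibble(x = nodes$x[lookup[as.character(edges$column_i)]],
                y = nodes$y[lookup[as.character(edges$column_i)]],
                xend = nodes$x[lookup[as.character(edges$column_j)]],
                yend = nodes$y[lookup[as.character(edges$column_j)]],
                score = edges$score)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       alpha = .data$score),
                          color = "grey40") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree),
                        color = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$position), size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Co-evolution network",
                  size = "partners", alpha = "score")
}

#' Sequence-logo style plot of one subgroup's fingerprint
#'
#' Letter heights are residue frequency times position information content
#' (bits), drawn as stacked text.
#'
#' @param fps A `fingerprint_set` from [extract_motifs()].
#' @param subgroup Subgroup id to plot.
#' @return A ggplot.
#' @export
plot_motif_logo <- function(fps, subgroup) {
  m <- logo_matrix(fps, subgroup)
  df <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    h <- m[i, m[i, ] > 0]
    if (length(h) == 0) return(NULL)
    h <- sort(h)
    tibble(position = factor(rownames(m)[i], levels = rownames(m)),
           residue = names(h), height = unname(h),
           y = cumsum(h) - h / 2)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y,
                                   label = .data$residue,
                                   size = .data$height,
                                   color = .data$residue)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(2, 10)) +
    ggplot2::ylim(0, log2(20)) +
    ggplot2::labs(x = "position", y = "bits",
                  title = paste("Fingerprint, subgroup", subgroup)) +
    ggplot2::theme_minimal()
}
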