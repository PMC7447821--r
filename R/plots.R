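#' Plot refined subclone frequency vectors
#'
#' One line per detected subclone across biopsies, with the per-mutation
#' first-approximation frequencies underlaid as translucent points. Crossing
#' lines indicate subclones on distinct branches; nested lines are
#' candidates for ancestry.
#'
#' @param object A `subclone_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.subclone_fit <- function(object, ...) {
  pts <- object$phi_tilde %>%
    inner_join(tidy(object) %>% filter(!is.na(.data$cluster)),
               by = "mutation_id") %>%
    mutate(cluster = factor(.data$cluster))
  lines <- object$frequencies %>% mutate(cluster = factor(.data$cluster))
  ggplot2::ggplot(lines,
                  ggplot2::aes(x = .data$biopsy_id, y = .data$phi,
                               colour = .data$cluster,
                               group = .data$cluster)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$phi_tilde), alpha = 0.2,
                        size = 0.8,
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "biopsy", y = "subclone frequency φ",
                  colour = "subclone") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a clone tree
#'
#' Simple layered layout: depth from the germline root on the vertical axis,
#' siblings spread horizontally.
#'
#' @param object A `clone_tree`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.clone_tree <- function(object, ...) {
  edges <- object$edges
  depth <- c(germline = 0)
  todo <- edges
  while (nrow(todo)) {
    ready <- todo$parent %in% names(depth)
    depth[todo$child[ready]] <- depth[todo$parent[ready]] + 1
    todo <- todo[!ready, , drop = FALSE]
  }
  nodes <- tibble(id = names(depth), depth = unname(depth)) %>%
    group_by(.data$depth) %>%
    mutate(x = row_number() - (n() + 1) / 2) %>%
    ungroup()
  seg <- edges %>%
    left_join(nodes, by = c("parent" = "id")) %>%
    dplyr::rename(x0 = "x", y0 = "depth") %>%
    left_join(nodes, by = c("child" = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = -.data$y0,
                                       xend = .data$x, yend = -.data$depth),
                          colour = "grey50") +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = -.data$depth,
                                     label = .data$id)) +
    ggplot2::theme_void()
}

#' Plot subclone-count convergence across region subsets
#'
#' @param object Output of [region_convergence()].
#' @param ... Unused.
#' @return A ggplot (boxplots of detected subclone counts per subset size).
#' @export
plot_region_convergence <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$k), y = .data$n_clusters)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "number of regions", y = "detected subclones") +
    ggplot2::theme_minimal()
}
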