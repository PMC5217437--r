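#' Plot a windowed SNP profile
#'
#' The classic per-pair divergence track: SNPs per window along the
#' reference, with uncovered windows left blank.
#'
#' @param profile tibble from [snp_windows()].
#' @return a ggplot.
#' @export
plot_snp_profile <- function(profile) {
  ggplot2::ggplot(profile[profile$covered %in% TRUE, ],
                  ggplot2::aes(x = (window_start + window_end) / 2,
                               y = n_snps)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "reference position (bp)", y = "SNPs per window") +
    ggplot2::theme_minimal()
}

#' Plot a fragment recruitment profile
#'
#' Position-versus-identity scatter of recruited reads.
#'
#' @param x a `recruitment_profile` from [recruit()].
#' @return a ggplot.
#' @export
plot_recruitment <- function(x) {
  stopifnot(inherits(x, "recruitment_profile"))
  ggplot2::ggplot(x$hits, ggplot2::aes(x = position, y = 100 * identity)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6, colour = "steelblue") +
    ggplot2::labs(x = sprintf("%s position (bp)", x$replicon),
                  y = "read identity (%)",
                  title = sprintf("RPKG %.2f (%d reads)", x$rpkg,
                                  x$n_recruited)) +
    ggplot2::theme_minimal()
}

#' Plot a protein-sharing network
#'
#' @param net a `sharing_network` from [build_sharing_network()].
#' @param seed layout seed (Fruchterman-Reingold).
#' @return a ggplot.
#' @export
plot_network <- function(net, seed = 1L) {
  stopifnot(inherits(net, "sharing_network"))
  set.seed(seed)
  lay <- igraph::layout_with_fr(net$graph)
  nodes <- tibble(element = igraph::V(net$graph)$name,
                  x = lay[, 1], y = lay[, 2])
  edges <- net$edges |>
    left_join(nodes, by = c("a" = "element")) |>
    rename(x0 = x, y0 = y) |>
    left_join(nodes, by = c("b" = "element")) |>
    rename(x1 = x, y1 = y)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = x0, y = y0, xend = x1, yend = y1,
                                       linewidth = weight),
                          colour = "grey60", alpha = 0.7) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = x, y = y), size = 4,
                        colour = "firebrick") +
    ggplot2::geom_text(data = nodes, ggplot2::aes(x = x, y = y,
                                                  label = element),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::theme_void()
}

#' Plot windowed GC and GC skew
#'
#' @param comp a `composition` from [composition()].
#' @return a ggplot.
#' @export
plot_composition <- function(comp) {
  stopifnot(inherits(comp, "composition"))
  w <- comp$windows |>
    tidyr::pivot_longer(c(gc, gc_skew), names_to = "metric")
  ggplot2::ggplot(w, ggplot2::aes(x = (start + end) / 2, y = value)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL, title = comp$id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_recruitment
#' @param object a `recruitment_profile`.
#' @param ... unused.
#' @method autoplot recruitment_profile
#' @export
autoplot.recruitment_profile <- function(object, ...) plot_recruitment(object)

#' @rdname plot_network
#' @param object a `sharing_network`.
#' @param ... unused.
#' @method autoplot sharing_network
#' @export
autoplot.sharing_network <- function(object, ...) plot_network(object)

#' @rdname plot_composition
#' @param object a `composition`.
#' @param ... unused.
#' @method autoplot composition
#' @export
autoplot.composition <- function(object, ...) plot_composition(object)
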