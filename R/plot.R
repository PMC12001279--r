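#' Plot a fold network
#'
#' Cycle-member edges are drawn in one colour and incomplete (dead-end)
#' edges in another, over the node set.
#'
#' @param object A [fold_network()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fold_network <- function(object, ...) {
  net <- object
  if (is.null(net$cycles)) net <- classify_network_edges(net)
  cyc_edges <- unique(unlist(net$cycles))
  segs <- lapply(seq_along(net$edges), function(i) {
    p <- net$edges[[i]]$path
    data.frame(x = p[-nrow(p), 1], y = p[-nrow(p), 2],
               xend = p[-1, 1], yend = p[-1, 2],
               class = if (i %in% cyc_edges) "cycle" else "incomplete")
  })
  segs <- do.call(rbind, segs)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = x, y = y,
                                       xend = xend, yend = yend,
                                       colour = class)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = NULL, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot solver convergence (residual and elastic energy over time)
#'
#' @param object A `sim_state`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_state <- function(object, ...) {
  lg <- object$log
  df <- rbind(data.frame(time = lg$time, value = lg$residual,
                         what = "max residual force"),
              data.frame(time = lg$time, value = lg$energy,
                         what = "elastic energy"))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "simulation time", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an optimization history (best-so-far objective)
#'
#' @param object An `opt_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.opt_result <- function(object, ...) {
  h <- object$history
  df <- data.frame(iteration = h$iteration, objective = h$objective,
                   best = cummin(h$objective))
  ggplot2::ggplot(df, ggplot2::aes(x = iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = objective), alpha = 0.4) +
    ggplot2::geom_step(ggplot2::aes(y = best)) +
    ggplot2::labs(x = "evaluation", y = "objective (best-so-far line)") +
    ggplot2::theme_minimal()
}
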