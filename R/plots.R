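#' Plot simulated trajectories
#'
#' Biomass, spawning biomass, mean fishing mortality and catch per
#' population over the simulated years.
#'
#' @param sim Output of [run_simulation()].
#' @return A ggplot.
#' @export
plot_simulation <- function(sim) {
  long <- tidyr::pivot_longer(sim, c("B_t", "SSB_t", "F", "Y_t"),
                              names_to = "output", values_to = "value")
  ggplot(long, aes(x = .data$year, y = .data$value, colour = .data$population)) +
    geom_line() +
    facet_wrap(~output, scales = "free_y") +
    labs(x = "simulated year", y = NULL,
         title = "Simulated trajectories per population") +
    theme_minimal()
}

#' Sensitivity heatmap
#'
#' Axes as rows, outputs as columns, first-order index as fill -- to be read
#' column-wise: dark cells mark the parameters driving that output.
#'
#' @param object An `ri_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_sensitivity <- function(object, ...) {
  ord <- object |>
    group_by(.data$axis) |>
    summarise(m = max(.data$S1)) |>
    arrange(.data$m)
  object$axis <- factor(object$axis, levels = ord$axis)
  ggplot(object, aes(x = .data$output, y = .data$axis, fill = .data$S1)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "black", limits = c(0, 1)) +
    labs(x = "output variable", y = "input axis",
         fill = expression(S[1])) +
    theme_minimal()
}

#' Tree diagram
#'
#' @param object An `ri_tree`.
#' @param ... Unused.
#' @return A ggplot of the node-link structure; robust leaves (when
#'   labelled) are filled black, others grey.
#' @export
autoplot.ri_tree <- function(object, ...) {
  nd <- object$nodes
  # leaf x-positions by left-to-right order, internal nodes centered
  xpos <- setNames(rep(NA_real_, nrow(nd)), nd$id)
  counter <- 0
  assign_x <- function(id) {
    row <- nd[nd$id == id, ]
    if (row$is_leaf) {
      counter <<- counter + 1
      xpos[[as.character(id)]] <<- counter
    } else {
      assign_x(row$left); assign_x(row$right)
      xpos[[as.character(id)]] <<-
        (xpos[[as.character(row$left)]] + xpos[[as.character(row$right)]]) / 2
    }
  }
  assign_x(nd$id[is.na(nd$parent)])
  nd$x <- unname(xpos[as.character(nd$id)])
  nd$y <- -nd$depth
  edges <- nd[!is.na(nd$parent), ]
  par <- nd[match(edges$parent, nd$id), ]
  edges$xend <- par$x; edges$yend <- par$y
  nd$label <- ifelse(nd$is_leaf, sprintf("n=%d\n%.0f%%", nd$n, 100 * nd$prop),
                     sprintf("%s\n<= %.3g", nd$axis, nd$split))
  nd$robust_fill <- if (!is.null(nd$robust)) ifelse(nd$is_leaf & nd$robust, "robust",
                                                    ifelse(nd$is_leaf, "leaf", "split"))
                    else ifelse(nd$is_leaf, "leaf", "split")
  ggplot() +
    geom_segment(data = edges, aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend),
                 colour = "grey60") +
    geom_label(data = nd, aes(x = .data$x, y = .data$y, label = .data$label,
                              fill = .data$robust_fill), size = 3) +
    scale_fill_manual(values = c(robust = "grey20", leaf = "grey85",
                                 split = "white"), guide = "none") +
    theme_void()
}

#' Tolerated-uncertainty margins of robust regions
#'
#' One horizontal interval per (region, natural axis) in normalized units,
#' with the reference parameterisation at 0.5.
#'
#' @param object An `ri_regions`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_regions <- function(object, ...) {
  cons <- object$constraints
  cons <- cons[cons$set == "U", ]
  if (!nrow(cons)) abort("no natural-axis constraints to plot")
  cons$region <- factor(cons$region_id)
  ggplot(cons, aes(y = .data$axis, colour = .data$region)) +
    geom_segment(aes(x = .data$lower, xend = .data$upper,
                     yend = .data$axis),
                 position = position_dodge(width = 0.5), linewidth = 2) +
    geom_vline(xintercept = 0.5, linetype = 2) +
    coord_cartesian(xlim = c(0, 1)) +
    labs(x = "normalized axis value (reference = 0.5)", y = NULL,
         colour = "region") +
    theme_minimal()
}
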