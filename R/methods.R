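# Tidy accessors and plots for simulation results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' `tidy()` returns the per-time counts in long form (one row per time point
#' and phenotype); `glance()` returns a one-row summary of the whole run.
#'
#' @param x An `oncosim_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy oncosim_sim
#' @export
tidy.oncosim_sim <- function(x, ...) {
  tidyr::pivot_longer(
    x$counts,
    cols = c("n_epithelial", "n_tumor", "n_tcell"),
    names_to = "phenotype", names_prefix = "n_",
    values_to = "n"
  )
}

#' @rdname tidy.oncosim_sim
#' @method glance oncosim_sim
#' @export
glance.oncosim_sim <- function(x, ...) {
  fin <- x$counts[nrow(x$counts), ]
  ct <- x$state$counters
  tibble::tibble(
    t_final = fin$t,
    n_epithelial = fin$n_epithelial,
    n_tumor = fin$n_tumor,
    n_tcell = fin$n_tcell,
    tumor_fraction = fin$tumor_fraction,
    tumor_extinct = fin$n_tumor == 0L && length(x$state$traces) > 0L,
    divisions = ct$divisions,
    mutations = ct$mutations,
    deaths = ct$deaths,
    tcell_entries = ct$tcell_entries,
    engulfments = ct$engulfments,
    cum_intravasated = ct$intravasations,
    seedings = ct$seedings,
    seed = x$seed
  )
}

#' Tidy the cell table of a state
#'
#' @param x An `oncosim_state`.
#' @param ... Unused.
#' @return The cell tibble with a `t` column prepended.
#' @method tidy oncosim_state
#' @export
tidy.oncosim_state <- function(x, ...) {
  t_now <- x$t  # the cell table has a column named x; avoid data masking
  dplyr::mutate(x$cells, t = t_now, .before = 1)
}

#' Plot count trajectories of a run
#'
#' Lines of epithelial, tumor and T-cell counts against time.
#'
#' @param object An `oncosim_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oncosim_sim
#' @export
autoplot.oncosim_sim <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$n,
                                   colour = .data$phenotype)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(
      values = c(epithelial = "#2e7d32", tumor = "#c62828", tcell = "#1565c0")
    ) +
    ggplot2::labs(x = "time (s)", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the spatial cell arrangement of a state
#'
#' Cells are drawn at their positions with point area proportional to their
#' cross-section; the domain boundary and vessel points are overlaid. In 3D
#' the x-y projection is shown.
#'
#' @param object An `oncosim_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oncosim_state
#' @export
autoplot.oncosim_state <- function(object, ...) {
  cells <- object$cells
  Rd <- object$config$domain$radius
  th <- seq(0, 2 * pi, length.out = 181)
  ring <- tibble::tibble(x = Rd * cos(th), y = Rd * sin(th))
  vp <- tibble::as_tibble(object$vessels[, 1:2, drop = FALSE],
                          .name_repair = ~ c("x", "y"))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = ring, colour = "grey40") +
    ggplot2::geom_point(data = vp, shape = 21, size = 5, stroke = 1,
                        colour = "black", fill = "white") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phenotype,
                                     size = .data$R^2), alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(epithelial = "#2e7d32", tumor = "#c62828", tcell = "#1565c0")
    ) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = NULL) +
    ggplot2::theme_minimal()
}
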