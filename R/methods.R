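# Tidy accessors and plots for run objects and worlds.

#' @export
print.mtswarm_run <- function(x, ...) {
  cat(sprintf("<mtswarm_run> preset %s: %d trial(s), %d iterations each\n",
              x$config$preset, length(x$trials), x$config$iterations))
  for (tr in x$trials) {
    fin <- tr$counts[nrow(tr$counts), ]
    cat(sprintf(
      "  trial %d (seed %d): %g active / %g inactive dimers, %g chains, max length %g, %g ring(s)\n",
      tr$trial, tr$seed, fin$active_dimers, fin$inactive_dimers,
      fin$chain_count, fin$max_chain_length, fin$closed_ring_count))
  }
  invisible(x)
}

#' Tidy a run into its per-iteration counts
#'
#' @param x an `mtswarm_run`.
#' @param ... unused.
#' @return a tibble of the per-iteration analytics rows of every trial, with
#'   a `trial` column.
#' @export
tidy.mtswarm_run <- function(x, ...) {
  purrr::map_dfr(x$trials, function(tr) {
    dplyr::mutate(tr$counts, trial = tr$trial, .before = 1)
  })
}

#' One-row-per-trial summary of a run
#'
#' @param x an `mtswarm_run`.
#' @param ... unused.
#' @return a tibble with final counts and chain statistics per trial.
#' @export
glance.mtswarm_run <- function(x, ...) {
  purrr::map_dfr(x$trials, function(tr) {
    fin <- tr$counts[nrow(tr$counts), ]
    stats <- chain_statistics(tr$world)
    tibble::tibble(
      trial = tr$trial, seed = tr$seed,
      iterations = x$config$iterations,
      final_active = fin$active_dimers,
      final_inactive = fin$inactive_dimers,
      final_free_gtp = fin$free_gtp,
      final_free_gdp = fin$free_gdp,
      chain_count = stats$chain_count,
      max_chain_length = stats$max_length,
      closed_rings = fin$closed_ring_count,
      wall_time_s = tr$manifest$wall_time_s)
  })
}

#' Plot the population counts of a run
#'
#' Population counts (dimers, free nucleotides, chain statistics) against
#' iteration, one facet per quantity and one line per trial.
#'
#' @param object an `mtswarm_run`.
#' @param quantities counts columns to plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mtswarm_run <- function(object,
                                 quantities = c("inactive_dimers",
                                                "active_dimers", "free_gtp",
                                                "free_gdp",
                                                "max_chain_length",
                                                "chain_count"),
                                 ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(quantities), names_to = "quantity",
                        values_to = "count") |>
    dplyr::mutate(quantity = factor(.data$quantity, levels = quantities))
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$count,
                                   group = .data$trial,
                                   colour = factor(.data$trial))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "count", colour = "trial") +
    ggplot2::theme_minimal()
}

#' Plot the agents of a world
#'
#' A snapshot of the tray: tubulins coloured by assembly state, nucleotides
#' by nucleotide state, points scaled roughly to agent radii.
#'
#' @param object an `mt_world`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mt_world <- function(object, ...) {
  df <- world_coordinates(object) |>
    dplyr::filter(.data$state != "bound")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$state,
                                   size = .data$type == "nucleotide")) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 0.8),
                               guide = "none") +
    ggplot2::coord_fixed(xlim = c(0, object$space[1]),
                         ylim = c(0, object$space[2]), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
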