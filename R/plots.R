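# Tidiers and plots: broom-style tidy()/glance() and ggplot2 autoplot()
# methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CRN into its reaction table
#'
#' @param x A `dsd_crn`.
#' @param ... Unused.
#' @return Tibble with one row per reaction (labelled reactants/products,
#'   kind, rate).
#' @export
tidy.dsd_crn <- function(x, ...) crn_reactions(x)

#' One-row summary of a CRN
#'
#' @param x A `dsd_crn`.
#' @param ... Unused.
#' @return Tibble with species/reaction counts by kind.
#' @export
glance.dsd_crn <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$species),
    n_reactions = nrow(x$reactions),
    n_bind = sum(x$reactions$kind == "bind"),
    n_unbind = sum(x$reactions$kind == "unbind"),
    n_migrate = sum(x$reactions$kind == "migrate"),
    origami_mode = length(x$tethered_strands) > 0L
  )
}

#' Tidy a time course to long format
#'
#' @param x A `dsd_timecourse`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `species`, `conc_nM`.
#' @export
tidy.dsd_timecourse <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"time_s", names_to = "species", values_to = "conc_nM")
}

#' One-row summary of a time course
#'
#' @param x A `dsd_timecourse`.
#' @param ... Unused.
#' @return Tibble with solver, grid size, duration and conservation residual.
#' @export
glance.dsd_timecourse <- function(x, ...) {
  st <- strand_totals(x)
  tot <- as.matrix(st[, -1L, drop = FALSE])
  resid <- max(abs(sweep(tot, 2L, tot[1L, ], "-")) /
                 pmax(matrix(tot[1L, ], nrow(tot), ncol(tot), byrow = TRUE),
                      .Machine$double.eps))
  tibble::tibble(
    solver = attr(x, "solver"), n_species = ncol(x) - 1L, n_points = nrow(x),
    duration_h = max(x$time_s) / 3600, conservation_residual = resid
  )
}

#' Plot species trajectories of a time course
#'
#' @param object A `dsd_timecourse`.
#' @param species Character vector of species labels (default: the six
#'   highest-concentration species).
#' @param log_time Logarithmic time axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsd_timecourse <- function(object, species = NULL, log_time = TRUE,
                                    ...) {
  long <- tidy.dsd_timecourse(object) |>
    dplyr::filter(!startsWith(.data$species, "f_"))
  if (is.null(species)) {
    top <- long |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(m = max(.data$conc_nM), .groups = "drop") |>
      dplyr::slice_max(.data$m, n = 6L)
    species <- top$species
  }
  gg <- long |>
    dplyr::filter(.data$species %in% !!species) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_s / 3600, y = .data$conc_nM,
                                 colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_time) gg <- gg + ggplot2::scale_x_log10()
  gg
}

#' Plot normalized fluorescence channels
#'
#' @param tc A `dsd_timecourse` with fluorescence columns (see
#'   [add_fluorescence()]).
#' @param log_time Logarithmic time axis.
#' @return A ggplot of the Cy3/Cy5 proxies vs time.
#' @export
plot_fluorescence <- function(tc, log_time = FALSE) {
  cols <- intersect(c("f_cy3", "f_cy5"), names(tc))
  if (length(cols) == 0L) {
    stop("no fluorescence columns; run add_fluorescence() first", call. = FALSE)
  }
  long <- tibble::as_tibble(tc)[, c("time_s", cols)] |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "f") |>
    dplyr::mutate(channel = ifelse(.data$channel == "f_cy3", "Cy3", "Cy5"))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 3600,
                                           y = .data$f,
                                           colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(Cy3 = "#2e7d32", Cy5 = "#c62828")) +
    ggplot2::labs(x = "time (h)", y = "normalized fluorescence", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_time) gg <- gg + ggplot2::scale_x_log10()
  gg
}

#' Tidy an assembly result
#'
#' @param x A `dsd_fibrils` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.dsd_fibrils <- function(x, ...) tibble::as_tibble(x)

#' One-row-per-condition summary of an assembly result
#'
#' @param x A `dsd_fibrils` tibble.
#' @param ... Unused.
#' @return The [xn_summary()] tibble.
#' @export
glance.dsd_fibrils <- function(x, ...) xn_summary(x)

#' Plot fibril length distributions at the TEM checkpoints
#'
#' Histograms normalized to most-abundant = 100, faceted by species and
#' checkpoint time.
#'
#' @param object A `dsd_fibrils` tibble.
#' @param times_h Checkpoints to show (default 0.5, 2, 18 h).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsd_fibrils <- function(object, times_h = c(0.5, 2, 18), ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$time_h %in% times_h) |>
    dplyr::group_by(.data$species, .data$time_h, .data$length) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(count = .data$count / max(.data$count) * 100) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$count,
                                   fill = .data$species)) +
    ggplot2::geom_col(position = "identity", alpha = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$species),
      cols = ggplot2::vars(.data$time_h),
      labeller = ggplot2::labeller(time_h = function(v) paste0(v, " h"))
    ) +
    ggplot2::scale_fill_manual(values = c(cylinder = "#c62828",
                                          cuboid = "#2e7d32")) +
    ggplot2::labs(x = "fibril length (monomers)",
                  y = "normalized count (most abundant = 100)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot an arming trace
#'
#' @param arming Tibble from [arming_trace()].
#' @return A ggplot of `a(t)` and the disarm hazard.
#' @export
plot_arming <- function(arming) {
  ggplot2::ggplot(arming, ggplot2::aes(x = .data$time_s / 3600)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$a, colour = "armed fraction")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$d / max(.data$d, 1e-12),
                                    colour = "disarm hazard (scaled)")) +
    ggplot2::labs(x = "time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
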