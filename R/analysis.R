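# Distribution statistics for fibril length counts (simulated or
# hand-entered TEM count tables in the same (time_h, species, length, count)
# schema).

check_distribution <- function(d) {
  if (!is.data.frame(d) || !all(c("length", "count") %in% names(d))) {
    stop("a length distribution needs `length` and `count` columns", call. = FALSE)
  }
  if (nrow(d) == 0L || sum(d$count) <= 0) {
    stop("empty length distribution: statistics undefined", call. = FALSE)
  }
  if (any(d$length < 1L) || any(d$count < 0)) {
    stop("lengths must be >= 1 and counts >= 0", call. = FALSE)
  }
  invisible(d)
}

#' Number-average degree of polymerization
#'
#' `Xn = sum(length * count) / sum(count)`, counting monomers as length 1.
#'
#' @param d Tibble with `length` and `count` columns.
#' @return Numeric scalar, >= 1.
#' @export
number_average_length <- function(d) {
  check_distribution(d)
  sum(d$length * d$count) / sum(d$count)
}

#' Normalize a length histogram to most-abundant = 100
#'
#' Scales counts so the most abundant species is exactly 100, matching the
#' normalization used for TEM count tables. Idempotent.
#'
#' @param d Tibble with `length` and `count` columns.
#' @return The tibble with rescaled `count`.
#' @export
normalize_histogram <- function(d) {
  check_distribution(d)
  if (max(d$count) <= 0) stop("all counts are zero", call. = FALSE)
  d$count <- d$count / max(d$count) * 100
  d
}

#' Largest observed fibril length
#'
#' @param d Tibble with `length` and `count` columns.
#' @return Integer: largest length with positive count.
#' @export
max_length <- function(d) {
  check_distribution(d)
  max(d$length[d$count > 0])
}

#' Per-checkpoint Xn summary of an assembly simulation
#'
#' Computes the number-average degree of polymerization per species, time and
#' seed, then seed-level mean and standard deviation (the statistic used for
#' comparisons against TEM count tables, which carry comparable sampling
#' noise; comparisons use the seed mean).
#'
#' @param fib A `dsd_fibrils` tibble (or any tibble with `seed`, `species`,
#'   `time_h`, `length`, `count`).
#' @return Tibble with `species`, `time_h`, `xn_mean`, `xn_sd`, `n_seeds`,
#'   `max_length`.
#' @export
xn_summary <- function(fib) {
  per_seed <- fib |>
    dplyr::group_by(.data$species, .data$time_h, .data$seed) |>
    dplyr::summarise(
      xn = sum(.data$length * .data$count) / sum(.data$count),
      lmax = max(.data$length[.data$count > 0]),
      .groups = "drop"
    )
  per_seed |>
    dplyr::group_by(.data$species, .data$time_h) |>
    dplyr::summarise(
      xn_mean = mean(.data$xn),
      xn_sd = stats::sd(.data$xn),
      n_seeds = dplyr::n(),
      max_length = max(.data$lmax),
      .groups = "drop"
    )
}
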