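# Fluorescence proxies: map species trajectories to normalized Cy3/Cy5
# signals comparable to plate-reader traces.
#
# Quenching is declared per complex, not computed from geometry: a
# fluorophore is dark when a quencher-bearing strand is bound in the same
# complex. The one structural exception is the activator on the cuboid
# connector: bound via its 6*/7* end, its quencher-modified 2* end dangles
# away from the Cy3, so activator-bound c2 species stay bright (this is what
# makes the Cy3 channel report cuboid activation at all). Two context factors
# model the partial quenching Cy3 suffers inside three-strand complexes.

#' Brightness map of a CRN
#'
#' One brightness factor per fluorophore-bearing species and channel.
#' Default rule: 0 if a quencher-bearing strand is in the complex, else 1.
#' Overrides, in order:
#' \itemize{
#'   \item Cy3 species containing the activator but no inhibitor are bright
#'     (the activator's quencher end dangles off the c2-bound complex);
#'     in origami mode the full c2/c2*/activator bridge triplex gets
#'     `b_cy3_activator_triplex`.
#'   \item Cy3 in the c2/c2*/fuelA bridge triplex gets `b_cy3_fuelA_triplex`
#'     (DNA-context quenching of the dye inside the three-strand complex).
#' }
#'
#' @param crn A `dsd_crn`.
#' @param origami_mode Apply the origami-context factor for the activator
#'   bridge triplex.
#' @param b_cy3_fuelA_triplex,b_cy3_activator_triplex Context factors in
#'   `[0, 1]` (packaged defaults 0.8).
#' @return Tibble with `label`, `channel`, `b`.
#' @export
brightness_map <- function(crn, origami_mode = FALSE,
                           b_cy3_fuelA_triplex = 0.8,
                           b_cy3_activator_triplex = 0.8) {
  stopifnot(b_cy3_fuelA_triplex >= 0, b_cy3_fuelA_triplex <= 1,
            b_cy3_activator_triplex >= 0, b_cy3_activator_triplex <= 1)
  meta <- species_meta(crn)
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    st <- meta$strands[[i]]
    for (ch in c("Cy3", "Cy5")) {
      if (ch == "Cy3" && !meta$has_cy3[i]) next
      if (ch == "Cy5" && !meta$has_cy5[i]) next
      b <- if (meta$has_quencher[i]) 0 else 1
      if (ch == "Cy3" && "activator" %in% st && !"inhibitor" %in% st) {
        b <- if (origami_mode && "c2s" %in% st) b_cy3_activator_triplex else 1
      }
      if (ch == "Cy3" && "fuelA" %in% st && "c2s" %in% st) {
        b <- b_cy3_fuelA_triplex
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = meta$label[i], channel = ch, b = b
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Normalized fluorescence trace of a channel
#'
#' `F(t) = sum_s b(s) [s](t) / C_total`, where the sum runs over the
#' channel's fluorophore-bearing species and `C_total` is the channel's total
#' fluorophore concentration (the reference state, all fluorophores unquenched,
#' gives F = 1).
#'
#' @param tc A `dsd_timecourse`.
#' @param channel `"Cy3"` or `"Cy5"`.
#' @param bm Brightness map tibble from [brightness_map()]; `NULL` for the
#'   default rule.
#' @param crn The CRN (needed when `bm` is `NULL`).
#' @param origami_mode Passed to [brightness_map()] when `bm` is `NULL`.
#' @return Tibble with `time_s`, `channel`, `f`.
#' @export
fluorescence_trace <- function(tc, channel = c("Cy3", "Cy5"), bm = NULL,
                               crn = NULL, origami_mode = FALSE) {
  channel <- match.arg(channel)
  meta <- attr(tc, "meta")
  has <- if (channel == "Cy3") meta$has_cy3 else meta$has_cy5
  if (!any(has)) {
    stop("channel ", channel, " absent from this circuit", call. = FALSE)
  }
  if (is.null(bm)) {
    if (is.null(crn)) stop("provide a brightness map or the CRN", call. = FALSE)
    bm <- brightness_map(crn, origami_mode = origami_mode)
  }
  bmc <- dplyr::filter(bm, .data$channel == !!channel)
  bvec <- stats::setNames(bmc$b, bmc$label)
  labels <- meta$label[has]
  miss <- setdiff(labels, names(bvec))
  if (length(miss) > 0L) {
    # default rule for species without an explicit entry
    q <- meta$has_quencher[match(miss, meta$label)]
    bvec <- c(bvec, stats::setNames(as.numeric(!q), miss))
  }
  conc <- as.matrix(tc[, labels, drop = FALSE])
  # fluorophore copies per complex (a complex could carry several)
  lib <- dsd_strands()
  carries <- names(lib)[vapply(lib, function(s) channel %in% s$labels, logical(1))]
  ncopies <- vapply(meta$strands[has], function(st) sum(st %in% carries), numeric(1))
  # total fluorophore concentration is conserved; take it from t = 0
  total <- sum(conc[1L, ] * ncopies)
  f <- as.vector(conc %*% (bvec[labels] * ncopies)) / total
  tibble::tibble(time_s = tc$time_s, channel = channel, f = f)
}

#' Append normalized fluorescence columns to a time course
#'
#' Adds `f_cy3` and/or `f_cy5` columns (whichever fluorophores the circuit
#' carries).
#'
#' @param tc A `dsd_timecourse`.
#' @param crn The CRN the time course came from.
#' @param origami_mode Apply origami-context brightness factors.
#' @param ... Passed to [brightness_map()].
#' @return The time course with fluorescence columns.
#' @export
add_fluorescence <- function(tc, crn, origami_mode = FALSE, ...) {
  meta <- attr(tc, "meta")
  bm <- brightness_map(crn, origami_mode = origami_mode, ...)
  if (any(meta$has_cy3)) {
    tc$f_cy3 <- fluorescence_trace(tc, "Cy3", bm)$f
  }
  if (any(meta$has_cy5)) {
    tc$f_cy5 <- fluorescence_trace(tc, "Cy5", bm)$f
  }
  tc
}

as_trace <- function(trace) {
  if (is.data.frame(trace)) {
    vcol <- intersect(c("f", "value", "conc"), names(trace))
    if (length(vcol) == 0L) vcol <- setdiff(names(trace), c("time_s", "channel"))[1L]
    list(t = trace$time_s, v = trace[[vcol[1L]]])
  } else {
    stop("trace must be a data frame with a time_s column", call. = FALSE)
  }
}

#' Time of the trace maximum
#'
#' First grid time attaining the maximum (ties broken towards earlier times).
#'
#' @param trace Tibble with `time_s` and a value column (`f`, `value`, ...).
#' @return Time in seconds.
#' @export
peak_time <- function(trace) {
  tr <- as_trace(trace)
  if (length(tr$t) == 0L) stop("empty trace", call. = FALSE)
  tr$t[which.max(tr$v)]
}

#' Completion time of a trace
#'
#' First time from which the trace stays within `level * F_final` of its
#' final value.
#'
#' @param trace Tibble with `time_s` and a value column.
#' @param level Relative band around the final value, in (0, 1).
#' @return Time in seconds.
#' @export
completion_time <- function(trace, level = 0.10) {
  stopifnot(level > 0, level < 1)
  tr <- as_trace(trace)
  if (length(tr$t) == 0L) stop("empty trace", call. = FALSE)
  ffin <- tr$v[length(tr$v)]
  out <- abs(tr$v - ffin) > level * abs(ffin)
  if (!any(out)) return(tr$t[1L])
  tr$t[min(max(which(out)) + 1L, length(tr$t))]
}
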