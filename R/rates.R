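# Toehold-limited rate model.
#
# The rate-determining step of a displacement reaction is binding to the
# toehold. Binding rates follow a length-based saturating model with a log10
# discount per missing effective base and a fixed standard unbinding rate;
# hairpin-loop presentation and origami tethering enter as multiplicative
# context factors.

#' Rate model parameters
#'
#' Defaults are the packaged calibrated set (see the calibration functions and
#' the methods vignette for how they were fixed against the printed kinetic
#' milestones of the free-strand and origami circuits).
#'
#' @param u0 Toehold unbinding rate, s^-1. Standard value 0.012.
#' @param k_max Saturated toehold binding rate, nM^-1 s^-1.
#' @param n_sat Toehold length (nb) at which binding saturates.
#' @param sigma log10 rate discount per missing effective base.
#' @param k_migrate Branch-migration/displacement completion rate, s^-1.
#' @param h Hairpin protection factor in (0, 1] applied to binds initiated at
#'   a loop-presented toehold.
#' @param rho Origami architectural slowdown factor in (0, 1], multiplying a
#'   bimolecular rate once per origami-tethered reactant complex.
#' @param leak0 Rate assigned to zero-effective-length (leak) channels,
#'   nM^-1 s^-1. Default 0: the enumerated network is leak-free.
#' @param u_bridge_solo Fraying rate, s^-1, of an isolated bridging duplex
#'   (a two-strand complex held by a single long bond, e.g. activator/c2*
#'   after fuel B has broken a fibril bridge). Default equals `u0`.
#' @return An object of class `dsd_rate_params`.
#' @export
rate_params <- function(u0 = 0.012,
                        k_max = 1e-3,
                        n_sat = 6L,
                        sigma = 0.5,
                        k_migrate = 0.1,
                        h = 0.08,
                        rho = 0.35,
                        leak0 = 0,
                        u_bridge_solo = u0) {
  p <- list(u0 = u0, k_max = k_max, n_sat = as.integer(n_sat), sigma = sigma,
            k_migrate = k_migrate, h = h, rho = rho, leak0 = leak0,
            u_bridge_solo = u_bridge_solo)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || is.na(v) || v < 0,
                 logical(1)))) {
    stop("all rate parameters must be single non-negative numbers", call. = FALSE)
  }
  if (p$h <= 0 || p$h > 1) stop("h must lie in (0, 1]", call. = FALSE)
  if (p$rho <= 0 || p$rho > 1) stop("rho must lie in (0, 1]", call. = FALSE)
  structure(p, class = "dsd_rate_params")
}

#' @export
print.dsd_rate_params <- function(x, ...) {
  cat("<rate params>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Effective toehold length
#'
#' Length in nucleobases minus the mismatch count, floored at zero. The
#' mismatched connector toehold 6' (8 nb, 4 mismatches) has effective length
#' 4, which is what slows the inhibitor displacement relative to the fully
#' complementary threshold toehold 6.
#'
#' @param d A [domain()].
#' @return Integer effective length in nb.
#' @export
effective_toehold_length <- function(d) {
  stopifnot(inherits(d, "dsd_domain"))
  max(0L, d$length_nb - d$mismatch_nb)
}

# effective length of a *bond* between two domain instances: mismatches on
# either variant count against the pairing
effective_pair_length <- function(d1, d2) {
  max(0L, d1$length_nb - max(d1$mismatch_nb, d2$mismatch_nb))
}

#' Toehold binding rate
#'
#' `k = k_max * 10^(-sigma * max(0, n_sat - n_eff))`, multiplied by `h` when
#' the initiating toehold is presented from a hairpin loop and by `rho` once
#' per origami-tethered reactant complex. A zero effective length is a leak
#' channel and gets `leak0`.
#'
#' @param d The initiating [domain()] (toehold).
#' @param p [rate_params()].
#' @param loop Is the toehold presented from a hairpin loop?
#' @param tethered_partners Number of origami-tethered reactant complexes
#'   (0, 1 or 2).
#' @param n_eff Override for the effective toehold length; defaults to
#'   [effective_toehold_length()] of `d`.
#' @return Rate in nM^-1 s^-1.
#' @export
binding_rate <- function(d, p = rate_params(), loop = FALSE,
                         tethered_partners = 0L, n_eff = NULL) {
  if (is.null(n_eff)) n_eff <- effective_toehold_length(d)
  if (n_eff <= 0L) return(p$leak0)
  k <- p$k_max * 10^(-p$sigma * max(0, p$n_sat - n_eff))
  if (isTRUE(loop)) k <- k * p$h
  k * p$rho^tethered_partners
}

#' Toehold unbinding rate
#'
#' Returns the standard unbinding rate `u0` for toehold-length duplexes
#' (effective length at most `n_sat + 4` nb); longer duplexes are treated as
#' non-dissociating (rate 0) on the simulated horizon.
#'
#' @param d The bound [domain()].
#' @param p [rate_params()].
#' @param n_eff Override for the effective duplex length.
#' @return Rate in s^-1.
#' @export
unbinding_rate <- function(d, p = rate_params(), n_eff = NULL) {
  if (is.null(n_eff)) n_eff <- effective_toehold_length(d)
  if (n_eff > p$n_sat + 4L) return(0)
  p$u0
}
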