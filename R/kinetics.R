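# Deterministic and stochastic integration of an enumerated CRN.
#
# Concentrations are in nM, time in seconds. The output grid is geometric
# from 1 s to the duration plus t = 0, which resolves both the minutes-scale
# displacement transients and the 18 h endpoint.

timecourse_grid <- function(duration_s, n = 1000L) {
  c(0, exp(seq(log(1), log(duration_s), length.out = n)))
}

# per-species metadata needed downstream (fluorescence, arming)
species_meta <- function(crn) {
  tb <- crn$species_tbl
  strands <- lapply(crn$species, function(cx)
    vapply(cx$strands, function(s) s$name, character(1)))
  lab_of <- stats::setNames(tb$label, tb$key)
  slab <- lapply(crn$species, function(cx)
    unlist(lapply(cx$strands, function(s) s$labels)))
  tibble::tibble(
    key = names(crn$species),
    label = unname(lab_of[names(crn$species)]),
    strands = unname(strands),
    has_cy3 = vapply(slab, function(l) "Cy3" %in% l, logical(1)),
    has_cy5 = vapply(slab, function(l) "Cy5" %in% l, logical(1)),
    has_quencher = vapply(slab, function(l) "quencher" %in% l, logical(1))
  ) |> dplyr::arrange(.data$key)
}

new_timecourse <- function(times, conc, meta, solver, crn, seed = NA_integer_,
                           volume_scale = NA_real_) {
  tc <- tibble::as_tibble(as.data.frame(conc))
  names(tc) <- meta$label
  tc <- dplyr::bind_cols(tibble::tibble(time_s = times), tc)
  structure(tc, class = c("dsd_timecourse", class(tc)),
            meta = meta, solver = solver, seed = seed,
            volume_scale = volume_scale,
            params = crn$params)
}

#' @export
print.dsd_timecourse <- function(x, ...) {
  cat(sprintf("<timecourse: %d species, %d points, 0-%.2f h, solver %s>\n",
              ncol(x) - 1L, nrow(x), max(x$time_s) / 3600, attr(x, "solver")))
  NextMethod()
}

# map a named init vector (by label or key) onto the CRN species order
resolve_init <- function(crn, init) {
  meta <- species_meta(crn)
  x0 <- stats::setNames(numeric(nrow(meta)), meta$label)
  for (nm in names(init)) {
    if (nm %in% meta$label) x0[nm] <- init[[nm]]
    else if (nm %in% meta$key) x0[meta$label[match(nm, meta$key)]] <- init[[nm]]
    else stop("unknown species in init: ", nm, call. = FALSE)
  }
  x0
}

# index structure for mass-action flux evaluation
reaction_indices <- function(crn, meta) {
  rx <- crn$reactions
  key_idx <- stats::setNames(seq_len(nrow(meta)), meta$key)
  i1 <- unname(key_idx[rx$r1])
  i2 <- ifelse(is.na(rx$r2), 0L, unname(key_idx[rx$r2]))
  S <- matrix(0, nrow(meta), nrow(rx))
  for (j in seq_len(nrow(rx))) {
    S[i1[j], j] <- S[i1[j], j] - 1
    if (i2[j] > 0L) S[i2[j], j] <- S[i2[j], j] - 1
    for (pc in c("p1", "p2", "p3")) {
      pk <- rx[[pc]][j]
      if (!is.na(pk)) S[key_idx[[pk]], j] <- S[key_idx[[pk]], j] + 1
    }
  }
  list(i1 = i1, i2 = i2, S = S, rate = rx$rate)
}

#' Integrate a CRN deterministically
#'
#' Stiff-capable mass-action integration (lsoda) on a geometric-plus-zero
#' time grid. Absent species start at 0.
#'
#' @param crn A `dsd_crn`.
#' @param init Named numeric vector of initial concentrations (nM), by species
#'   label or canonical key.
#' @param duration_h Duration in hours (default 18).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-12 nM).
#' @param grid_points Number of geometric grid points (default 1000).
#' @return A `dsd_timecourse` tibble: `time_s` plus one concentration column
#'   per species label.
#' @export
simulate_ode <- function(crn, init, duration_h = 18, rtol = 1e-8, atol = 1e-12,
                         grid_points = 1000L) {
  stopifnot(inherits(crn, "dsd_crn"), duration_h > 0)
  meta <- species_meta(crn)
  x0 <- resolve_init(crn, init)
  idx <- reaction_indices(crn, meta)
  times <- timecourse_grid(duration_h * 3600, grid_points)
  deriv <- function(t, x, parms) {
    x <- pmax(x, 0)
    flux <- idx$rate * x[idx$i1] *
      ifelse(idx$i2 > 0L, x[pmax(idx$i2, 1L)], 1)
    list(as.vector(idx$S %*% flux))
  }
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    flux <- idx$rate * sol[nrow(sol), -1L][idx$i1]
    worst <- which.max(abs(flux))
    stop("ODE solver failure; worst-behaved reaction flux: reaction ", worst,
         " (", crn$reactions$kind[worst], ")", call. = FALSE)
  }
  conc <- pmax(unname(sol[, -1L, drop = FALSE]), 0)
  new_timecourse(times, conc, meta, "ode", crn)
}

#' Per-strand totals of a time course
#'
#' Sums, for every strand name, the concentration-weighted copy count over
#' all species. Under mass-action dynamics each total is a conserved quantity;
#' the residual is a solver-quality check.
#'
#' @param tc A `dsd_timecourse`.
#' @return Tibble: `time_s` plus one column per strand name.
#' @export
strand_totals <- function(tc) {
  meta <- attr(tc, "meta")
  all_strands <- sort(unique(unlist(meta$strands)))
  out <- lapply(all_strands, function(sn) {
    cnt <- vapply(meta$strands, function(v) sum(v == sn), numeric(1))
    as.matrix(tc[, meta$label, drop = FALSE]) %*% cnt
  })
  names(out) <- all_strands
  dplyr::bind_cols(tibble::tibble(time_s = tc$time_s),
                   tibble::as_tibble(lapply(out, as.vector)))
}

#' Integrate a CRN stochastically (Gillespie SSA)
#'
#' Exact direct-method simulation on copy numbers. Concentrations are
#' converted with `volume_scale` (copies per nM); bimolecular propensities are
#' scaled accordingly. The trajectory is recorded on the standard output grid
#' (state at the last event before each grid time).
#'
#' @param crn A `dsd_crn`.
#' @param init Named initial concentrations (nM).
#' @param duration_h Duration in hours.
#' @param volume_scale Copies per nM of concentration (default 625, i.e.
#'   1e5 copies for a 160 nM species).
#' @param seed Integer random seed (required for reproducibility).
#' @param grid_points Output grid size.
#' @return A `dsd_timecourse` with concentrations in nM (copies divided by
#'   `volume_scale`); attribute `volume_scale` records the conversion.
#' @export
simulate_ssa <- function(crn, init, duration_h = 18, volume_scale = 625,
                         seed = 1L, grid_points = 1000L) {
  stopifnot(inherits(crn, "dsd_crn"), duration_h > 0, volume_scale > 0)
  meta <- species_meta(crn)
  x0 <- resolve_init(crn, init)
  n0 <- round(x0 * volume_scale)
  idx <- reaction_indices(crn, meta)
  times <- timecourse_grid(duration_h * 3600, grid_points)
  # propensity constants: unimolecular rate k -> k; bimolecular k (nM^-1 s^-1)
  # -> k / volume_scale per pair; A+A uses n(n-1)/2 pairing in the core
  bimol <- idx$i2 > 0L
  c_rate <- idx$rate
  c_rate[bimol] <- c_rate[bimol] / volume_scale
  counts <- ssa_core(
    as.numeric(n0), idx$i1 - 1L, idx$i2 - 1L, c_rate, idx$S, times,
    as.integer(seed)
  )
  new_timecourse(times, counts / volume_scale, meta, "ssa", crn,
                 seed = as.integer(seed), volume_scale = volume_scale)
}
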