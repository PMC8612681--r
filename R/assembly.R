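# Coupling of the DSD connector kinetics to stochastic reversible step-growth
# assembly of colloidal monomers (operator splitting: the well-mixed strand
# trajectory drives the assembly propensities; fibril topology does not feed
# back onto the strand concentrations).

#' Monomer specification
#'
#' Describes one origami type: its connector count per face, concentration,
#' and which strands arm (bridge) or disarm its connectors in the DSD layer.
#'
#' @param name `"cylinder"` or `"cuboid"`.
#' @param connectors_per_face 8 or 16.
#' @param concentration Monomer concentration in nM.
#' @param connector_strand Connector strand name carried by the monomer
#'   (`"c1"` or `"c2"`).
#' @param bridge_strands Strands whose presence in a connector complex arms it
#'   for polymerization (cylinder: `"input"`, dangling 9*; cuboid:
#'   `"activator"` or `"fuelA"`, dangling/bridging 8*).
#' @param disarm_strands Strands whose presence disarms the connector
#'   (cylinder: `"inhibitor"`; cuboid: `"fuelB"`).
#' @param initial_dimer_frac Fraction of monomers pre-paired as dimers at
#'   t = 0 (base-stacking dimers; packaged default 0.1 for cuboids, 0 for
#'   cylinders).
#' @return An object of class `dsd_monomer_spec`.
#' @export
monomer_spec <- function(name, connectors_per_face, concentration,
                         connector_strand, bridge_strands, disarm_strands,
                         initial_dimer_frac = 0) {
  stopifnot(name %in% c("cylinder", "cuboid"),
            connectors_per_face %in% c(8L, 16L),
            concentration >= 0,
            initial_dimer_frac >= 0, initial_dimer_frac <= 1)
  structure(
    list(name = name, connectors_per_face = as.integer(connectors_per_face),
         concentration = concentration, connector_strand = connector_strand,
         bridge_strands = bridge_strands, disarm_strands = disarm_strands,
         initial_dimer_frac = initial_dimer_frac),
    class = "dsd_monomer_spec"
  )
}

#' Monomer specifications of an origami circuit
#'
#' @param circuit A `dsd_circuit` built from an origami preset.
#' @return Named list of [monomer_spec()]s (`cylinder`, `cuboid`).
#' @export
monomer_specs <- function(circuit) {
  cfg <- circuit$config
  if (!cfg$origami_mode) {
    stop("monomer specs exist only for origami-mode circuits", call. = FALSE)
  }
  list(
    cylinder = monomer_spec(
      "cylinder", cfg$connectors_per_face[["cylinder"]],
      cfg$monomer_concentrations[["cylinder"]],
      connector_strand = "c1", bridge_strands = "input",
      disarm_strands = "inhibitor", initial_dimer_frac = 0
    ),
    cuboid = monomer_spec(
      "cuboid", cfg$connectors_per_face[["cuboid"]],
      cfg$monomer_concentrations[["cuboid"]],
      connector_strand = "c2", bridge_strands = c("activator", "fuelA"),
      disarm_strands = "fuelB", initial_dimer_frac = 0.1
    )
  )
}

#' Assembly model parameters
#'
#' @param k_bond Baseline face-face association rate, nM^-1 s^-1 (calibrated).
#' @param gamma Length-dependent collision discount exponent: a pair of
#'   fibrils of lengths `Li`, `Lj` joins with kernel `(Li Lj)^-gamma`.
#' @param m_arm Armed-fraction exponent for bonding: join propensities carry
#'   `a(t)^m_arm` (both faces of a new bond must be armed).
#' @param theta_break Scission cooperativity exponent on the disarmed
#'   fraction: per-bond break rate carries `(1 - a(t))^theta_break`.
#' @param k_break Dimensionless scale linking the per-connector disarm hazard
#'   `d(t)` to the per-bond scission rate (calibrated).
#' @param k_frag0 Baseline per-bond scission rate, s^-1 (calibrated): the slow
#'   thermal/collisional fragmentation that balances growth into the observed
#'   dynamic plateau of armed fibrils.
#' @param n_monomers_sim Simulated monomer count per type (default 5000).
#' @return An object of class `dsd_assembly_params`.
#' @export
assembly_params <- function(k_bond = 1.97e-3, gamma = 0.5, m_arm = 2,
                            theta_break = 2, k_break = 1.54, k_frag0 = 3.39e-4,
                            n_monomers_sim = 5000L) {
  stopifnot(k_bond >= 0, gamma >= 0, m_arm >= 0, theta_break >= 0,
            k_break >= 0, k_frag0 >= 0, n_monomers_sim >= 100L)
  structure(
    list(k_bond = k_bond, gamma = gamma, m_arm = m_arm,
         theta_break = theta_break, k_break = k_break, k_frag0 = k_frag0,
         n_monomers_sim = as.integer(n_monomers_sim)),
    class = "dsd_assembly_params"
  )
}

#' Arming trace of a monomer type
#'
#' From a strand-level time course, computes `a(t)`, the armed fraction of
#' the monomer's connectors (concentration of connector complexes containing
#' a bridging strand and no disarming strand, over the total connector pool),
#' and `d(t)`, the instantaneous per-connector disarming hazard (total flux
#' of reactions that reduce the armed pool, divided by the armed
#' concentration).
#'
#' @param tc A `dsd_timecourse`.
#' @param spec A [monomer_spec()].
#' @param crn The `dsd_crn` the time course came from.
#' @return Tibble with `time_s`, `a`, `d`.
#' @export
arming_trace <- function(tc, spec, crn) {
  meta <- attr(tc, "meta")
  conn_cnt <- vapply(meta$strands, function(st) sum(st == spec$connector_strand),
                     numeric(1))
  if (all(conn_cnt == 0)) {
    stop("connector strand ", spec$connector_strand,
         " absent from the time course", call. = FALSE)
  }
  armed <- conn_cnt > 0 &
    vapply(meta$strands, function(st) any(st %in% spec$bridge_strands), logical(1)) &
    !vapply(meta$strands, function(st) any(st %in% spec$disarm_strands), logical(1))
  conc <- as.matrix(tc[, meta$label, drop = FALSE])
  total <- as.vector(conc %*% conn_cnt)
  armed_conc <- as.vector(conc %*% (conn_cnt * armed))
  a <- ifelse(total > 0, armed_conc / total, 0)

  # disarming flux: reactions that reduce the armed connector count
  rx <- crn$reactions
  armed_cnt <- stats::setNames(conn_cnt * armed, meta$key)
  dcount <- numeric(nrow(rx))
  for (j in seq_len(nrow(rx))) {
    before <- armed_cnt[[rx$r1[j]]] +
      (if (!is.na(rx$r2[j])) armed_cnt[[rx$r2[j]]] else 0)
    after <- armed_cnt[[rx$p1[j]]] +
      (if (!is.na(rx$p2[j])) armed_cnt[[rx$p2[j]]] else 0) +
      (if (!is.na(rx$p3[j])) armed_cnt[[rx$p3[j]]] else 0)
    dcount[j] <- max(0, before - after)
  }
  act <- dcount > 0
  d <- numeric(nrow(tc))
  if (any(act)) {
    key_idx <- stats::setNames(seq_len(nrow(meta)), meta$key)
    i1 <- unname(key_idx[rx$r1[act]])
    i2v <- rx$r2[act]
    flux <- matrix(0, nrow(tc), sum(act))
    for (k in seq_along(i1)) {
      fl <- rx$rate[act][k] * conc[, i1[k]]
      if (!is.na(i2v[k])) fl <- fl * conc[, key_idx[[i2v[k]]]]
      flux[, k] <- fl * dcount[act][k]
    }
    d <- rowSums(flux) / pmax(armed_conc, 1e-9)
  }
  tibble::tibble(time_s = tc$time_s, a = a, d = d)
}

#' Simulate fibril assembly of one monomer type
#'
#' Gillespie simulation over the fibril population with time-varying
#' propensities (piecewise-constant arming/disarm traces, exact SSA within
#' each interval). Joining of fibrils i, j has propensity
#' `k_bond * c_m / N * a(t)^m_arm * (Li Lj)^-gamma` (with `c_m` the monomer
#' concentration and `N` the simulated monomer count); every internal bond
#' breaks at `k_break * d(t) * (1 - a(t))^theta_break`. Monomers are
#' conserved exactly; self-sorting is structural (each type is simulated on
#' its own population).
#'
#' @param arming Tibble from [arming_trace()].
#' @param spec A [monomer_spec()].
#' @param params [assembly_params()].
#' @param checkpoints_h Checkpoint times (hours) at which the length
#'   distribution is recorded.
#' @param seed Integer seed.
#' @return Tibble with `species`, `time_h`, `length`, `count`.
#' @export
simulate_assembly <- function(arming, spec, params = assembly_params(),
                              checkpoints_h = c(0, 0.25, 0.5, 1, 2, 4, 8, 18),
                              seed = 1L) {
  stopifnot(inherits(spec, "dsd_monomer_spec"),
            inherits(params, "dsd_assembly_params"))
  tg <- arming$time_s
  k_join <- params$k_bond * spec$concentration / params$n_monomers_sim
  snaps <- assembly_core(
    params$n_monomers_sim, spec$initial_dimer_frac,
    tg, arming$a[-length(arming$a)], arming$d[-length(arming$d)],
    k_join, params$gamma, params$m_arm, params$theta_break, params$k_break,
    params$k_frag0, checkpoints_h * 3600, as.integer(seed)
  )
  rows <- lapply(seq_along(checkpoints_h), function(i) {
    tab <- table(snaps[[i]])
    tibble::tibble(
      species = spec$name, time_h = checkpoints_h[i],
      length = as.integer(names(tab)), count = as.integer(tab)
    )
  })
  dplyr::bind_rows(rows)
}

#' Coupled DSD + assembly simulation of an origami preset
#'
#' Runs the deterministic strand-level trajectory once, derives the arming
#' traces of both monomer types, and drives stochastic assembly replicates.
#'
#' @param circuit Origami preset name, configuration or built circuit.
#' @param p [rate_params()].
#' @param params [assembly_params()].
#' @param seeds Integer vector of replicate seeds.
#' @param checkpoints_h Checkpoint times in hours.
#' @param duration_h Simulated duration (hours).
#' @return A tibble of class `dsd_fibrils` with `seed`, `species`, `time_h`,
#'   `length`, `count`; attributes keep the time course and arming traces.
#' @export
simulate_fibrils <- function(circuit, p = rate_params(),
                             params = assembly_params(), seeds = 1:20,
                             checkpoints_h = c(0, 0.25, 0.5, 1, 2, 4, 8, 18),
                             duration_h = 18) {
  if (is.character(circuit) || inherits(circuit, "dsd_circuit_config")) {
    circuit <- build_circuit(circuit)
  }
  crn <- circuit_crn(circuit, p)
  tc <- simulate_ode(crn, circuit$conc, duration_h = duration_h)
  specs <- monomer_specs(circuit)
  out <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    arm <- arming_trace(tc, spec, crn)
    for (sd in seeds) {
      res <- simulate_assembly(arm, spec, params, checkpoints_h,
                               seed = sd * 8L + si)
      res$seed <- sd
      out[[length(out) + 1L]] <- res
    }
  }
  fib <- dplyr::bind_rows(out) |>
    dplyr::select("seed", "species", "time_h", "length", "count")
  structure(fib, class = c("dsd_fibrils", class(fib)),
            timecourse = tc,
            arming = lapply(specs, arming_trace, tc = tc, crn = crn))
}
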