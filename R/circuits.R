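# Strand library and preset experimental conditions.
#
# The packaged domain architecture realizes the published negative-feedback
# circuit: an input strand displaces a quencher-bearing activator from the
# cylinder connector c1 (toehold 5, 8 nb), the released activator displaces a
# quencher-bearing inhibitor from the cuboid connector c2 (mismatched toehold
# 6', 4 nb effective, loop-presented), and the released inhibitor completes
# the feedback by displacing the input from the cylinder (toehold 1, 9 nb),
# burying every c1 entry toehold so completion is irreversible. Bridging
# domains 9 (cylinder, via c1*) and 8 (cuboid, via c2*) arm polymerization.
# Fuel A re-displaces the activator from the cuboid bridge while replacing it
# (toehold 10, 7 nb); fuel B does the same but cannot bridge (no 8*); the
# threshold gate is a competitive activator sink with a fully complementary
# toehold 6.

circuit_domains <- function() {
  list(
    d1  = domain("1", 9L),
    d2  = domain("2", 16L),
    d5  = domain("5", 8L),
    d6  = domain("6", 8L),
    d6p = domain("6", 8L, mismatch_nb = 4L),
    d7  = domain("7", 16L),
    d8  = domain("8", 16L, bridge = TRUE),
    d9  = domain("9", 16L, bridge = TRUE),
    d10 = domain("10", 7L)
  )
}

#' The packaged strand library
#'
#' Returns the ten strands of the circuit as a named list. Toehold lengths
#' follow the published design (1: 9 nb, 5: 8 nb, 10: 7 nb, 6/6': 8 nb with a
#' 4-base mismatch on the connector variant 6'); the branch-migration cores 2
#' and 7 and the bridging domains 8 and 9 are 16 nb.
#'
#' @return Named list of [strand()] objects: `c1`, `c1s`, `c2`, `c2s`,
#'   `input`, `activator`, `inhibitor`, `fuelA`, `fuelB`, `threshold`.
#' @export
dsd_strands <- function() {
  d <- circuit_domains()
  cpl <- function(x) complement(x)
  list(
    c1 = strand("c1", list(d$d1, d$d2, d$d5), labels = "Cy5"),
    c1s = strand("c1s", list(d$d9)),
    c2 = strand("c2", list(d$d6p, d$d7), labels = "Cy3"),
    c2s = strand("c2s", list(d$d8)),
    input = strand("input", list(cpl(d$d9), cpl(d$d2), cpl(d$d5))),
    activator = strand(
      "activator",
      list(cpl(d$d2), cpl(d$d6), cpl(d$d7), cpl(d$d8), d$d10),
      labels = "quencher",
      hairpins = list(hairpin(protected = c("6*", "7*", "8*"), guard = "2*",
                              mode = "while_guard_bound", loop = "6*"))
    ),
    inhibitor = strand(
      "inhibitor",
      list(cpl(d$d7), cpl(d$d1), cpl(d$d2), cpl(d$d5)),
      labels = "quencher",
      hairpins = list(hairpin(protected = c("1*", "2*", "5*"), guard = "7*",
                              mode = "while_guard_bound", loop = "1*"))
    ),
    fuelA = strand("fuelA", list(cpl(d$d10), cpl(d$d7), cpl(d$d8))),
    fuelB = strand("fuelB", list(cpl(d$d10), cpl(d$d7))),
    threshold = strand(
      "threshold", list(d$d6, d$d7),
      hairpins = list(hairpin(protected = "7", guard = "6",
                              mode = "until_guard_bound", loop = character()))
    )
  )
}

# the preannealed gate complexes and free species, keyed by species label
circuit_species <- function() {
  s <- dsd_strands()
  list(
    "activator/c1" = complex(list(s$c1, s$activator),
                             rbind(c(1L, 2L, 2L, 1L))),
    "c2/inhibitor" = complex(list(s$c2, s$inhibitor),
                             rbind(c(1L, 2L, 2L, 1L))),
    "c1s" = complex(list(s$c1s)),
    "c2s" = complex(list(s$c2s)),
    "input" = complex(list(s$input)),
    "fuelA" = complex(list(s$fuelA)),
    "fuelB" = complex(list(s$fuelB)),
    "threshold" = complex(list(s$threshold))
  )
}

ORIGAMI_TETHERED <- c("c1", "c1s", "c2", "c2s")

#' Circuit configuration
#'
#' A validated run condition: which circuit modules are active, the initial
#' concentration of every species (nM), and -- for origami conditions -- the
#' monomer concentrations and connectors per face, from which the connector
#' pools are derived (`monomer concentration x connectors_per_face`).
#'
#' @param modules Character subset of `c("basic", "fuelA", "fuelB", "threshold")`.
#' @param condition Named numeric vector, species label -> initial nM.
#' @param origami_mode Logical; activates the architectural slowdown factor
#'   `rho` and the assembly coupling.
#' @param connectors_per_face Named integer vector (`cylinder`, `cuboid`),
#'   8 or 16, used when `origami_mode` is `TRUE`.
#' @param monomer_concentrations Named numeric vector (`cylinder`, `cuboid`),
#'   nM of each origami monomer.
#' @param duration_h Simulated duration in hours.
#' @param name Optional preset name.
#' @return An object of class `dsd_circuit_config`.
#' @export
circuit_config <- function(modules = "basic",
                           condition,
                           origami_mode = FALSE,
                           connectors_per_face = c(cylinder = 16L, cuboid = 16L),
                           monomer_concentrations = c(cylinder = 0, cuboid = 0),
                           duration_h = 18,
                           name = NA_character_) {
  bad <- setdiff(modules, c("basic", "fuelA", "fuelB", "threshold"))
  if (length(bad) > 0L) {
    stop("unknown circuit modules: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  known <- names(circuit_species())
  badc <- setdiff(names(condition), known)
  if (length(badc) > 0L) {
    stop("unknown species in condition: ", paste(badc, collapse = ", "), call. = FALSE)
  }
  if (any(condition < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (origami_mode) {
    if (!all(c("cylinder", "cuboid") %in% names(connectors_per_face)) ||
        !all(connectors_per_face %in% c(8L, 16L))) {
      stop("connectors_per_face must name cylinder and cuboid, values 8 or 16",
           call. = FALSE)
    }
    pools <- monomer_concentrations[c("cylinder", "cuboid")] *
      connectors_per_face[c("cylinder", "cuboid")]
    # connector totals must equal monomer concentration x connectors per face
    chk <- c("activator/c1" = unname(pools["cylinder"]),
             "c2/inhibitor" = unname(pools["cuboid"]))
    for (nm in names(chk)) {
      if (!isTRUE(all.equal(unname(condition[nm]), chk[[nm]]))) {
        stop("origami condition inconsistent: ", nm, " pool must be ",
             chk[[nm]], " nM", call. = FALSE)
      }
    }
  }
  structure(
    list(modules = modules, condition = condition, origami_mode = origami_mode,
         connectors_per_face = connectors_per_face,
         monomer_concentrations = monomer_concentrations,
         temperature_C = 37, duration_h = duration_h, name = name),
    class = "dsd_circuit_config"
  )
}

#' @export
print.dsd_circuit_config <- function(x, ...) {
  cat(sprintf("<circuit config%s: modules %s, %s>\n",
              if (!is.na(x$name)) paste0(" '", x$name, "'") else "",
              paste(x$modules, collapse = "+"),
              if (x$origami_mode) "origami mode" else "free strands"))
  cond <- x$condition[x$condition > 0]
  for (nm in names(cond)) cat(sprintf("  %-14s %g nM\n", nm, cond[[nm]]))
  invisible(x)
}

preset_table <- function() {
  og <- function(cyl_nM, cub_nM, cyl_c, cub_c) {
    list(connectors = c(cylinder = as.integer(cyl_c), cuboid = as.integer(cub_c)),
         monomers = c(cylinder = cyl_nM, cuboid = cub_nM))
  }
  list(
    # free-strand reference circuits
    "freestrand-160" = list(
      modules = "basic", origami = NULL,
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160)),
    "freestrand-320" = list(
      modules = "basic", origami = NULL,
      conc = c("activator/c1" = 320, "c1s" = 320, "c2/inhibitor" = 320,
               "c2s" = 320, "input" = 320)),
    "freestrand-160-noinput" = list(
      modules = "basic", origami = NULL,
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 0)),
    "freestrand-fuelA-240" = list(
      modules = c("basic", "fuelA"), origami = NULL,
      conc = c("activator/c1" = 160, "c1s" = 160, "input" = 160,
               "c2/inhibitor" = 240, "c2s" = 240, "fuelA" = 240)),
    "freestrand-threshold" = list(
      modules = c("basic", "threshold"), origami = NULL,
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160, "threshold" = 160)),
    "freestrand-threshold-fuelB" = list(
      modules = c("basic", "threshold", "fuelB"), origami = NULL,
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160, "threshold" = 160, "fuelB" = 160)),
    # origami circuits (connector pools = monomer nM x connectors per face)
    "origami-basic-10" = list(
      modules = "basic", origami = og(10, 10, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160)),
    "origami-basic-20" = list(
      modules = "basic", origami = og(20, 20, 16, 16),
      conc = c("activator/c1" = 320, "c1s" = 320, "c2/inhibitor" = 320,
               "c2s" = 320, "input" = 320)),
    "origami-basic-10-noinput" = list(
      modules = "basic", origami = og(10, 10, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 0)),
    "origami-cuboid8c-20" = list(
      modules = "basic", origami = og(10, 20, 16, 8),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160)),
    "origami-fuelA" = list(
      modules = c("basic", "fuelA"), origami = og(10, 15, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 240,
               "c2s" = 240, "input" = 160, "fuelA" = 160)),
    "origami-fuelA-240" = list(
      modules = c("basic", "fuelA"), origami = og(10, 15, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 240,
               "c2s" = 240, "input" = 160, "fuelA" = 240)),
    "origami-fuelA-80" = list(
      modules = c("basic", "fuelA"), origami = og(10, 15, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 240,
               "c2s" = 240, "input" = 160, "fuelA" = 80)),
    "origami-fuelB-480" = list(
      modules = c("basic", "fuelB"), origami = og(10, 15, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 240,
               "c2s" = 240, "input" = 160, "fuelB" = 480)),
    "origami-threshold" = list(
      modules = c("basic", "threshold"), origami = og(10, 10, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160, "threshold" = 160)),
    "origami-threshold-fuelB" = list(
      modules = c("basic", "threshold", "fuelB"), origami = og(10, 10, 16, 16),
      conc = c("activator/c1" = 160, "c1s" = 160, "c2/inhibitor" = 160,
               "c2s" = 160, "input" = 160, "threshold" = 160, "fuelB" = 160))
  )
}

#' List the packaged presets
#'
#' @return Tibble with `preset`, `modules`, `origami_mode` and the non-zero
#'   initial concentrations as a compact string.
#' @export
dsd_presets <- function() {
  tb <- preset_table()
  tibble::tibble(
    preset = names(tb),
    modules = vapply(tb, function(x) paste(x$modules, collapse = "+"), character(1)),
    origami_mode = vapply(tb, function(x) !is.null(x$origami), logical(1)),
    condition = vapply(tb, function(x) {
      cc <- x$conc[x$conc > 0]
      paste(sprintf("%s=%g", names(cc), cc), collapse = ", ")
    }, character(1))
  )
}

#' Fetch a preset condition
#'
#' @param name Preset name (see [dsd_presets()]).
#' @param ... Overrides applied to the condition vector, e.g. `input = 0`.
#'   Species labels with `/` must be backtick-quoted.
#' @param duration_h Simulated duration in hours.
#' @return A [circuit_config()].
#' @export
preset <- function(name, ..., duration_h = 18) {
  tb <- preset_table()
  if (!name %in% names(tb)) {
    stop("unknown preset '", name, "'; see dsd_presets()", call. = FALSE)
  }
  pp <- tb[[name]]
  conc <- pp$conc
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(circuit_species())) {
      stop("unknown species override: ", nm, call. = FALSE)
    }
    conc[nm] <- ov[[nm]]
  }
  if (is.null(pp$origami)) {
    circuit_config(pp$modules, conc, origami_mode = FALSE,
                   duration_h = duration_h, name = name)
  } else {
    circuit_config(pp$modules, conc, origami_mode = TRUE,
                   connectors_per_face = pp$origami$connectors,
                   monomer_concentrations = pp$origami$monomers,
                   duration_h = duration_h, name = name)
  }
}

#' Materialize a circuit configuration
#'
#' Resolves a configuration into the initial species (complexes), their
#' concentrations, and the origami-tethering information the rate model needs.
#'
#' @param cfg A [circuit_config()] or preset name.
#' @return A list of class `dsd_circuit`: `species` (named list of complexes,
#'   label -> complex, for species with non-zero or declared concentration),
#'   `conc` (named nM vector), `tethered_strands` (character; empty unless
#'   origami mode), `config` (the input configuration).
#' @export
build_circuit <- function(cfg) {
  if (is.character(cfg)) cfg <- preset(cfg)
  stopifnot(inherits(cfg, "dsd_circuit_config"))
  all_sp <- circuit_species()
  need <- names(cfg$condition)
  module_species <- list(
    basic = c("activator/c1", "c1s", "c2/inhibitor", "c2s", "input"),
    fuelA = "fuelA", fuelB = "fuelB", threshold = "threshold"
  )
  allowed <- unique(unlist(module_species[cfg$modules]))
  extra <- setdiff(need[cfg$condition > 0], allowed)
  if (length(extra) > 0L) {
    stop("species not part of the configured modules: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(
    list(species = all_sp[need], conc = cfg$condition,
         tethered_strands = if (cfg$origami_mode) ORIGAMI_TETHERED else character(),
         config = cfg),
    class = "dsd_circuit"
  )
}

#' @export
print.dsd_circuit <- function(x, ...) {
  cat(sprintf("<circuit: %d initial species, %s>\n", length(x$species),
              if (length(x$tethered_strands)) "origami mode" else "free strands"))
  invisible(x)
}
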