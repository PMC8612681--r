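# Domain-level representation of strands.
#
# A domain is a named stretch of bases; complementarity is by name, with the
# starred form marked by `is_complement`. Mismatched variants (e.g. toehold 6'
# which pairs 6* with a 4-base mismatch) carry `mismatch_nb` > 0.

#' Create a sequence domain
#'
#' Domains are the atomic unit of the model: a short named stretch of
#' nucleobases. Complementarity is tracked by name (the starred form of `"5"`
#' pairs `"5"`), and engineered mismatches against the nominal complement are
#' carried as a base count, e.g. the 8-nb connector toehold with a 4-base
#' mismatch that the presets call `6'`.
#'
#' @param name Short identifier, e.g. `"5"`, `"6"`, `"10"`.
#' @param length_nb Domain length in nucleobases (>= 1).
#' @param complement Logical; `TRUE` for the starred form.
#' @param mismatch_nb Number of mismatched bases relative to the nominal
#'   complement (0 for a perfect match).
#' @param bridge Logical; marks a polymer-bridging domain (8, 9). An isolated
#'   two-strand duplex held only by a bridging bond is metastable and frays at
#'   `u_bridge_solo`; gate duplexes (non-bridge long bonds) do not.
#' @return An object of class `dsd_domain`.
#' @examples
#' domain("5", 8)
#' domain("6", 8, mismatch_nb = 4) # displayed as 6'
#' @export
domain <- function(name, length_nb, complement = FALSE, mismatch_nb = 0L,
                   bridge = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length_nb <- as.integer(length_nb)
  mismatch_nb <- as.integer(mismatch_nb)
  if (length_nb < 1L) stop("domain length_nb must be >= 1", call. = FALSE)
  if (mismatch_nb < 0L || mismatch_nb > length_nb) {
    stop("mismatch_nb must lie in [0, length_nb]", call. = FALSE)
  }
  structure(
    list(
      name = name,
      length_nb = length_nb,
      is_complement = isTRUE(complement),
      mismatch_nb = mismatch_nb,
      bridge = isTRUE(bridge)
    ),
    class = "dsd_domain"
  )
}

#' Complement of a domain
#'
#' Returns the starred/unstarred partner with identical length and mismatch
#' count. The operation is an involution: `complement(complement(d))` is `d`.
#'
#' @param d A `dsd_domain`.
#' @return The complementary `dsd_domain`.
#' @export
complement <- function(d) UseMethod("complement")

#' @export
complement.dsd_domain <- function(d) {
  d$is_complement <- !d$is_complement
  d
}

#' Printable label of a domain
#'
#' Mismatched variants get a prime (`6'`), complements a star (`6*`).
#'
#' @param d A `dsd_domain`.
#' @return Character scalar, e.g. `"5"`, `"6'"`, `"6*"`.
#' @export
domain_label <- function(d) {
  paste0(d$name, if (d$mismatch_nb > 0L) "'", if (d$is_complement) "*")
}

#' @export
print.dsd_domain <- function(x, ...) {
  cat(sprintf(
    "<domain %s: %d nb%s>\n", domain_label(x), x$length_nb,
    if (x$mismatch_nb > 0L) sprintf(", %d mismatches", x$mismatch_nb) else ""
  ))
  invisible(x)
}

# Domains at or below this length behave as toeholds: they nucleate
# displacement and can dissociate spontaneously. Longer domains (the 16-nb
# branch-migration cores 2 and 7 and bridging domains 8 and 9) are
# non-dissociating on the simulated horizon.
TOEHOLD_MAX_NB <- 10L

#' Is a domain a toehold?
#'
#' @param d A `dsd_domain`.
#' @return Logical.
#' @export
is_toehold <- function(d) d$length_nb <= TOEHOLD_MAX_NB

# two domain instances can pair iff same name and opposite orientation
domains_complementary <- function(a, b) {
  a$name == b$name && a$is_complement != b$is_complement
}

#' Declare hairpin protection on a strand
#'
#' Hairpin loops are modelled kinetically, not structurally. A protection
#' declaration lists the domains sequestered by the hairpin, a guard domain,
#' and a mode:
#' \describe{
#'   \item{`"while_guard_bound"`}{protected domains are inert while the guard
#'     domain is bound -- the steric protection a gate exerts on the loop of a
#'     bound signal strand, released when the strand leaves the gate.}
#'   \item{`"until_guard_bound"`}{protected domains are inert until the guard
#'     (the hairpin's entry toehold) is bound -- a stem that opens only after
#'     toehold invasion, as in the threshold gate.}
#' }
#' The `loop` subset of the protected domains (by default all of them) are the
#' loop-presented toeholds proper: once active they initiate binding with the
#' hairpin protection factor `h` of the rate model, while the remaining
#' protected domains react at the full rate after release.
#'
#' @param protected Character vector of domain labels (see [domain_label()]).
#' @param guard Single domain label.
#' @param mode `"while_guard_bound"` or `"until_guard_bound"`.
#' @param loop Character vector (subset of `protected`) carrying the kinetic
#'   factor `h`; may be empty.
#' @return A `dsd_hairpin` declaration.
#' @export
hairpin <- function(protected, guard,
                    mode = c("while_guard_bound", "until_guard_bound"),
                    loop = protected) {
  mode <- match.arg(mode)
  stopifnot(is.character(protected), length(protected) >= 1L,
            is.character(guard), length(guard) == 1L)
  if (length(loop) > 0L && !all(loop %in% protected)) {
    stop("hairpin loop domains must be a subset of the protected domains",
         call. = FALSE)
  }
  structure(list(protected = protected, guard = guard, mode = mode, loop = loop),
            class = "dsd_hairpin")
}

#' Create a strand
#'
#' A strand is an ordered list of domains plus end/position annotations:
#' fluorophore and quencher labels, and hairpin protection declarations. Every
#' hairpin's protected and guard domains must occur on the strand.
#'
#' @param name Strand identifier.
#' @param domains List of [domain()] objects, in strand order.
#' @param labels Character vector drawn from `c("Cy3", "Cy5", "quencher")`.
#' @param hairpins List of [hairpin()] declarations.
#' @return An object of class `dsd_strand`.
#' @export
strand <- function(name, domains, labels = character(), hairpins = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.list(domains), length(domains) >= 1L)
  ok <- vapply(domains, inherits, logical(1), "dsd_domain")
  if (!all(ok)) stop("all domains must be dsd_domain objects", call. = FALSE)
  bad <- setdiff(labels, c("Cy3", "Cy5", "quencher"))
  if (length(bad) > 0L) {
    stop("unknown strand labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  labs <- vapply(domains, domain_label, character(1))
  for (hp in hairpins) {
    if (!inherits(hp, "dsd_hairpin")) stop("hairpins must be dsd_hairpin objects", call. = FALSE)
    missing <- setdiff(c(hp$protected, hp$guard), labs)
    if (length(missing) > 0L) {
      stop("hairpin references domains absent from strand '", name, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(name = name, domains = domains, labels = labels, hairpins = hairpins),
    class = "dsd_strand"
  )
}

#' @export
print.dsd_strand <- function(x, ...) {
  labs <- vapply(x$domains, domain_label, character(1))
  cat(sprintf("<strand %s: [%s]%s>\n", x$name, paste(labs, collapse = " "),
              if (length(x$labels)) paste0(" {", paste(x$labels, collapse = ","), "}") else ""))
  invisible(x)
}

strand_domain_labels <- function(s) vapply(s$domains, domain_label, character(1))

# indices of domains protected on strand s, given logical vector `bound`
# marking which domain positions are currently paired
protected_domain_idx <- function(s, bound) {
  labs <- strand_domain_labels(s)
  prot <- rep(FALSE, length(labs))
  for (hp in s$hairpins) {
    guard_bound <- any(bound[labs == hp$guard])
    active_guard <- switch(hp$mode,
      while_guard_bound = guard_bound,
      until_guard_bound = !guard_bound
    )
    if (active_guard) prot <- prot | labs %in% hp$protected
  }
  which(prot)
}

# is a given domain position part of any hairpin loop declaration
# (carries the h factor when it initiates a bind)?
loop_domain_idx <- function(s) {
  labs <- strand_domain_labels(s)
  which(labs %in% unlist(lapply(s$hairpins, `[[`, "loop")))
}
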