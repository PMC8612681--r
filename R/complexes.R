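# Complexes: multisets of strands joined by domain-level bonds.
#
# Bonds are stored as an integer matrix with one row per bond and columns
# (s1, d1, s2, d2): strand index / domain index of each partner. Bond partners
# must be complementary by name, each domain instance participates in at most
# one bond, and the strand-bond graph must be connected.

#' Create a complex
#'
#' @param strands List of [strand()] objects (a multiset; the same strand may
#'   occur more than once).
#' @param bonds Integer matrix with columns `(s1, d1, s2, d2)` pairing domain
#'   instances on distinct strands, or `NULL` for a free strand.
#' @param validate Check invariants (complementarity, single pairing,
#'   connectivity, pseudoknot freedom).
#' @return An object of class `dsd_complex`.
#' @export
complex <- function(strands, bonds = NULL, validate = TRUE) {
  if (inherits(strands, "dsd_strand")) strands <- list(strands)
  stopifnot(is.list(strands), length(strands) >= 1L)
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 4L)
  bonds <- matrix(as.integer(bonds), ncol = 4L,
                  dimnames = list(NULL, c("s1", "d1", "s2", "d2")))
  x <- structure(list(strands = strands, bonds = bonds), class = "dsd_complex")
  if (validate) validate_complex(x)
  x
}

#' Validate a complex
#'
#' Checks the structural invariants: bond references in range, partners
#' complementary by name, each domain instance in at most one bond, strand-bond
#' graph connected, and no pseudoknots (some strand ordering draws all bonds
#' without crossings; bonds internal to the polymerization bridge are handled
#' by the assembly module, not here).
#'
#' @param x A `dsd_complex`.
#' @param check_planarity Also run the pseudoknot check (exhaustive over strand
#'   orderings; intended for the small complexes of the enumerated universe).
#' @return `x`, invisibly. Errors with a structural message on violation.
#' @export
validate_complex <- function(x, check_planarity = TRUE) {
  ns <- length(x$strands)
  b <- x$bonds
  if (nrow(b) > 0L) {
    if (any(b[, c(1L, 3L)] < 1L) || any(b[, c(1L, 3L)] > ns)) {
      stop("bond references a strand outside the complex", call. = FALSE)
    }
    for (i in seq_len(nrow(b))) {
      s1 <- x$strands[[b[i, 1L]]]; s2 <- x$strands[[b[i, 3L]]]
      if (b[i, 2L] < 1L || b[i, 2L] > length(s1$domains) ||
          b[i, 4L] < 1L || b[i, 4L] > length(s2$domains)) {
        stop("bond references a domain outside its strand", call. = FALSE)
      }
      if (b[i, 1L] == b[i, 3L]) {
        stop("bonds must join distinct strands", call. = FALSE)
      }
      d1 <- s1$domains[[b[i, 2L]]]; d2 <- s2$domains[[b[i, 4L]]]
      if (!domains_complementary(d1, d2)) {
        stop(sprintf("bond partners %s and %s are not complementary",
                     domain_label(d1), domain_label(d2)), call. = FALSE)
      }
    }
    ends <- rbind(b[, 1:2, drop = FALSE], b[, 3:4, drop = FALSE])
    keys <- paste(ends[, 1L], ends[, 2L])
    if (anyDuplicated(keys)) {
      stop("a domain instance participates in more than one bond", call. = FALSE)
    }
  }
  if (ns > 1L) {
    comp <- strand_components(x)
    if (length(unique(comp)) != 1L) {
      stop("strand-bond graph is not connected", call. = FALSE)
    }
  }
  if (check_planarity && !is_pseudoknot_free(x)) {
    stop("complex is pseudoknotted (no strand ordering draws bonds without crossing)",
         call. = FALSE)
  }
  invisible(x)
}

# connected components of the strand-bond graph (integer component id per strand)
strand_components <- function(x) {
  ns <- length(x$strands)
  comp <- seq_len(ns)
  root <- function(i) { while (comp[i] != i) { comp[i] <- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(x$bonds) > 0L) {
    for (i in seq_len(nrow(x$bonds))) {
      a <- comp[x$bonds[i, 1L]]; b2 <- comp[x$bonds[i, 3L]]
      while (comp[a] != a) a <- comp[a]
      while (comp[b2] != b2) b2 <- comp[b2]
      if (a != b2) comp[b2] <- a
    }
    for (i in seq_len(ns)) { j <- i; while (comp[j] != j) j <- comp[j]; comp[i] <- j }
  }
  comp
}

# TRUE if some strand ordering and per-strand traversal direction renders all
# bonds as non-crossing arcs on a line. Strands are written template-parallel
# in this library (an antiparallel duplex pairs equal-direction indices), so
# each strand may be laid down in either direction.
is_pseudoknot_free <- function(x) {
  ns <- length(x$strands)
  if (nrow(x$bonds) <= 1L) return(TRUE)
  nd <- vapply(x$strands, function(s) length(s$domains), integer(1))
  perms <- all_permutations(ns)
  orients <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ns)))
  for (p in perms) {
    offset <- cumsum(c(0L, nd[p]))[seq_len(ns)]
    for (oi in seq_len(nrow(orients))) {
      rev_s <- orients[oi, ]
      pos_of <- function(s, d) {
        k <- match(s, p)
        dd <- ifelse(rev_s[s], nd[s] + 1L - d, d)
        offset[k] + dd
      }
      a <- mapply(pos_of, x$bonds[, 1L], x$bonds[, 2L])
      b <- mapply(pos_of, x$bonds[, 3L], x$bonds[, 4L])
      lo <- pmin(a, b); hi <- pmax(a, b)
      crossing <- FALSE
      nb <- length(lo)
      for (i in seq_len(nb - 1L)) {
        for (j in (i + 1L):nb) {
          if ((lo[i] < lo[j] && lo[j] < hi[i] && hi[i] < hi[j]) ||
              (lo[j] < lo[i] && lo[i] < hi[j] && hi[j] < hi[i])) {
            crossing <- TRUE; break
          }
        }
        if (crossing) break
      }
      if (!crossing) return(TRUE)
    }
  }
  FALSE
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  # setdiff keeps order, so index the remaining values by the sub-permutation
  out
}

# logical matrix-style list: for each strand, which domain positions are bound
bound_positions <- function(x) {
  out <- lapply(x$strands, function(s) rep(FALSE, length(s$domains)))
  if (nrow(x$bonds) > 0L) {
    for (i in seq_len(nrow(x$bonds))) {
      out[[x$bonds[i, 1L]]][x$bonds[i, 2L]] <- TRUE
      out[[x$bonds[i, 3L]]][x$bonds[i, 4L]] <- TRUE
    }
  }
  out
}

serialize_complex <- function(x, perm) {
  ns <- length(x$strands)
  inv <- integer(ns); inv[perm] <- seq_len(ns)
  sn <- vapply(x$strands[perm], function(s) s$name, character(1))
  b <- x$bonds
  if (nrow(b) > 0L) {
    s1 <- inv[b[, 1L]]; s2 <- inv[b[, 3L]]
    d1 <- b[, 2L]; d2 <- b[, 4L]
    flip <- (s1 > s2) | (s1 == s2 & d1 > d2)
    t1 <- ifelse(flip, s2, s1); td1 <- ifelse(flip, d2, d1)
    t2 <- ifelse(flip, s1, s2); td2 <- ifelse(flip, d1, d2)
    o <- order(t1, td1, t2, td2)
    bs <- paste(t1[o], td1[o], t2[o], td2[o], sep = ".", collapse = ";")
  } else {
    bs <- ""
  }
  paste0(paste(sn, collapse = "+"), "|", bs)
}

#' Canonical identity key of a complex
#'
#' Deterministic string identical for isomorphic complexes (same strand
#' multiset and bond structure, regardless of the order strands were listed)
#' and distinct for non-isomorphic ones. Computed as the lexicographic minimum
#' of the complex serialization over all strand orderings.
#'
#' @param x A `dsd_complex`.
#' @return Character scalar key.
#' @export
canonical_key <- function(x) {
  stopifnot(inherits(x, "dsd_complex"))
  validate_complex(x, check_planarity = FALSE)
  perms <- all_permutations(length(x$strands))
  min(vapply(perms, function(p) serialize_complex(x, p), character(1)))
}

#' Short human-readable label of a complex
#'
#' Strand names joined by `/` in sorted order, e.g. `"activator/c1"`. Not
#' guaranteed unique across bond structures; the species registry
#' disambiguates colliding labels with a `#k` suffix.
#'
#' @param x A `dsd_complex`.
#' @return Character scalar.
#' @export
species_label <- function(x) {
  paste(sort(vapply(x$strands, function(s) s$name, character(1))), collapse = "/")
}

#' @export
print.dsd_complex <- function(x, ...) {
  cat(sprintf("<complex %s: %d strand(s), %d bond(s)>\n",
              species_label(x), length(x$strands), nrow(x$bonds)))
  invisible(x)
}

#' List the free toeholds of a complex
#'
#' Returns the unbound toehold domain instances of a complex, flagging those
#' sequestered inside an unopened hairpin loop as protected (they cannot
#' nucleate a reaction until their guard condition releases them).
#'
#' @param x A `dsd_complex`.
#' @return A tibble with columns `strand`, `strand_idx`, `domain`,
#'   `domain_idx`, `length_nb`, `n_eff`, `loop` (part of a hairpin loop) and
#'   `protected`.
#' @export
free_toeholds <- function(x) {
  stopifnot(inherits(x, "dsd_complex"))
  bnd <- bound_positions(x)
  rows <- list()
  for (si in seq_along(x$strands)) {
    s <- x$strands[[si]]
    prot <- protected_domain_idx(s, bnd[[si]])
    loops <- loop_domain_idx(s)
    for (di in seq_along(s$domains)) {
      d <- s$domains[[di]]
      if (bnd[[si]][di] || !is_toehold(d)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strand = s$name, strand_idx = si,
        domain = domain_label(d), domain_idx = di,
        length_nb = d$length_nb,
        n_eff = effective_toehold_length(d),
        loop = di %in% loops,
        protected = di %in% prot
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      strand = character(), strand_idx = integer(), domain = character(),
      domain_idx = integer(), length_nb = integer(), n_eff = integer(),
      loop = logical(), protected = logical()
    ))
  }
  dplyr::bind_rows(rows)
}
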