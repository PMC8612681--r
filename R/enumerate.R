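# Reaction enumeration: breadth-first closure of an initial species set under
# toehold-mediated 3-way strand displacement semantics.
#
# Moves:
#   bind     - bimolecular join of two complexes at a free complementary
#              domain pair (reversible toehold association; long-domain
#              hybridizations such as the 8/9 fibril bridges also initiate
#              here, at the saturated rate).
#   unbind   - dissociation of a toehold-length bond whose removal splits the
#              complex, at the standard unbinding rate; an isolated two-strand
#              bridge duplex frays at u_bridge_solo.
#   migrate  - irreversible branch-migration run (maximal zip/displacement
#              from an anchored toehold) or an anchored takeover in which an
#              invader bound on the incumbent strand assumes the incumbent's
#              template bonds (the fuel pathways), at k_migrate.

# all unbound domain instances of a complex with loop/protection flags
free_domains <- function(x) {
  bnd <- bound_positions(x)
  rows <- list()
  for (si in seq_along(x$strands)) {
    s <- x$strands[[si]]
    prot <- protected_domain_idx(s, bnd[[si]])
    loops <- loop_domain_idx(s)
    free <- which(!bnd[[si]])
    for (di in free) {
      d <- s$domains[[di]]
      rows[[length(rows) + 1L]] <- list(
        strand_idx = si, domain_idx = di, d = d,
        label = domain_label(d),
        loop = di %in% loops, protected = di %in% prot
      )
    }
  }
  rows
}

# join two complexes with a new bond; returns dsd_complex (unvalidated)
join_complexes <- function(x, y, sx, dx, sy, dy) {
  off <- length(x$strands)
  strands <- c(x$strands, y$strands)
  yb <- y$bonds
  if (nrow(yb) > 0L) yb[, c(1L, 3L)] <- yb[, c(1L, 3L)] + off
  bonds <- rbind(x$bonds, yb, c(sx, dx, sy + off, dy))
  complex(strands, bonds, validate = FALSE)
}

# split a complex into its connected components (list of dsd_complex)
split_components <- function(x) {
  comp <- strand_components(x)
  ids <- unique(comp)
  if (length(ids) == 1L) return(list(x))
  lapply(ids, function(id) {
    keep <- which(comp == id)
    remap <- match(seq_along(x$strands), keep)
    b <- x$bonds
    if (nrow(b) > 0L) {
      inb <- b[, 1L] %in% keep & b[, 3L] %in% keep
      b <- b[inb, , drop = FALSE]
      b[, 1L] <- remap[b[, 1L]]; b[, 3L] <- remap[b[, 3L]]
    }
    complex(x$strands[keep], b, validate = FALSE)
  })
}

bond_n_eff <- function(x, i) {
  d1 <- x$strands[[x$bonds[i, 1L]]]$domains[[x$bonds[i, 2L]]]
  d2 <- x$strands[[x$bonds[i, 3L]]]$domains[[x$bonds[i, 4L]]]
  effective_pair_length(d1, d2)
}

# signature of a bond row for channel identification
bond_signature <- function(x, row) {
  s1 <- x$strands[[row[1L]]]; s2 <- x$strands[[row[3L]]]
  a <- paste0(s1$name, ":", domain_label(s1$domains[[row[2L]]]))
  b <- paste0(s2$name, ":", domain_label(s2$domains[[row[4L]]]))
  paste(sort(c(a, b)), collapse = "=")
}

#' Apply a branch-migration move at an anchored bond
#'
#' Attempts maximal 3-way branch-migration runs starting from the given bond
#' of a complex, treating each bonded strand in turn as the anchored invader.
#' A run transfers the incumbent's contiguous holds on the template to the
#' invader (zipping over free template domains on the way); strands left
#' without bonds detach, and the result is split into connected components.
#' Anchored-takeover moves (an invader bound *on* the incumbent strand that
#' carries free copies of the incumbent's bound domains, as in the fuel
#' pathways) are also attempted from the anchor.
#'
#' @param x A `dsd_complex`.
#' @param invader_anchor Row index into `x$bonds` of the anchor bond.
#' @param p [rate_params()] (used for the toehold-length cutoffs of the
#'   takeover/completion rules).
#' @return `NULL` if no migration is possible from this anchor (the no-op
#'   signal), otherwise a list of distinct moves, each a list of product
#'   `dsd_complex` objects.
#' @export
apply_migration <- function(x, invader_anchor, p = rate_params()) {
  stopifnot(inherits(x, "dsd_complex"))
  if (invader_anchor < 1L || invader_anchor > nrow(x$bonds)) {
    stop("invader_anchor is not a bond of this complex", call. = FALSE)
  }
  moves <- migration_moves(x, p, anchors = invader_anchor)
  if (length(moves) == 0L) return(NULL)
  lapply(moves, `[[`, "products")
}

# enumerate all migration + takeover moves of a complex
# returns list of list(products = list of complexes, channel = string)
migration_moves <- function(x, p = rate_params(), anchors = seq_len(nrow(x$bonds))) {
  out <- list()
  seen <- character()
  for (bi in anchors) {
    row <- x$bonds[bi, ]
    # both orientations: (invader strand, template strand)
    for (swap in c(FALSE, TRUE)) {
      if (!swap) { sV <- row[1L]; dV <- row[2L]; sT <- row[3L]; dT <- row[4L] }
      else       { sV <- row[3L]; dV <- row[4L]; sT <- row[1L]; dT <- row[2L] }
      for (delta in c(-1L, 1L)) {
        for (eps in c(-1L, 1L)) {
          res <- run_migration(x, sV, dV, sT, dT, delta, eps)
          if (is.null(res)) next
          if (!res$channel %in% seen) {
            seen <- c(seen, res$channel)
            out[[length(out) + 1L]] <- res
          }
        }
      }
      tk <- takeover_move(x, sV, dV, sT, dT, p)
      if (!is.null(tk) && !tk$channel %in% seen) {
        seen <- c(seen, tk$channel)
        out[[length(out) + 1L]] <- tk
      }
    }
  }
  out
}

# orientation-invariant serialization of a bond between two domain instances
norm_bond_str <- function(s1, d1, s2, d2) {
  a <- paste(s1, d1, sep = "."); b <- paste(s2, d2, sep = ".")
  if (a <= b) paste(a, b) else paste(b, a)
}

# single maximal migration run; NULL if no step possible
run_migration <- function(x, sV, dV, sT, dT, delta, eps) {
  bnd <- bound_positions(x)
  bonds <- x$bonds
  tmpl <- x$strands[[sT]]; inv <- x$strands[[sV]]
  ti <- dT; vi <- dV
  removed <- character(); added <- character()
  repeat {
    ti <- ti + delta
    if (ti < 1L || ti > length(tmpl$domains)) break
    # template position held by the invader itself: branch point lies further
    hold <- bond_partner(bonds, sT, ti)
    if (!is.null(hold) && hold[1L] == sV) { next }
    vi2 <- vi + eps
    if (vi2 < 1L || vi2 > length(inv$domains)) break
    if (bnd[[sV]][vi2]) break
    if (!domains_complementary(tmpl$domains[[ti]], inv$domains[[vi2]])) break
    if (is.null(hold)) {
      # zip over a free template domain
      bonds <- rbind(bonds, c(sV, vi2, sT, ti))
      added <- c(added, norm_bond_str(sV, vi2, sT, ti))
    } else {
      # displace the incumbent's hold
      ib <- which((bonds[, 1L] == sT & bonds[, 2L] == ti) |
                  (bonds[, 3L] == sT & bonds[, 4L] == ti))
      removed <- c(removed, norm_bond_str(bonds[ib, 1L], bonds[ib, 2L],
                                          bonds[ib, 3L], bonds[ib, 4L]))
      bonds <- bonds[-ib, , drop = FALSE]
      bonds <- rbind(bonds, c(sV, vi2, sT, ti))
      added <- c(added, norm_bond_str(sV, vi2, sT, ti))
    }
    bnd[[sV]][vi2] <- TRUE
    vi <- vi2
  }
  if (length(added) == 0L) return(NULL)
  y <- complex(x$strands, bonds, validate = FALSE)
  list(
    products = split_components(y),
    channel = paste0("mig|", paste(sort(removed), collapse = ","), ">",
                     paste(sort(added), collapse = ","))
  )
}

bond_partner <- function(bonds, s, d) {
  if (nrow(bonds) == 0L) return(NULL)
  i <- which(bonds[, 1L] == s & bonds[, 2L] == d)
  if (length(i) == 1L) return(c(bonds[i, 3L], bonds[i, 4L]))
  i <- which(bonds[, 3L] == s & bonds[, 4L] == d)
  if (length(i) == 1L) return(c(bonds[i, 1L], bonds[i, 2L]))
  NULL
}

# anchored takeover: invader sV bound (only via the anchor) on incumbent sT;
# invader's free domains substitute for the incumbent's same-label bound
# domains on the shared templates, then the incumbent's remaining
# toehold-length bonds are stripped (completion by unbinding).
takeover_move <- function(x, sV, dV, sT, dT, p = rate_params()) {
  bonds <- x$bonds
  vbonds <- which(bonds[, 1L] == sV | bonds[, 3L] == sV)
  if (length(vbonds) != 1L) return(NULL)
  anchor_ne <- bond_n_eff(x, vbonds)
  if (anchor_ne > p$n_sat + 4L) return(NULL) # anchor must be a toehold
  inv <- x$strands[[sV]]
  bnd <- bound_positions(x)
  inv_free <- which(!bnd[[sV]])
  inv_free_lab <- vapply(inv_free, function(i) domain_label(inv$domains[[i]]), character(1))
  inc <- x$strands[[sT]]
  ibonds <- which((bonds[, 1L] == sT | bonds[, 3L] == sT))
  removed <- character(); added <- character(); transfers <- 0L
  for (ib in ibonds) {
    rowb <- bonds[ib, ]
    if (rowb[1L] == sT) { di <- rowb[2L]; so <- rowb[3L]; do_ <- rowb[4L] }
    else { di <- rowb[4L]; so <- rowb[1L]; do_ <- rowb[2L] }
    if (so == sV) next # the anchor itself
    lab <- domain_label(inc$domains[[di]])
    j <- match(lab, inv_free_lab)
    if (is.na(j)) next
    vi <- inv_free[j]
    inv_free <- inv_free[-j]; inv_free_lab <- inv_free_lab[-j]
    removed <- c(removed, norm_bond_str(rowb[1L], rowb[2L], rowb[3L], rowb[4L]))
    added <- c(added, norm_bond_str(sV, vi, so, do_))
    bonds[ib, ] <- c(sV, vi, so, do_)
    transfers <- transfers + 1L
  }
  if (transfers == 0L) return(NULL)
  # strip the incumbent's remaining toehold-length bonds (incl. the anchor)
  y <- complex(x$strands, bonds, validate = FALSE)
  keep <- rep(TRUE, nrow(bonds))
  for (ib in seq_len(nrow(bonds))) {
    if (bonds[ib, 1L] != sT && bonds[ib, 3L] != sT) next
    if (bond_n_eff(y, ib) <= p$n_sat + 4L) {
      removed <- c(removed, norm_bond_str(bonds[ib, 1L], bonds[ib, 2L],
                                          bonds[ib, 3L], bonds[ib, 4L]))
      keep[ib] <- FALSE
    }
  }
  bonds <- bonds[keep, , drop = FALSE]
  y <- complex(x$strands, bonds, validate = FALSE)
  list(
    products = split_components(y),
    channel = paste0("tko|", paste(sort(removed), collapse = ","), ">",
                     paste(sort(added), collapse = ","))
  )
}

# unbind moves: list of list(products, n_eff, channel)
unbind_moves <- function(x, p) {
  out <- list()
  nb <- nrow(x$bonds)
  if (nb == 0L) return(out)
  for (i in seq_len(nb)) {
    ne <- bond_n_eff(x, i)
    b <- x$bonds[-i, , drop = FALSE]
    y <- complex(x$strands, b, validate = FALSE)
    comp <- strand_components(y)
    disconnects <- length(x$strands) > 1L && length(unique(comp)) > 1L
    if (ne <= p$n_sat + 4L) {
      if (!disconnects) next # internal fraying rebinds instantly; not enumerated
    } else {
      d1 <- x$strands[[x$bonds[i, 1L]]]$domains[[x$bonds[i, 2L]]]
      if (!(nb == 1L && length(x$strands) == 2L && d1$bridge)) {
        next # long non-bridge bond, or co-anchored neighbours: non-dissociating
      }
    }
    # long solo bridge bond: metastable isolated duplex (u_bridge_solo)
    out[[length(out) + 1L]] <- list(
      products = split_components(y), n_eff = ne,
      channel = paste0("unb|", bond_signature(x, x$bonds[i, ]))
    )
  }
  out
}

# bind moves between complexes x and y
# returns list of list(product, n_eff, loop, teth, channel)
bind_moves <- function(x, y, p, tethered_strands) {
  fx <- free_domains(x); fy <- free_domains(y)
  teth <- (if (complex_tethered(x, tethered_strands)) 1L else 0L) +
          (if (complex_tethered(y, tethered_strands)) 1L else 0L)
  out <- list()
  for (a in fx) {
    if (a$protected) next
    for (b in fy) {
      if (b$protected) next
      if (!domains_complementary(a$d, b$d)) next
      ne <- effective_pair_length(a$d, b$d)
      if (ne <= 0L && p$leak0 <= 0) next # leak channel disabled by default
      prod <- join_complexes(x, y, a$strand_idx, a$domain_idx,
                             b$strand_idx, b$domain_idx)
      out[[length(out) + 1L]] <- list(
        product = prod, n_eff = ne, loop = a$loop || b$loop, teth = teth,
        channel = paste0("bnd|", a$strand_idx, ".", a$domain_idx, "+",
                         b$strand_idx, ".", b$domain_idx, "|", a$label)
      )
    }
  }
  out
}

complex_tethered <- function(x, tethered_strands) {
  if (length(tethered_strands) == 0L) return(FALSE)
  any(vapply(x$strands, function(s) s$name, character(1)) %in% tethered_strands)
}

strand_multiset <- function(x) sort(vapply(x$strands, function(s) s$name, character(1)))

#' Enumerate the reaction network reachable from an initial species set
#'
#' Breadth-first closure of the initial complexes under toehold bind, toehold
#' unbind and migrate-and-release moves (including the anchored-takeover fuel
#' pathways). Complexes exceeding the strand cap are rejected with a warning;
#' the closure is guarded by a species-count cap.
#'
#' @param initial_species List of [complex()] objects.
#' @param p [rate_params()].
#' @param max_strands_per_complex Reject complexes with more strands (>= 2,
#'   default 4; polymer-forming bridges are truncated at the dimer-bridge
#'   level and handled by the assembly module).
#' @param max_species Non-termination guard (default 500).
#' @param tethered_strands Names of origami-tethered strands; every
#'   bimolecular rate picks up one factor `rho` per tethered reactant complex.
#' @return An object of class `dsd_crn` with fields `species` (named list of
#'   complexes by canonical key), `species_tbl` (tibble: `key`, `label`,
#'   `n_strands`, `tethered`), `reactions` (tibble: `kind`, `r1`, `r2`, `p1`,
#'   `p2`, `p3`, `rate`) and `params`.
#' @export
enumerate_crn <- function(initial_species, p = rate_params(),
                          max_strands_per_complex = 4L,
                          max_species = 500L,
                          tethered_strands = character()) {
  if (inherits(initial_species, "dsd_complex")) initial_species <- list(initial_species)
  stopifnot(length(initial_species) >= 1L)
  if (max_strands_per_complex < 2L) {
    stop("max_strands_per_complex must be >= 2", call. = FALSE)
  }
  for (s in initial_species) validate_complex(s)

  registry <- list()   # key -> complex
  processed <- character()
  queue <- character()
  rejected <- character()
  reactions <- list()
  rxn_seen <- character()

  add_species <- function(cx) {
    key <- canonical_key(cx)
    if (is.null(registry[[key]])) {
      if (length(registry) + 1L > max_species) {
        stop("enumeration-overflow: species cap exceeded while adding '",
             species_label(cx), "'", call. = FALSE)
      }
      registry[[key]] <<- cx
      queue <<- c(queue, key)
    }
    key
  }

  add_reaction <- function(kind, rkeys, pkeys, channel,
                           n_eff = NA_integer_, loop = NA, teth = NA_integer_) {
    sig <- paste(kind, paste(sort(rkeys), collapse = "&"),
                 paste(sort(pkeys), collapse = "&"), channel, sep = "||")
    if (sig %in% rxn_seen) return(invisible(NULL))
    rxn_seen <<- c(rxn_seen, sig)
    reactions[[length(reactions) + 1L]] <<- list(
      kind = kind,
      r1 = rkeys[1L], r2 = if (length(rkeys) > 1L) rkeys[2L] else NA_character_,
      p1 = pkeys[1L], p2 = if (length(pkeys) > 1L) pkeys[2L] else NA_character_,
      p3 = if (length(pkeys) > 2L) pkeys[3L] else NA_character_,
      n_eff = as.integer(n_eff), loop = loop, teth = as.integer(teth)
    )
    invisible(NULL)
  }

  for (cx in initial_species) add_species(cx)

  while (length(queue) > 0L) {
    key <- queue[1L]; queue <- queue[-1L]
    x <- registry[[key]]

    # unimolecular: unbind
    for (mv in unbind_moves(x, p)) {
      pkeys <- vapply(mv$products, add_species, character(1))
      add_reaction("unbind", key, pkeys, mv$channel, n_eff = mv$n_eff)
    }
    # unimolecular: migrate / takeover
    for (mv in migration_moves(x, p)) {
      pkeys <- vapply(mv$products, add_species, character(1))
      add_reaction("migrate", key, pkeys, mv$channel)
    }
    # bimolecular: bind against every processed species and itself
    partners <- c(processed, key)
    for (pk in partners) {
      y <- registry[[pk]]
      if (length(x$strands) + length(y$strands) > max_strands_per_complex) {
        lbl <- paste(species_label(x), "+", species_label(y))
        if (!lbl %in% rejected &&
            length(bind_moves(x, y, p, tethered_strands)) > 0L) {
          rejected <- c(rejected, lbl)
          warning("rejected complex beyond strand cap: ", lbl, call. = FALSE)
        }
        next
      }
      for (mv in bind_moves(x, y, p, tethered_strands)) {
        pr <- mv$product
        if (!is_pseudoknot_free(pr)) next
        pkey <- add_species(pr)
        add_reaction("bind", c(key, pk), pkey, paste0(mv$channel, "|", pk),
                     n_eff = mv$n_eff, loop = mv$loop, teth = mv$teth)
      }
    }
    processed <- c(processed, key)
  }

  rx <- dplyr::bind_rows(lapply(reactions, tibble::as_tibble))
  if (nrow(rx) == 0L) {
    rx <- tibble::tibble(kind = character(), r1 = character(), r2 = character(),
                         p1 = character(), p2 = character(), p3 = character(),
                         n_eff = integer(), loop = logical(), teth = integer(),
                         mult = integer(), rate = numeric())
  } else {
    # aggregate parallel channels of the same transformation and rate class
    rx <- rx |>
      dplyr::group_by(.data$kind, .data$r1, .data$r2, .data$p1, .data$p2,
                      .data$p3, .data$n_eff, .data$loop, .data$teth) |>
      dplyr::summarise(mult = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$kind, .data$r1, .data$r2, .data$p1)
    rx$rate <- reaction_rates(rx, p)
  }

  keys <- names(registry)
  labels0 <- vapply(registry, species_label, character(1))
  labels <- labels0
  for (lbl in unique(labels0[duplicated(labels0)])) {
    idx <- which(labels0 == lbl)
    idx <- idx[order(keys[idx])]
    labels[idx] <- c(lbl, paste0(lbl, "#", seq_along(idx[-1]) + 1L))
  }
  sp_tbl <- tibble::tibble(
    key = keys, label = unname(labels),
    n_strands = vapply(registry, function(c) length(c$strands), integer(1)),
    tethered = vapply(registry, complex_tethered, logical(1),
                      tethered_strands = tethered_strands)
  ) |> dplyr::arrange(.data$key)

  structure(
    list(species = registry, species_tbl = sp_tbl, reactions = rx, params = p,
         tethered_strands = tethered_strands),
    class = "dsd_crn"
  )
}

#' @export
print.dsd_crn <- function(x, ...) {
  cat(sprintf("<dsd_crn: %d species, %d reactions>\n",
              length(x$species), nrow(x$reactions)))
  invisible(x)
}

#' Species table of a CRN
#' @param crn A `dsd_crn`.
#' @return Tibble with `key`, `label`, `n_strands`, `tethered`.
#' @export
crn_species <- function(crn) crn$species_tbl

#' Reaction table of a CRN with human-readable labels
#' @param crn A `dsd_crn`.
#' @return Tibble with `kind`, reactant/product labels and `rate` (nM^-1 s^-1
#'   for bimolecular binds, s^-1 otherwise).
#' @export
crn_reactions <- function(crn) {
  lab <- stats::setNames(crn$species_tbl$label, crn$species_tbl$key)
  dplyr::mutate(
    crn$reactions,
    r1 = unname(lab[.data$r1]),
    r2 = ifelse(is.na(.data$r2), NA_character_, unname(lab[.data$r2])),
    p1 = unname(lab[.data$p1]),
    p2 = ifelse(is.na(.data$p2), NA_character_, unname(lab[.data$p2])),
    p3 = ifelse(is.na(.data$p3), NA_character_, unname(lab[.data$p3]))
  )
}

# compute the rate column of a reaction table from its descriptors
reaction_rates <- function(rx, p) {
  rate <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    rate[i] <- switch(rx$kind[i],
      bind = {
        ne <- rx$n_eff[i]
        k <- if (ne <= 0L) p$leak0
             else p$k_max * 10^(-p$sigma * max(0, p$n_sat - ne))
        if (isTRUE(rx$loop[i])) k <- k * p$h
        k * p$rho^rx$teth[i]
      },
      unbind = if (rx$n_eff[i] <= p$n_sat + 4L) p$u0 else p$u_bridge_solo,
      migrate = p$k_migrate
    )
  }
  rate * rx$mult
}

#' Recompute reaction rates of a CRN under new rate parameters
#'
#' The enumerated network structure is parameter-independent (the cutoff
#' between toehold-length and non-dissociating bonds uses the default
#' `n_sat`); the rate constants are recomputed from the stored per-reaction
#' descriptors. Used heavily by the calibration stages.
#'
#' @param crn A `dsd_crn`.
#' @param p New [rate_params()].
#' @return The CRN with updated `reactions$rate` and `params`.
#' @export
update_rates <- function(crn, p) {
  stopifnot(inherits(crn, "dsd_crn"), inherits(p, "dsd_rate_params"))
  crn$reactions$rate <- reaction_rates(crn$reactions, p)
  crn$params <- p
  crn
}

.crn_cache <- new.env(parent = emptyenv())

#' Enumerate (with caching) the CRN of a circuit
#'
#' Convenience wrapper: enumerates the reaction network of a built circuit,
#' caching the (parameter-independent) network structure per species set so
#' repeated calls with different rate parameters are cheap.
#'
#' @param circuit A `dsd_circuit` from [build_circuit()] or a preset name.
#' @param p [rate_params()].
#' @return A `dsd_crn` with rates computed under `p`.
#' @export
circuit_crn <- function(circuit, p = rate_params()) {
  if (is.character(circuit) || inherits(circuit, "dsd_circuit_config")) {
    circuit <- build_circuit(circuit)
  }
  key <- paste(c(sort(names(circuit$species)), circuit$tethered_strands),
               collapse = "&")
  crn <- .crn_cache[[key]]
  if (is.null(crn)) {
    crn <- suppressWarnings(enumerate_crn(
      unname(circuit$species), rate_params(),
      tethered_strands = circuit$tethered_strands
    ))
    .crn_cache[[key]] <- crn
  }
  update_rates(crn, p)
}

#' Check strand conservation of every reaction
#'
#' @param crn A `dsd_crn`.
#' @return Logical vector, one entry per reaction: does the strand multiset of
#'   the reactants equal that of the products?
#' @export
crn_conserved <- function(crn) {
  ms <- lapply(crn$species, strand_multiset)
  apply(crn$reactions, 1L, function(r) {
    rs <- sort(c(ms[[r[["r1"]]]], if (!is.na(r[["r2"]])) ms[[r[["r2"]]]]))
    ps <- sort(c(ms[[r[["p1"]]]],
                 if (!is.na(r[["p2"]])) ms[[r[["p2"]]]],
                 if (!is.na(r[["p3"]])) ms[[r[["p3"]]]]))
    identical(rs, ps)
  })
}
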