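# Shared fixtures: tiny toy strand systems and random-complex generators.

# two-strand toy: A = [t, x], B = [t*, x*] (t an 8-nb toehold, x a 16-nb core)
toy_pair <- function() {
  t_d <- domain("t", 8L)
  x_d <- domain("x", 16L)
  list(
    A = strand("A", list(t_d, x_d)),
    B = strand("B", list(complement(t_d), complement(x_d)))
  )
}

# toy CRN capped at two-strand complexes (the dimer universe of toy_pair);
# larger aggregates are outside the scope of these fixtures
toy_crn <- function(p = rate_params()) {
  tp <- toy_pair()
  suppressWarnings(enumerate_crn(
    list(complex(list(tp$A)), complex(list(tp$B))), p,
    max_strands_per_complex = 2L
  ))
}

# single-channel association fixture: one long complementary domain pair,
# so the only reaction is the irreversible bimolecular bind at k_max
pair_crn <- function(p = rate_params()) {
  x_d <- domain("x", 16L)
  A <- strand("A", list(x_d))
  B <- strand("B", list(complement(x_d)))
  enumerate_crn(list(complex(list(A)), complex(list(B))), p)
}

# small strand pool for random complex generation
random_strand_pool <- function() {
  da <- domain("a", 8L); db <- domain("b", 16L); dc <- domain("c", 7L)
  list(
    P = strand("P", list(da, db)),
    Q = strand("Q", list(complement(da), complement(db), dc)),
    R = strand("R", list(complement(dc), da)),
    S = strand("S", list(complement(da)))
  )
}

# build a random valid complex by sequential attachment at free
# complementary domain pairs (guarantees connectivity and validity)
random_complex <- function(pool, n_strands = 2L) {
  repeat {
    picks <- sample(names(pool), n_strands, replace = TRUE)
    cx <- complex(list(pool[[picks[1L]]]), validate = FALSE)
    ok <- TRUE
    for (k in seq_len(n_strands - 1L)) {
      nxt <- complex(list(pool[[picks[k + 1L]]]), validate = FALSE)
      fx <- dsdfibril:::free_domains(cx)
      fy <- dsdfibril:::free_domains(nxt)
      cand <- list()
      for (a in fx) for (b in fy) {
        if (dsdfibril:::domains_complementary(a$d, b$d)) {
          cand[[length(cand) + 1L]] <- list(a = a, b = b)
        }
      }
      if (length(cand) == 0L) { ok <- FALSE; break }
      ch <- cand[[sample.int(length(cand), 1L)]]
      cx <- dsdfibril:::join_complexes(cx, nxt, ch$a$strand_idx, ch$a$domain_idx,
                                       ch$b$strand_idx, ch$b$domain_idx)
    }
    if (ok) return(cx)
  }
}

# independent brute-force isomorphism oracle: exists a strand bijection
# (same names) mapping one bond set exactly onto the other
complexes_isomorphic <- function(x, y) {
  nx <- vapply(x$strands, function(s) s$name, character(1))
  ny <- vapply(y$strands, function(s) s$name, character(1))
  if (length(nx) != length(ny) || !identical(sort(nx), sort(ny))) return(FALSE)
  bond_set <- function(cx, perm) {
    b <- cx$bonds
    if (nrow(b) == 0L) return(character())
    s1 <- perm[b[, 1L]]; s2 <- perm[b[, 3L]]
    swap <- s1 > s2 | (s1 == s2 & b[, 2L] > b[, 4L])
    a1 <- ifelse(swap, s2, s1); d1 <- ifelse(swap, b[, 4L], b[, 2L])
    a2 <- ifelse(swap, s1, s2); d2 <- ifelse(swap, b[, 2L], b[, 4L])
    sort(paste(a1, d1, a2, d2))
  }
  target <- bond_set(y, seq_along(ny))
  perms <- dsdfibril:::all_permutations(length(nx))
  for (p in perms) {
    # p maps position i of x to position p[i]; names must match
    if (!identical(nx, ny[p])) next
    inv <- integer(length(p)); inv[p] <- seq_along(p)
    # strand i of x corresponds to strand p[i] of y
    if (identical(bond_set(x, p), target)) return(TRUE)
  }
  FALSE
}

# preset gate complexes for reuse in tests
gate_complexes <- function() dsdfibril:::circuit_species()
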