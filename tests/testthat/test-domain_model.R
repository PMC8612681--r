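test_that("complement is an involution and preserves fields", {
  d5 <- domain("5", 8L)
  expect_equal(domain_label(complement(d5)), "5*")
  expect_equal(complement(d5)$length_nb, 8L)
  expect_identical(complement(complement(d5)), d5)
  # mismatched variant keeps its mismatch count under complementation
  d6p <- domain("6", 8L, mismatch_nb = 4L)
  expect_equal(domain_label(d6p), "6'")
  expect_equal(complement(d6p)$mismatch_nb, 4L)
})

test_that("domain and strand constructors enforce invariants", {
  expect_error(domain("z", 0L), "length_nb")
  expect_error(domain("z", 4L, mismatch_nb = 5L), "mismatch_nb")
  expect_error(strand("s", list(domain("a", 5L)), labels = "GFP"), "labels")
  expect_error(
    strand("s", list(domain("a", 5L)),
           hairpins = list(hairpin("b", "a"))),
    "absent from strand"
  )
  expect_error(hairpin("a", "b", loop = "c"), "subset")
})

test_that("the packaged strand library regenerates the printed toehold lengths", {
  lib <- dsd_strands()
  len_of <- function(strand, lbl) {
    labs <- vapply(strand$domains, domain_label, character(1))
    strand$domains[[match(lbl, labs)]]$length_nb
  }
  expect_equal(len_of(lib$c1, "1"), 9L)
  expect_equal(len_of(lib$c1, "5"), 8L)
  expect_equal(len_of(lib$activator, "10"), 7L)
  expect_equal(len_of(lib$threshold, "6"), 8L)
  d6p <- lib$c2$domains[[1L]]
  expect_equal(d6p$length_nb, 8L)
  expect_equal(d6p$mismatch_nb, 4L)
  expect_equal(effective_toehold_length(d6p), 4L)
})

test_that("complex validation rejects malformed structures", {
  tp <- toy_pair()
  expect_error(complex(list(tp$A, tp$B), rbind(c(1L, 1L, 2L, 2L))),
               "not complementary")
  expect_error(complex(list(tp$A, tp$B), rbind(c(1L, 1L, 2L, 1L),
                                               c(1L, 1L, 2L, 1L))),
               "more than one bond")
  expect_error(complex(list(tp$A, tp$B)), "not connected")
  expect_error(complex(list(tp$A, tp$B), rbind(c(1L, 3L, 2L, 1L))),
               "outside its strand")
})

test_that("canonical keys are invariant to strand listing order", {
  tp <- toy_pair()
  c1 <- complex(list(tp$A, tp$B), rbind(c(1L, 1L, 2L, 1L)))
  c2 <- complex(list(tp$B, tp$A), rbind(c(2L, 1L, 1L, 1L)))
  expect_identical(canonical_key(c1), canonical_key(c2))
  # different bond structure -> different key
  c3 <- complex(list(tp$A, tp$B), rbind(c(1L, 2L, 2L, 2L)))
  expect_false(identical(canonical_key(c1), canonical_key(c3)))
  # idempotent under repetition
  expect_identical(canonical_key(c1), canonical_key(c1))
})

test_that("canonical keys agree with a brute-force isomorphism oracle", {
  set.seed(42)
  pool <- random_strand_pool()
  cxs <- lapply(1:200, function(i) random_complex(pool, sample(2:3, 1L)))
  keys <- vapply(cxs, canonical_key, character(1))
  # key equality must coincide with graph isomorphism on every pair
  for (i in seq_len(60)) {
    a <- sample(200, 1L); b <- sample(200, 1L)
    expect_equal(keys[a] == keys[b], complexes_isomorphic(cxs[[a]], cxs[[b]]),
                 info = sprintf("pair %d/%d", a, b))
  }
  # shuffled copies must collide with their originals
  for (i in sample(200, 25)) {
    cx <- cxs[[i]]
    p <- sample(length(cx$strands))
    inv <- integer(length(p)); inv[p] <- seq_along(p)
    b <- cx$bonds
    if (nrow(b) > 0L) { b[, 1L] <- inv[b[, 1L]]; b[, 3L] <- inv[b[, 3L]] }
    shuf <- complex(cx$strands[p], b, validate = FALSE)
    expect_identical(canonical_key(shuf), keys[i])
  }
})

test_that("free_toeholds reports entry points and hairpin protection", {
  gates <- gate_complexes()
  ft <- free_toeholds(gates[["activator/c1"]])
  # toehold 5 is a listed free entry point on the resting cylinder gate
  expect_true("5" %in% ft$domain[!ft$protected])
  expect_true("1" %in% ft$domain[!ft$protected])
  # the activator's loop-presented 6* is protected while the gate holds it
  expect_true(all(ft$protected[ft$domain == "6*"]))
  # activator bound on c2 exposes toehold 10
  lib <- dsd_strands()
  c2_act <- complex(list(lib$c2, lib$activator),
                    rbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 3L)))
  ft2 <- free_toeholds(c2_act)
  expect_true("10" %in% ft2$domain[!ft2$protected])
  # a fully paired duplex has no free toeholds
  tp <- toy_pair()
  dup <- complex(list(tp$A, tp$B), rbind(c(1L, 1L, 2L, 1L), c(1L, 2L, 2L, 2L)))
  expect_equal(nrow(free_toeholds(dup)), 0L)
})
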