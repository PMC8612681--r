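test_that("toy two-strand system matches the hand-written oracle CRN", {
  p <- rate_params()
  crn <- toy_crn(p)
  # oracle (dimer universe): A, B, A/B bound at t, A/B bound at x, full duplex
  expect_equal(length(crn$species), 5L)
  rx <- crn_reactions(crn)
  expect_equal(sum(rx$kind == "bind"), 2L)    # two entry bonds
  expect_equal(sum(rx$kind == "migrate"), 2L) # zip from either anchor
  expect_equal(sum(rx$kind == "unbind"), 1L)  # only the toehold bond releases
  # rates: toehold entry at k_max (8 nb saturated), zip at k_migrate,
  # release at u0
  expect_setequal(rx$rate[rx$kind == "bind"], p$k_max)
  expect_setequal(rx$rate[rx$kind == "migrate"], p$k_migrate)
  expect_equal(rx$rate[rx$kind == "unbind"], p$u0)
})

test_that("enumeration is deterministic and conserves strands", {
  circ <- build_circuit("freestrand-160")
  # strand-cap rejections along the closure are expected and logged
  crn1 <- suppressWarnings(enumerate_crn(unname(circ$species)))
  crn2 <- suppressWarnings(enumerate_crn(unname(circ$species)))
  expect_identical(crn1$reactions, crn2$reactions)
  expect_identical(names(crn1$species), names(crn2$species))
  expect_true(all(crn_conserved(crn1)))
})

test_that("the basic module CRN contains the three headline pathways", {
  crn <- circuit_crn("freestrand-160")
  rx <- crn_reactions(crn)
  binds <- rx[rx$kind == "bind", ]
  pair <- function(a, b) any((binds$r1 == a & binds$r2 == b) |
                             (binds$r1 == b & binds$r2 == a))
  # (i) input invades the cylinder gate
  expect_true(pair("input", "activator/c1"))
  # (ii) released activator invades the cuboid gate
  expect_true(pair("activator", "c2/inhibitor"))
  # (iii) released inhibitor attacks the bright cylinder complex
  expect_true(pair("inhibitor", "c1/c1s/input"))
  # feedback completion: some migrate reaction yields the final c1/inhibitor
  migs <- rx[rx$kind == "migrate", ]
  expect_true(any(migs$p1 == "c1/inhibitor" | migs$p2 == "c1/inhibitor" |
                    (!is.na(migs$p3) & migs$p3 == "c1/inhibitor")))
})

test_that("without input the initial species are a leak-free closure", {
  gates <- gate_complexes()
  crn <- enumerate_crn(unname(gates[c("activator/c1", "c1s",
                                      "c2/inhibitor", "c2s")]))
  expect_equal(length(crn$species), 4L)
  expect_equal(nrow(crn$reactions), 0L)
})

test_that("apply_migration releases the activator from an anchored invasion", {
  lib <- dsd_strands()
  cx <- complex(
    list(lib$c1, lib$activator, lib$input),
    rbind(c(1L, 2L, 2L, 1L),  # c1:2 - activator:2*
          c(1L, 3L, 3L, 3L))  # c1:5 - input:5* (the anchor)
  )
  moves <- apply_migration(cx, 2L)
  expect_false(is.null(moves))
  prods <- moves[[1L]]
  expect_equal(length(prods), 2L)
  labs <- sort(vapply(prods, species_label, character(1)))
  expect_equal(labs, c("activator", "c1/input"))
})

test_that("fuel B takeover splits the cuboid bridge and strands the activator", {
  lib <- dsd_strands()
  cx <- complex(
    list(lib$c2, lib$c2s, lib$activator, lib$fuelB),
    rbind(c(1L, 1L, 3L, 2L),  # c2:6' - activator:6*
          c(1L, 2L, 3L, 3L),  # c2:7  - activator:7*
          c(2L, 1L, 3L, 4L),  # c2*:8 - activator:8*
          c(3L, 5L, 4L, 1L))  # activator:10 - fuelB:10* (anchor)
  )
  moves <- apply_migration(cx, 4L)
  expect_false(is.null(moves))
  labs <- sort(vapply(moves[[1L]], species_label, character(1)))
  expect_equal(labs, c("activator/c2s", "c2/fuelB"))
})

test_that("an anchor with no migratable neighbour is a no-op", {
  tp <- toy_pair()
  full <- complex(list(tp$A, tp$B),
                  rbind(c(1L, 1L, 2L, 1L), c(1L, 2L, 2L, 2L)))
  expect_null(apply_migration(full, 1L))
  expect_error(apply_migration(full, 5L), "not a bond")
})

test_that("complexes beyond the strand cap are rejected with a warning", {
  circ <- build_circuit("freestrand-160")
  w <- testthat::capture_warnings(
    enumerate_crn(unname(circ$species), max_strands_per_complex = 2L)
  )
  expect_true(any(grepl("strand cap", w)))
})

test_that("the fuel A pathway replaces the bridge in a single migrate step", {
  crn <- circuit_crn("origami-fuelA")
  rx <- crn_reactions(crn)
  migs <- rx[rx$kind == "migrate", ]
  # c2/c2*/activator + fuelA (anchored) -> c2/c2*/fuelA + free activator
  hit <- migs[grepl("activator/c2/c2s/fuelA", migs$r1) &
                ((migs$p1 == "c2/c2s/fuelA" & migs$p2 == "activator") |
                 (migs$p2 == "c2/c2s/fuelA" & migs$p1 == "activator")), ]
  expect_gte(nrow(hit), 1L)
})
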