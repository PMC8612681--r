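flat_arming <- function(a, d = 0, duration_s = 18 * 3600, n = 200L) {
  tt <- c(0, exp(seq(log(1), log(duration_s), length.out = n)))
  tibble::tibble(time_s = tt, a = rep(a, length(tt)), d = rep(d, length(tt)))
}

cyl_spec <- function(conc = 10) {
  monomer_spec("cylinder", 16L, conc, "c1", "input", "inhibitor",
               initial_dimer_frac = 0)
}

test_that("unarmed monomers never polymerize", {
  fib <- simulate_assembly(flat_arming(0), cyl_spec(),
                           assembly_params(n_monomers_sim = 500L), seed = 1L)
  expect_true(all(fib$length == 1L))
  expect_true(all(tapply(fib$count, fib$time_h, sum) == 500))
})

test_that("monomers are conserved exactly at every checkpoint", {
  fib <- simulate_assembly(flat_arming(1), cyl_spec(),
                           assembly_params(n_monomers_sim = 1000L), seed = 2L)
  totals <- tapply(fib$length * fib$count, fib$time_h, sum)
  expect_true(all(totals == 1000))
})

test_that("assembly replicates are reproducible per seed", {
  ap <- assembly_params(n_monomers_sim = 500L)
  f1 <- simulate_assembly(flat_arming(1), cyl_spec(), ap, seed = 11L)
  f2 <- simulate_assembly(flat_arming(1), cyl_spec(), ap, seed = 11L)
  f3 <- simulate_assembly(flat_arming(1), cyl_spec(), ap, seed = 12L)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("irreversible constant-kernel growth matches the closed-form Xn", {
  # gamma = 0, a = 1, no scission: mean-field cluster count follows
  # dF/dt = -k_join F^2 / 2, so Xn(t) = 1 + k_bond c t / 2
  kb <- 2e-3; conc <- 10; N <- 2000L
  ap <- assembly_params(k_bond = kb, gamma = 0, k_break = 0, k_frag0 = 0,
                        n_monomers_sim = N)
  checks <- c(1, 2, 4)
  xn <- sapply(1:8, function(sd) {
    fib <- simulate_assembly(flat_arming(1), cyl_spec(conc), ap,
                             checkpoints_h = checks, seed = sd)
    tapply(fib$length * fib$count, fib$time_h, sum) /
      tapply(fib$count, fib$time_h, sum)
  })
  xn_mean <- rowMeans(xn)
  xn_se <- apply(xn, 1L, stats::sd) / sqrt(ncol(xn))
  expected <- 1 + kb * conc * checks * 3600 / 2
  # within Monte-Carlo error plus a small finite-size allowance
  expect_true(all(abs(xn_mean - expected) <= 3 * xn_se + 0.03 * expected))
})

test_that("the irreversible length distribution is Flory most-probable", {
  # stop at moderate conversion (Xn ~ 3) so the low-L bins carry good counts
  ap <- assembly_params(k_bond = 2e-3, gamma = 0, k_break = 0, k_frag0 = 0,
                        n_monomers_sim = 4000L)
  fib <- simulate_assembly(flat_arming(1, duration_s = 200), cyl_spec(), ap,
                           checkpoints_h = 200 / 3600, seed = 5L)
  xn <- sum(fib$length * fib$count) / sum(fib$count)
  p <- 1 - 1 / xn
  # number fraction of L-mers is (1-p) p^(L-1); check the first three
  nf <- fib$count / sum(fib$count)
  for (L in 1:3) {
    expect_equal(nf[fib$length == L], (1 - p) * p^(L - 1), tolerance = 0.15)
  }
})

test_that("scission with a disarm hazard depolymerizes fibrils", {
  ap <- assembly_params(k_bond = 2e-3, k_break = 1, k_frag0 = 0,
                        n_monomers_sim = 1000L)
  grow <- flat_arming(1, d = 0, duration_s = 2 * 3600)
  shrink <- flat_arming(0.02, d = 5e-3, duration_s = 2 * 3600)
  arming <- dplyr::bind_rows(
    grow,
    dplyr::mutate(shrink, time_s = time_s + max(grow$time_s))
  )
  fib <- simulate_assembly(arming, cyl_spec(), ap,
                           checkpoints_h = c(2, 4), seed = 9L)
  xn <- tapply(fib$length * fib$count, fib$time_h, sum) /
    tapply(fib$count, fib$time_h, sum)
  expect_gt(xn[["2"]], 2)
  expect_lt(xn[["4"]], 1.2)
})

test_that("arming traces capture activation and feedback of both species", {
  circ <- build_circuit("origami-basic-10")
  crn <- circuit_crn(circ)
  tc <- simulate_ode(crn, circ$conc)
  specs <- monomer_specs(circ)
  acyl <- arming_trace(tc, specs$cylinder, crn)
  acub <- arming_trace(tc, specs$cuboid, crn)
  # before input acts nothing is armed
  expect_equal(acyl$a[1L], 0)
  expect_equal(acub$a[1L], 0)
  expect_true(all(acyl$a >= 0 & acyl$a <= 1))
  # cylinders arm transiently (rise then fall); cuboids arm monotonically
  expect_gt(max(acyl$a), 0.5)
  expect_lt(acyl$a[nrow(acyl)], 0.2)
  i2h <- findInterval(2 * 3600, acub$time_s)
  expect_gt(acub$a[nrow(acub)], acub$a[i2h] - 1e-9)
  # during the feedback phase only cylinders see a sustained disarm hazard
  i2 <- findInterval(2 * 3600, acyl$time_s)
  expect_gt(acyl$d[i2], 5 * acub$d[i2])
  expect_error(arming_trace(tc, monomer_spec("cuboid", 16L, 10, "zz", "a", "b"),
                            crn), "absent")
})

test_that("self-sorting is structural: no mixed fibrils are ever produced", {
  fib <- simulate_fibrils("origami-basic-10", seeds = 1:2,
                          params = assembly_params(n_monomers_sim = 500L))
  expect_setequal(unique(fib$species), c("cylinder", "cuboid"))
  # per-species monomer totals conserved independently
  tot <- fib |>
    dplyr::group_by(species, seed, time_h) |>
    dplyr::summarise(n = sum(length * count), .groups = "drop")
  expect_true(all(tot$n == 500))
})

test_that("cuboids start with the base-stacking dimer fraction", {
  circ <- build_circuit("origami-basic-10")
  specs <- monomer_specs(circ)
  expect_equal(specs$cuboid$initial_dimer_frac, 0.1)
  expect_equal(specs$cylinder$initial_dimer_frac, 0)
  fib <- simulate_assembly(flat_arming(0), specs$cuboid,
                           assembly_params(n_monomers_sim = 1000L), seed = 1L)
  at0 <- fib[fib$time_h == 0, ]
  expect_equal(at0$count[at0$length == 2L], 50L)
})
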