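test_that("ODE matches the pseudo-first-order closed form", {
  # A + B -> AB with B in large excess: [A](t) = A0 exp(-k [B] t)
  crn <- pair_crn()
  k <- rate_params()$k_max
  B0 <- 50; A0 <- 0.1 # 500-fold excess
  tc <- simulate_ode(crn, c(A = A0, B = B0), duration_h = 0.05)
  # exact irreversible second-order solution; its B >> A limit is the
  # pseudo-first-order exponential
  exact <- A0 * (B0 - A0) / (B0 * exp(k * (B0 - A0) * tc$time_s) - A0)
  expect_lt(max(abs(tc$A - exact) / exact), 1e-5)
  # the exponential limit agrees to the B-depletion error, A0/B0 ~ 0.2%
  expect_lt(max(abs(tc$A - A0 * exp(-k * B0 * tc$time_s)) / exact), 0.02)
})

test_that("strand totals are conserved along ODE trajectories", {
  circ <- build_circuit("freestrand-160")
  crn <- circuit_crn(circ)
  tc <- simulate_ode(crn, circ$conc)
  st <- strand_totals(tc)
  tot <- as.matrix(st[, -1L])
  resid <- max(abs(sweep(tot, 2L, tot[1L, ], "-")) / tot[1L, ])
  expect_lt(resid, 1e-6)
})

test_that("without input every trajectory is flat over 18 h", {
  circ <- build_circuit("freestrand-160-noinput")
  crn <- circuit_crn(circ)
  tc <- simulate_ode(crn, circ$conc)
  conc <- as.matrix(tc[, -1L])
  expect_lt(max(abs(sweep(conc, 2L, conc[1L, ], "-"))), 1e-9)
})

test_that("SSA trajectories are reproducible per seed and differ across seeds", {
  crn <- toy_crn()
  t1 <- simulate_ssa(crn, c(A = 10, B = 10), duration_h = 0.5, seed = 7L)
  t2 <- simulate_ssa(crn, c(A = 10, B = 10), duration_h = 0.5, seed = 7L)
  t3 <- simulate_ssa(crn, c(A = 10, B = 10), duration_h = 0.5, seed = 8L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("a single A+B pair fires exactly once and terminates cleanly", {
  # irreversible duplex formation from one copy of each strand
  crn <- pair_crn()
  tc <- simulate_ssa(crn, c(A = 1, B = 1), duration_h = 18,
                     volume_scale = 1, seed = 3L)
  final <- as.numeric(tc[nrow(tc), -1L])
  names(final) <- names(tc)[-1L]
  expect_equal(unname(final[["A"]]), 0)
  expect_equal(unname(final[["B"]]), 0)
  expect_equal(sum(final), 1) # exactly one duplex, zipped or not
  # integer copy conservation at every recorded point
  st <- strand_totals(tc)
  expect_true(all(st$A == 1 & st$B == 1))
})

test_that("doubling concentrations sharpens and shrinks the Cy5 transient", {
  c160 <- build_circuit("freestrand-160")
  c320 <- build_circuit("freestrand-320")
  crn <- circuit_crn(c160)
  f160 <- fluorescence_trace(simulate_ode(crn, c160$conc), "Cy5", crn = crn)
  f320 <- fluorescence_trace(simulate_ode(crn, c320$conc), "Cy5", crn = crn)
  expect_lt(peak_time(f320), peak_time(f160))
  expect_lt(max(f320$f), max(f160$f))
  # and the Cy3 rise is faster
  f3_160 <- fluorescence_trace(simulate_ode(crn, c160$conc), "Cy3", crn = crn)
  f3_320 <- fluorescence_trace(simulate_ode(crn, c320$conc), "Cy3", crn = crn)
  i30 <- findInterval(1800, f3_160$time_s)
  expect_gt(f3_320$f[i30], f3_160$f[i30])
})

test_that("ODE concentrations stay non-negative", {
  circ <- build_circuit("origami-fuelB-480")
  crn <- circuit_crn(circ)
  tc <- simulate_ode(crn, circ$conc)
  expect_gte(min(as.matrix(tc[, -1L])), 0)
})
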