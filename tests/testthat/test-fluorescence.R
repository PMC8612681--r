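test_that("both channels start dark and the reference state is 1", {
  circ <- build_circuit("freestrand-160")
  crn <- circuit_crn(circ)
  tc <- simulate_ode(crn, circ$conc)
  f5 <- fluorescence_trace(tc, "Cy5", crn = crn)
  f3 <- fluorescence_trace(tc, "Cy3", crn = crn)
  # all fluorophores quencher-paired at t = 0
  expect_equal(f5$f[1L], 0)
  expect_equal(f3$f[1L], 0)
  # reference states: all Cy5 as c1/c1*/input, all Cy3 as c2/c2*/activator
  ref5 <- tc[1L, ]; ref5[, -1L] <- 0; ref5[["c1/c1s/input"]] <- 160
  ref3 <- tc[1L, ]; ref3[, -1L] <- 0; ref3[["activator/c2/c2s"]] <- 160
  mk <- function(row) {
    out <- dplyr::bind_rows(row, row); out$time_s <- c(0, 1)
    attr(out, "meta") <- attr(tc, "meta")
    out
  }
  expect_equal(fluorescence_trace(mk(ref5), "Cy5", crn = crn)$f, c(1, 1))
  expect_equal(fluorescence_trace(mk(ref3), "Cy3", crn = crn)$f, c(1, 1))
})

test_that("fluorescence stays within [0, 1] under default brightness", {
  for (nm in c("freestrand-160", "freestrand-threshold-fuelB")) {
    circ <- build_circuit(nm)
    crn <- circuit_crn(circ)
    tc <- simulate_ode(crn, circ$conc, duration_h = 6)
    for (ch in c("Cy3", "Cy5")) {
      f <- fluorescence_trace(tc, ch, crn = crn)$f
      expect_gte(min(f), 0); expect_lte(max(f), 1 + 1e-9)
    }
  }
})

test_that("the brightness map applies quencher and context rules", {
  crn <- circuit_crn("origami-fuelA")
  bm_free <- brightness_map(crn, origami_mode = FALSE)
  bm_og <- brightness_map(crn, origami_mode = TRUE)
  b_of <- function(bm, lbl, ch) bm$b[bm$label == lbl & bm$channel == ch]
  # quencher-bearing complexes are dark
  expect_equal(b_of(bm_free, "activator/c1", "Cy5"), 0)
  expect_equal(b_of(bm_free, "c2/inhibitor", "Cy3"), 0)
  # activator-bound cuboid species stay bright (free strands)...
  expect_equal(b_of(bm_free, "activator/c2/c2s", "Cy3"), 1)
  # ...but carry the origami context factor on the full bridge triplex
  expect_equal(b_of(bm_og, "activator/c2/c2s", "Cy3"), 0.8)
  # fuel A triplex context quenching
  expect_equal(b_of(bm_og, "c2/c2s/fuelA", "Cy3"), 0.8)
  # unquenched cylinder complexes are bright
  expect_equal(b_of(bm_free, "c1/c1s/input", "Cy5"), 1)
})

test_that("a missing channel raises a configuration error", {
  crn <- toy_crn()
  tc <- simulate_ode(crn, c(A = 1, B = 1), duration_h = 0.01)
  expect_error(fluorescence_trace(tc, "Cy3", crn = crn), "absent")
})

test_that("peak_time and completion_time behave on synthetic traces", {
  tt <- seq(0, 100, by = 1)
  rising <- tibble::tibble(time_s = tt, f = tt / 100)
  expect_equal(peak_time(rising), 100)
  triangle <- tibble::tibble(time_s = tt, f = c(0:50, 49:0) / 50)
  expect_equal(peak_time(triangle), 50)
  # exponential approach: enters the 10% band of its final value at -log(0.1)/k
  expo <- tibble::tibble(time_s = tt, f = 1 - exp(-0.1 * tt))
  expect_equal(completion_time(expo, 0.10), ceiling(log(10) / 0.1), tolerance = 0.05)
  # a constant trace is complete from the start
  flat <- tibble::tibble(time_s = tt, f = rep(2, length(tt)))
  expect_equal(completion_time(flat, 0.10), 0)
  expect_error(peak_time(tibble::tibble(time_s = numeric(), f = numeric())),
               "empty")
})

test_that("fuel B lifts the Cy3 signal out of the triplex context quench", {
  circ <- build_circuit("origami-fuelB-480")
  crn <- circuit_crn(circ)
  # the fuel B end species carries neither quencher nor a bridge triplex:
  # full brightness, unlike the 0.8-context activator triplex
  bm <- brightness_map(crn, origami_mode = TRUE)
  expect_equal(bm$b[bm$label == "c2/fuelB" & bm$channel == "Cy3"], 1)
  tc <- simulate_ode(crn, circ$conc)
  f3 <- fluorescence_trace(tc, "Cy3", crn = crn, origami_mode = TRUE)
  # endpoint exceeds the context-quenched ceiling of the fuel-free circuit
  cb <- build_circuit("origami-basic-10")
  crn_b <- circuit_crn(cb)
  f3_b <- fluorescence_trace(simulate_ode(crn_b, cb$conc), "Cy3",
                             crn = crn_b, origami_mode = TRUE)
  expect_gt(f3$f[nrow(f3)], f3_b$f[nrow(f3_b)])
  expect_gt(f3$f[nrow(f3)], 0.8)
})
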