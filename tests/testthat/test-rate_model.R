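test_that("effective toehold length subtracts mismatches and floors at zero", {
  expect_equal(effective_toehold_length(domain("6", 8L, mismatch_nb = 4L)), 4L)
  expect_equal(effective_toehold_length(domain("6", 8L)), 8L)
  expect_equal(effective_toehold_length(domain("z", 5L, mismatch_nb = 5L)), 0L)
})

test_that("binding rate follows the saturating mismatch-discount model", {
  p <- rate_params()
  d8 <- domain("a", 8L)
  # saturated above n_sat
  expect_equal(binding_rate(d8, p), p$k_max)
  # a 4-nb effective toehold is 10^(-sigma*2) slower than a saturated one
  r4 <- binding_rate(d8, p, n_eff = 4L)
  expect_equal(r4 / binding_rate(d8, p, n_eff = 8L), 10^(-p$sigma * 2))
  # zero effective length is the (default-disabled) leak channel
  expect_equal(binding_rate(d8, p, n_eff = 0L), 0)
  # context factors multiply
  expect_equal(binding_rate(d8, p, loop = TRUE), p$k_max * p$h)
  expect_equal(binding_rate(d8, p, tethered_partners = 2L), p$k_max * p$rho^2)
})

test_that("binding rate is monotone in n_eff and constant above saturation", {
  p <- rate_params()
  d <- domain("a", 10L)
  rates <- vapply(1:10, function(n) binding_rate(d, p, n_eff = n), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[p$n_sat:10 - 0], rep(p$k_max, 11 - p$n_sat),
               tolerance = 1e-12)
})

test_that("unbinding uses the standard rate with the long-domain cutoff", {
  p <- rate_params()
  expect_equal(unbinding_rate(domain("5", 8L), p), 0.012)
  expect_equal(unbinding_rate(domain("9", 16L), p), 0)
  # user override passes through
  expect_equal(unbinding_rate(domain("5", 8L), rate_params(u0 = 0.05)), 0.05)
})

test_that("rho = 1, h = 1 recovers the free-strand rate set exactly", {
  p1 <- rate_params(h = 1, rho = 1)
  circ_free <- build_circuit("freestrand-160")
  circ_og <- build_circuit("origami-basic-10")
  # strand-cap rejections along the closure are expected and logged
  crn_free <- suppressWarnings(enumerate_crn(unname(circ_free$species), p1))
  crn_og <- suppressWarnings(enumerate_crn(
    unname(circ_og$species), p1, tethered_strands = circ_og$tethered_strands))
  # same network (same initial strands), bitwise-identical rate vectors
  expect_identical(crn_free$reactions$rate, crn_og$reactions$rate)
})
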