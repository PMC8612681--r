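test_that("number-average degree of polymerization is the weighted mean", {
  expect_equal(number_average_length(tibble::tibble(length = 1L, count = 10)), 1)
  expect_equal(
    number_average_length(tibble::tibble(length = c(1L, 2L), count = c(2, 1))),
    4 / 3
  )
  # invariant under uniform count scaling
  d <- tibble::tibble(length = c(1L, 3L, 7L), count = c(5, 2, 1))
  expect_equal(number_average_length(d),
               number_average_length(dplyr::mutate(d, count = count * 37)))
  expect_gte(number_average_length(d), 1)
  expect_error(number_average_length(tibble::tibble(length = integer(),
                                                    count = numeric())),
               "empty")
})

test_that("histogram normalization scales the mode to exactly 100", {
  d <- tibble::tibble(length = c(1L, 2L), count = c(50, 25))
  n1 <- normalize_histogram(d)
  expect_equal(n1$count, c(100, 50))
  # idempotent
  expect_equal(normalize_histogram(n1), n1)
  # uniform counts all map to 100
  u <- normalize_histogram(tibble::tibble(length = 1:4, count = rep(7, 4)))
  expect_true(all(u$count == 100))
  # contract: the maximum is exactly 100 for any distribution
  set.seed(1)
  r <- tibble::tibble(length = 1:10, count = runif(10, 0.1, 9))
  expect_equal(max(normalize_histogram(r)$count), 100)
})

test_that("max_length returns the largest populated length", {
  expect_equal(max_length(tibble::tibble(length = c(1L, 7L), count = c(3, 1))), 7L)
  expect_equal(max_length(tibble::tibble(length = 1L, count = 5)), 1L)
  expect_equal(max_length(tibble::tibble(length = c(1L, 9L), count = c(3, 0))), 1L)
})

test_that("xn_summary aggregates per seed then across seeds", {
  fib <- tibble::tibble(
    seed = rep(1:2, each = 2),
    species = "cuboid", time_h = 18,
    length = c(1L, 2L, 1L, 3L), count = c(2, 1, 1, 1)
  )
  s <- xn_summary(fib)
  expect_equal(nrow(s), 1L)
  expect_equal(s$xn_mean, mean(c(4 / 3, 2)))
  expect_equal(s$n_seeds, 2L)
  expect_equal(s$max_length, 3L)
})

test_that("distribution statistics reject malformed tables", {
  expect_error(number_average_length(tibble::tibble(length = 0L, count = 1)),
               ">= 1")
  expect_error(normalize_histogram(tibble::tibble(length = 1L, count = 0)),
               "empty")
  expect_error(max_length(data.frame(foo = 1)), "columns")
})
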