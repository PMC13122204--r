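test_that("exact binomial upper tail matches closed forms and brute force", {
  expect_equal(exact_binomial_one_sided(8, 8, 0.5)$p_value, 0.00390625)
  expect_equal(signif(exact_binomial_one_sided(81, 81, 0.5)$p_value, 3), 4.14e-25)
  expect_equal(exact_binomial_one_sided(0, 5, 0.5)$p_value, 1.0)

  # all-success tail is p0^n
  for (n in c(1, 10, 50, 100, 200)) {
    expect_equal(exact_binomial_one_sided(n, n, 0.5)$p_value, 0.5^n)
  }

  # brute-force pmf summation oracle over all (k, n <= 25), two p0 values
  for (p0 in c(0.5, 0.3)) {
    for (n in c(1, 7, 25)) {
      for (k in 0:n) {
        brute <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
        expect_equal(exact_binomial_one_sided(k, n, p0)$p_value, brute,
                     tolerance = 1e-12)
      }
    }
  }

  # agreement with the base-R exact test as an independent cross-check
  bt <- binom.test(59, 81, 0.5, alternative = "greater")
  expect_equal(exact_binomial_one_sided(59, 81, 0.5)$p_value, bt$p.value,
               tolerance = 1e-12)

  expect_error(exact_binomial_one_sided(9, 8), "k <= n")
  expect_error(exact_binomial_one_sided(4, 8, 1), "p0")
})

test_that("two-sample Student's t matches the textbook pooled formula", {
  a <- c(0, 0.1, -0.1, 0.05)
  b <- c(-1, -0.9, -1.1, -0.95)
  got <- t_test_two_sample(a, b)
  ref <- pooled_t_by_hand(a, b)
  expect_equal(got$t, ref$t, tolerance = 1e-10)
  expect_equal(got$df, ref$df)
  expect_equal(got$p_value, ref$p, tolerance = 1e-10)

  expect_equal(t_test_two_sample(c(1, 1), c(1, 1)),
               list(t = 0, df = 2, p_value = 1))

  # location/scale invariance of the statistic
  set.seed(13)
  x <- rnorm(6); y <- rnorm(5, 1)
  t0 <- t_test_two_sample(x, y)
  t1 <- t_test_two_sample(3 * x + 7, 3 * y + 7)
  expect_equal(t1$t, t0$t, tolerance = 1e-10)
  expect_equal(t1$p_value, t0$p_value, tolerance = 1e-10)

  # simulated dosage groups separated by one cycle are highly significant
  set.seed(17)
  male <- rnorm(4, 0, 0.1); female <- rnorm(4, -1, 0.1)
  expect_lt(t_test_two_sample(male, female)$p_value, 1e-4)
})

test_that("one-sample t behaves like the reference and is sign-symmetric", {
  v <- c(-1.0, -0.95, -1.05)
  got <- t_test_one_sample(v, 0)
  ref <- t.test(v, mu = 0)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(t_test_one_sample(c(2, 2, 2), 2), list(t = 0, df = 2, p_value = 1))
  flipped <- t_test_one_sample(-v, 0)
  expect_equal(flipped$p_value, got$p_value, tolerance = 1e-12)
})

test_that("efficiency estimation inverts the standard-curve slope", {
  # slope exactly -1/log10(2) is 100% efficiency
  li <- 0:-4
  f <- estimate_efficiency(li, 20 + li * (-1 / log10(2)))
  expect_equal(f$efficiency, 100, tolerance = 1e-9)
  expect_equal(f$slope, -3.3219, tolerance = 1e-4)
  expect_true(f$in_range)

  # slope -3.6 is below the window
  f <- estimate_efficiency(0:-4, 20 - 3.6 * (0:-4))
  expect_equal(f$efficiency, 89.6, tolerance = 1e-2)
  expect_false(f$in_range)

  # exact recovery of simulated efficiencies
  for (e in c(0.95, 1.0, 1.05)) {
    d <- simulate_dilution_series(assay_model("sex", e, 22), 10^-(0:4), 1e6)
    f <- estimate_efficiency(d$log10_input, d$cq)
    expect_equal(f$efficiency, 100 * e, tolerance = 1e-9)
  }

  # noisy series at E = 1 stays inside the acceptance window across seeds
  for (s in 1:10) {
    set.seed(s)
    d <- simulate_dilution_series(assay_model("sex", 1, 22), 10^-(0:4), 1e6,
                                  noise_sd = 0.1)
    expect_true(estimate_efficiency(d$log10_input, d$cq)$in_range)
  }

  expect_error(estimate_efficiency(c(0, -1, -0.5), c(20, 23, 22)), "monotone|strictly")
  f <- estimate_efficiency(0:-3, c(20, 19, 18, 17))   # rising titration: fail flag
  expect_true(is.na(f$efficiency))
  expect_false(f$in_range)
})

test_that("box summaries follow the 1.5 IQR whisker convention", {
  b <- box_summary(1:5)
  expect_equal(b$median, 3)
  expect_equal(c(b$q1, b$q3), c(2, 4))
  expect_equal(c(b$whisker_lo, b$whisker_hi), c(1, 5))
  expect_equal(length(b$outliers), 0)

  b <- box_summary(7)
  expect_equal(unlist(b[c("median", "q1", "q3", "whisker_lo", "whisker_hi")]),
               rep(7, 5), ignore_attr = TRUE)

  b <- box_summary(c(0, 0, 0, 0, 10))
  expect_equal(b$outliers, 10)
  expect_equal(b$whisker_hi, 0)
})

test_that("score_calls counts repeats as incorrect", {
  calls <- data.frame(sample_id = c("a", "b", "c"),
                      call = c("male", "repeat", "female"))
  truth <- data.frame(sample_id = c("a", "b", "c"),
                      sex = c("male", "male", "male"))
  sc <- score_calls(calls, truth)
  expect_equal(sc$n_correct, 1)
  expect_equal(sc$binomial$p_value,
               exact_binomial_one_sided(1, 3, 0.5)$p_value)
})
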