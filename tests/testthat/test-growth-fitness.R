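make_series <- function(rate, id = "s1", group = "healthy",
                        condition = "control", seed = 0.75e5,
                        timepoints = c(0, 72)) {
  count_series(id, group, condition, timepoints,
               seed * rate^(timepoints / 24))
}

test_that("growth rate follows the daily fold-change convention", {
  # static culture: identity growth
  s0 <- count_series("flat", "healthy", "control", c(0, 72),
                     c(0.75e5, 0.75e5))
  expect_equal(estimate_growth_rate(s0)$rate, 1)
  # eight-fold over three days: rate 2/day
  s8 <- count_series("hd", "healthy", "control", c(0, 72), c(0.75e5, 6e5))
  expect_equal(estimate_growth_rate(s8)$rate, 2)
  # 72 h count 2.74e5 from 0.75e5 sits at the healthy no-CXCL8 mean
  s <- count_series("hd2", "healthy", "control", c(0, 72), c(0.75e5, 2.74e5))
  expect_equal(estimate_growth_rate(s)$rate, 1.54, tolerance = 1e-2)
  # rate-constant convention is the log of the daily fold
  expect_equal(estimate_growth_rate(s8, convention = "rate_constant")$rate,
               log(2))
})

test_that("growth rate is invariant to count rescaling", {
  s <- make_series(1.37, timepoints = c(0, 24, 48, 72))
  for (m in c("two_point", "loglinear")) {
    g1 <- estimate_growth_rate(s, method = m)$rate
    s2 <- s
    s2$counts <- s$counts * 17.3
    s2$seed_density <- s2$counts[1]
    g2 <- estimate_growth_rate(s2, method = m)$rate
    expect_equal(g1, g2)
    expect_equal(g1, 1.37)
  }
})

test_that("log-linear fit recovers the rate from noisy multi-timepoint data", {
  set.seed(99)
  tp <- c(0, 24, 48, 72)
  counts <- 0.75e5 * 1.5^(tp / 24) * exp(rnorm(4, 0, 0.05))
  counts[1] <- 0.75e5
  s <- count_series("noisy", "cmml", "control", tp, counts)
  expect_equal(estimate_growth_rate(s, method = "loglinear")$rate, 1.5,
               tolerance = 0.1)
})

test_that("undefined rates and invalid series raise informative errors", {
  expect_error(count_series("bad", "healthy", "control", c(0, 72),
                            c(0.75e5, -1)), "negative count")
  expect_error(count_series("bad", "healthy", "control", c(0, 72), c(0, 1e5)),
               "time 0")
  s <- count_series("dead", "cmml", "control", c(0, 72), c(0.75e5, 0))
  expect_error(estimate_growth_rate(s), "dead")
})

test_that("healthy summary reports mean, sd and range", {
  rates <- lapply(c(1.44, 1.59, 1.59), function(x) {
    s <- make_series(x, id = paste0("hd", x))
    estimate_growth_rate(s)
  })
  sm <- summarize_healthy(rates, "control")
  expect_equal(sm$mean_rate, 1.54, tolerance = 1e-12)
  expect_equal(sm$min_rate, 1.44)
  expect_equal(sm$max_rate, 1.59)
  expect_equal(sm$n, 3)
  # single rate: mean = min = max, sd undefined
  one <- summarize_healthy(rates[1], "control")
  expect_equal(one$mean_rate, one$min_rate)
  expect_equal(one$mean_rate, one$max_rate)
  expect_true(is.na(one$sd_rate))
  # equal rates: sd = 0
  eq <- summarize_healthy(rates[2:3], "control")
  expect_equal(eq$sd_rate, 0)
  expect_error(summarize_healthy(rates, "cxcl8"), "no healthy")
})

test_that("fitness is the condition-matched ratio to the healthy mean", {
  hd <- lapply(c(1.44, 1.59, 1.59), function(x)
    estimate_growth_rate(make_series(x, id = paste0("hd", x))))
  sm <- summarize_healthy(hd, "control")
  g_eq <- estimate_growth_rate(make_series(1.54, id = "c1", group = "cmml"))
  expect_equal(compute_fitness(g_eq, sm)$r, 1, tolerance = 1e-12)
  g_hi <- estimate_growth_rate(make_series(2.5718, id = "c2", group = "cmml"))
  expect_equal(compute_fitness(g_hi, sm)$r, 1.67, tolerance = 1e-3)
  g_cx <- estimate_growth_rate(
    make_series(1.3, id = "c3", group = "cmml", condition = "cxcl8"))
  expect_error(compute_fitness(g_cx, sm), "condition mismatch")
})

test_that("a smaller healthy mean strictly increases fitness", {
  g <- estimate_growth_rate(make_series(1.6, id = "c", group = "cmml"))
  for (pair in list(c(1.54, 1.17), c(1.5, 1.49), c(2, 1))) {
    hi <- summarize_healthy(list(estimate_growth_rate(
      make_series(pair[1], id = "h"))), "control")
    lo <- summarize_healthy(list(estimate_growth_rate(
      make_series(pair[2], id = "h"))), "control")
    expect_gt(compute_fitness(g, lo)$r, compute_fitness(g, hi)$r)
  }
})

test_that("fitness table counts the advantageous subset strictly", {
  hd <- lapply(c(1.5, 1.5, 1.5), function(x)
    estimate_growth_rate(make_series(x, id = paste0("hd", runif(1)))))
  sm <- list(control = summarize_healthy(hd, "control"))
  # all CMML below the healthy mean: none advantageous
  low <- lapply(c(1.2, 1.4), function(x) estimate_growth_rate(
    make_series(x, id = paste0("lo", x), group = "cmml")))
  ft <- fitness_table(c(hd, low), sm)
  expect_equal(attr(ft, "advantageous_n"), 0)
  # all CMML exactly at the mean: r = 1 is not advantageous (strict)
  at <- lapply(1:3, function(i) estimate_growth_rate(
    make_series(1.5, id = paste0("at", i), group = "cmml")))
  ft2 <- fitness_table(c(hd, at), sm)
  expect_equal(attr(ft2, "advantageous_n"), 0)
  expect_true(all(abs(ft2$r[ft2$group == "cmml"] - 1) < 1e-12))
  # mixed cohort: count and both minimum conventions
  mix <- lapply(c(0.9, 1.2, 1.8, 2.1), function(x) estimate_growth_rate(
    make_series(1.5 * x, id = sprintf("cm_%g", x), group = "cmml")))
  ft3 <- fitness_table(c(hd, mix), sm)
  expect_equal(attr(ft3, "advantageous_n"), 3)
  expect_equal(attr(ft3, "r_min_all"), 0.9, tolerance = 1e-12)
  expect_equal(attr(ft3, "r_min_advantageous"), 1.2, tolerance = 1e-12)
  expect_equal(attr(ft3, "r_max"), 2.1, tolerance = 1e-12)
  expect_error(fitness_table(mix, list()), "no healthy summary")
})
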