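healthy_summary_of <- function(mean_rate, condition) {
  tp <- c(0, 72)
  s <- count_series("h", "healthy", condition, tp,
                    0.75e5 * mean_rate^(tp / 24))
  summarize_healthy(list(estimate_growth_rate(s)), condition)
}

test_that("the closed-form fixation time enforces its domain", {
  expect_error(approximate_fixation_time(moran_parameters(N = 1000, r = 1)),
               "r > 1")
  expect_error(approximate_fixation_time(moran_parameters(N = 1000, r = 0.8)),
               "r > 1")
  expect_error(approximate_fixation_time(
    moran_parameters(N = 1000, r = 1.5, initial_mutants = 2)),
    "single founder")
  # monotone decreasing in fitness at fixed N
  expect_gt(approximate_fixation_time(moran_parameters(N = 1000, r = 1.2)),
            approximate_fixation_time(moran_parameters(N = 1000, r = 1.6)))
})

test_that("iteration-to-years conversion is the stated linear scaling", {
  p <- moran_parameters(N = 100000, r = 1.5, division_rate = 1)
  expect_equal(iterations_to_years(1e6, p), 10)
  expect_equal(iterations_to_years(0, p), 0)
  p2 <- moran_parameters(N = 100000, r = 1.5, division_rate = 2)
  expect_equal(iterations_to_years(1e6, p2), 5)
  # output years scale exactly as 1/division_rate
  for (d in c(0.25, 1, 4)) {
    pd <- moran_parameters(N = 5000, r = 1.3, division_rate = d)
    it <- approximate_fixation_time(pd)
    expect_equal(iterations_to_years(it, pd) * d,
                 iterations_to_years(it, moran_parameters(
                   N = 5000, r = 1.3, division_rate = 1)))
  }
})

test_that("approximation tracks the exact conditional time smoothly", {
  rep_grid <- approximation_quality_report(N_values = c(50, 100, 200, 350, 500),
                                 r_values = c(1.1, 1.25, 1.5, 1.75, 2))
  # one sign throughout: the formula consistently over- or under-shoots,
  # rather than flickering around the exact value
  expect_true(all(rep_grid$rel_deviation > 0) ||
                all(rep_grid$rel_deviation < 0))
  # deviation shrinks monotonically with N for every fitness (smooth trend)
  for (r in unique(rep_grid$r)) {
    d <- rep_grid[rep_grid$r == r, ]
    d <- d[order(d$N), ]
    expect_true(all(diff(abs(d$rel_deviation)) < 0))
  }
  # deviation shrinks monotonically with r for every N
  for (N in unique(rep_grid$N)) {
    d <- rep_grid[rep_grid$N == N, ]
    d <- d[order(d$r), ]
    expect_true(all(diff(abs(d$rel_deviation)) < 0))
  }
  # at moderate N and mid-band fitness the two agree within ~15%
  sub <- rep_grid[rep_grid$N == 200 & rep_grid$r == 1.5, ]
  expect_lt(abs(sub$rel_deviation), 0.15)
})

test_that("per-sample scenario reproduces the condition-matched fitness", {
  h_without <- healthy_summary_of(1.54, "control")
  h_with <- healthy_summary_of(1.17, "cxcl8")
  sc <- fixation_for_sample(1.6, h_without, h_with, sample_id = "cm1")
  expect_equal(sc$r_without_cxcl8, 1.6 / 1.54, tolerance = 1e-12)
  expect_equal(sc$r_with_cxcl8, 1.6 / 1.17, tolerance = 1e-12)
  expect_lt(sc$fixation_years_with, sc$fixation_years_without)
  expect_gt(sc$speedup_factor, 1)
  # identical healthy means: no CXCL8 effect, speedup factor 1
  h_same <- healthy_summary_of(1.3, "cxcl8")
  h_ctrl <- healthy_summary_of(1.3, "control")
  sc2 <- fixation_for_sample(1.6, h_ctrl, h_same)
  expect_equal(sc2$speedup_factor, 1, tolerance = 1e-12)
  # growth below both means: no takeover on either branch
  sc3 <- fixation_for_sample(1.0, h_without, h_with)
  expect_true(is.na(sc3$fixation_years_without))
  expect_true(is.na(sc3$fixation_years_with))
  expect_equal(sc3$note, "no takeover predicted")
})

test_that("scenario methods agree between analytic and exact at small N", {
  h_without <- healthy_summary_of(1.54, "control")
  h_with <- healthy_summary_of(1.17, "cxcl8")
  p <- moran_parameters(N = 500, r = 2)
  sa <- fixation_for_sample(2.2, h_without, h_with, params_template = p,
                            method = "analytic")
  se <- fixation_for_sample(2.2, h_without, h_with, params_template = p,
                            method = "exact")
  expect_lt(se$fixation_years_with, se$fixation_years_without)
  # the approximation overshoots the exact time by a bounded margin here
  expect_equal(sa$fixation_years_without / se$fixation_years_without, 1,
               tolerance = 0.2)
})

test_that("sensitivity grid flags the low-fitness region", {
  g <- sensitivity_grid(r_values = seq(1.1, 1.9, by = 0.1),
                        N_values = c(25000, 100000, 1300000))
  for (N in unique(g$N)) {
    d <- g[g$N == N, ]
    s11 <- d$dT_dr_abs[abs(d$r - 1.2) < 1e-9] # innermost low-r point
    s19 <- d$dT_dr_abs[abs(d$r - 1.8) < 1e-9]
    expect_gt(s11, s19)
    expect_true(d$max_sensitivity[which.min(abs(d$r - 1.2))])
    # fixation years increase with N at fixed r
  }
  for (r in c(1.2, 1.5, 1.8)) {
    d <- g[abs(g$r - r) < 1e-9, ]
    expect_true(all(diff(d$fixation_years[order(d$N)]) > 0))
  }
  # grid row matches the single-call computation
  p <- moran_parameters(N = 100000, r = 1.5, division_rate = 1)
  row <- g[g$N == 100000 & abs(g$r - 1.5) < 1e-9, ]
  expect_equal(row$fixation_years,
               iterations_to_years(approximate_fixation_time(p), p))
  expect_error(sensitivity_grid(r_values = c(1, 1.5)), "> 1")
  expect_warning(sensitivity_grid(r_values = 1.5), "single-point")
})
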