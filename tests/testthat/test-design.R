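test_that("HSD spending matches its closed form and limits", {
  # exhausts the budget at t = 1, linear at gamma = 0
  expect_equal(hsd_spend(1, -4, 0.025), 0.025)
  expect_equal(hsd_spend(0.5, 0, 0.025), 0.0125)
  # direct evaluation of the closed form at the design's interim
  expect_equal(hsd_spend(0.5, -4, 0.025),
               0.025 * (1 - exp(2)) / (1 - exp(4)), tolerance = 1e-12)
  # monotone non-decreasing over a grid, 0 at t = 0
  for (g in c(-4, -2, 0, 1, 3)) {
    v <- hsd_spend(seq(0, 1, 0.05), g, 0.2)
    expect_true(all(diff(v) >= 0))
    expect_equal(v[1], 0)
  }
  expect_error(hsd_spend(1.2, -4, 0.025), "\\[0, 1\\]")
})

test_that("HSD spending is continuous in gamma at 0", {
  t <- c(0.2, 0.5, 0.8)
  for (g in c(1e-6, -1e-6)) {
    # the HSD family deviates from linear spending by a relative |gamma|/2
    # at most, so the limit is met to within 5e-7 here
    expect_equal(hsd_spend(t, g, 0.025), 0.025 * t, tolerance = 1e-6)
  }
})

test_that("quantile substitution reproduces the published t-scale bounds", {
  expect_equal(quantile_substitute(0, 30), 0)
  expect_equal(round(quantile_substitute(0.40, 30), 3), 0.404)
  expect_equal(round(quantile_substitute(2.75, 30), 3), 2.960)
  expect_equal(round(quantile_substitute(1.96, 62), 3), 1.999)
})

test_that("quantile substitution converges to the z bound as df grows", {
  z <- 1.96
  vals <- quantile_substitute(z, c(10, 100, 1000, 1e6))
  expect_true(all(diff(vals) < 0))  # decreasing toward z for z > 0
  expect_true(all(vals > z))
  expect_lt(abs(quantile_substitute(z, 1e6) - z), 1e-3)
  expect_error(quantile_substitute(1, 0.5), "df")
})

test_that("fixed-design effect size matches the design's theta and Hedges g", {
  es <- fixed_sample_theta(62, 0.05, 0.2)
  expect_equal(round(es$theta, 4), 0.3558)
  expect_equal(round(es$hedges_g, 2), 0.71)
  expect_equal(es$hedges_g, 2 * es$theta)
  # direct evaluation at n = 100: (1.959964 + 0.8416212) / 10
  expect_equal(fixed_sample_theta(100)$theta,
               (qnorm(0.975) + qnorm(0.8)) / 10, tolerance = 1e-12)
  expect_lt(fixed_sample_theta(1e8)$theta, 1e-3)
})

test_that("margin-of-error multipliers match the pilot's planning values", {
  expect_equal(round(margin_of_error(10), 2), 0.72)
  expect_equal(round(margin_of_error(10, 10), 2), 0.94)
  expect_equal(round(margin_of_error(8, 8), 2), 1.07)
  # large-sample limit: half-width times sqrt(n) -> 1.96
  expect_equal(margin_of_error(1e5) * sqrt(1e5), qnorm(0.975),
               tolerance = 1e-4)
  expect_error(margin_of_error(1), ">= 2")
})

test_that("a one-stage design reduces to the fixed-sample critical value", {
  spec <- design_spec(info_fractions = 1, n_fix = 62)
  b <- solve_boundaries(spec)
  expect_equal(b$z_upper, qnorm(0.975), tolerance = 1e-6)
  expect_equal(b$z_lower, b$z_upper)
  expect_equal(b$n_max, 62)
})

test_that("boundary solver reproduces the published interim boundaries", {
  b <- solve_boundaries(design_spec())
  expect_lt(abs(b$z_lower[1] - 0.40), 0.02)
  expect_lt(abs(b$z_upper[1] - 2.75), 0.02)
  expect_equal(b$z_lower[2], b$z_upper[2])  # bounds meet at the final stage
  expect_equal(b$dfs, c(30, 62))
  expect_equal(b$n_per_group, c(16, 32))
  expect_equal(ceiling(b$n_max), 64)
  # t-scale bounds exceed z-scale bounds for positive bounds at finite df
  expect_true(all(b$t_upper > b$z_upper))
})

test_that("error-spending construction respects the error budgets", {
  b <- solve_boundaries(design_spec())
  h0 <- gs_crossing(b$z_upper, b$z_lower, b$info_fractions, delta = 0)
  expect_lte(sum(h0$p_upper), 0.025 + 1e-6)
  expect_equal(sum(h0$p_upper), 0.025, tolerance = 1e-4)
  # total power 1 - beta under the design drift
  h1 <- gs_crossing(b$z_upper, b$z_lower, b$info_fractions, delta = b$delta)
  expect_equal(sum(h1$p_upper), 0.80, tolerance = 1e-4)
  expect_equal(sum(h1$p_lower), 0.20, tolerance = 1e-4)
})

test_that("quadrature agrees with plain Monte Carlo on crossing probabilities", {
  b <- solve_boundaries(design_spec())
  for (delta in c(0, b$delta)) {
    set.seed(42)
    n <- 1e6
    z1 <- rnorm(n, mean = delta * sqrt(0.5))
    # Brownian increment construction: z2*sqrt(1) = z1*sqrt(0.5) + increment
    z2 <- z1 * sqrt(0.5) + rnorm(n, mean = delta * 0.5, sd = sqrt(0.5))
    cross <- gs_crossing(b$z_upper, b$z_lower, b$info_fractions, delta)
    checks <- rbind(
      c(mean(z1 > b$z_upper[1]), cross$p_upper[1]),
      c(mean(z1 < b$z_lower[1]), cross$p_lower[1]),
      c(mean(z1 >= b$z_lower[1] & z1 <= b$z_upper[1] & z2 > b$z_upper[2]),
        cross$p_upper[2]))
    for (i in seq_len(nrow(checks))) {
      mc_se <- sqrt(checks[i, 1] * (1 - checks[i, 1]) / n)
      expect_lt(abs(checks[i, 1] - checks[i, 2]), 3 * mc_se + 1e-6)
    }
  }
})

test_that("expected sample size matches the published design summary", {
  b <- solve_boundaries(design_spec())
  expect_equal(expected_sample_size(b, b$theta), 54.7, tolerance = 0.5 / 54.7)
  expect_equal(expected_sample_size(b, 0), 42.8, tolerance = 0.5 / 42.8)
  # degenerate: no continuation region -> interim size
  b0 <- b
  b0$z_lower[1] <- b0$z_upper[1]
  expect_equal(expected_sample_size(b0, 0), b$n_max * 0.5)
})

test_that("design report and JSON export round-trip the boundary set", {
  b <- solve_boundaries(design_spec())
  tab <- design_report_table(b)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("stage", "info_fraction", "n_per_group", "z_futility",
                      "z_efficacy", "t_futility", "t_efficacy", "df",
                      "cum_alpha_spent", "cum_beta_spent"))
  path <- tempfile(fileext = ".json")
  write_design_json(b, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$z_upper, b$z_upper, tolerance = 1e-10)
  expect_equal(back$n_max, b$n_max, tolerance = 1e-10)
})

test_that("design spec validation rejects malformed inputs", {
  expect_error(design_spec(info_fractions = c(0.5, 0.4, 1)), "increasing")
  expect_error(design_spec(info_fractions = c(0.5, 0.9)), "last element 1")
  expect_error(design_spec(alpha_total = 1.2), "alpha")
})
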