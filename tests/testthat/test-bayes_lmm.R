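test_that("logit transform matches closed forms and boundary policies", {
  expect_equal(as.numeric(logit_transform(50)), 0)
  expect_equal(as.numeric(logit_transform(90)), log(9), tolerance = 1e-12)
  # boundary shrink adds half a pseudo-dose: logit((28 + 0.5) / 29)
  expect_equal(as.numeric(logit_transform(100, policy = "shrink", n_doses = 28)),
               qlogis(28.5 / 29), tolerance = 1e-12)
  expect_equal(as.numeric(logit_transform(0, policy = "shrink", n_doses = 14)),
               qlogis(0.5 / 15), tolerance = 1e-12)
  # epsilon policy and clamping of late-return values above 100
  expect_equal(as.numeric(logit_transform(100, policy = "epsilon", eps = 0.01)),
               qlogis(0.99))
  v <- logit_transform(c(107, 50), policy = "epsilon")
  expect_equal(attr(v, "n_clamped"), 1L)
  expect_error(logit_transform(107, clamp = FALSE), "clamping disabled")
  expect_error(logit_transform(100, policy = "none"), "boundary")
  expect_error(logit_transform(-5), "non-negative")
})

test_that("informative priors encode the adherence grid as reference-coded means", {
  p <- build_informative_priors()
  m <- p$coef_means
  expect_equal(unname(m["(Intercept)"]), qlogis(0.90), tolerance = 1e-12)
  expect_equal(unname(m["armMPH"]), qlogis(0.96) - qlogis(0.90),
               tolerance = 1e-12)
  expect_equal(unname(m["week8"]), qlogis(0.66) - qlogis(0.90),
               tolerance = 1e-12)
  expect_equal(unname(m["armMPH:week8"]),
               (qlogis(0.82) - qlogis(0.96)) - (qlogis(0.66) - qlogis(0.90)),
               tolerance = 1e-12)
  expect_equal(round(unname(m["armMPH:week8"]), 3), -0.128)
  expect_false(p$autoscale)
  expect_equal(p$coef_sds, 1)
  # identical grids: every treatment-involving prior mean is zero
  same <- rbind(placebo = c(`2` = 80, `4` = 70, `8` = 60),
                MPH = c(`2` = 80, `4` = 70, `8` = 60))
  m0 <- build_informative_priors(same)$coef_means
  expect_equal(unname(m0[grep("MPH", names(m0))]), rep(0, 3))
  expect_error(build_informative_priors(rbind(placebo = c(0, 50, 60),
                                              MPH = c(50, 50, 50))), "\\(0, 100\\)")
})

test_that("autoscale resolves prior scales from the data", {
  X <- cbind("(Intercept)" = 1, x = c(0, 0, 1, 1))
  y <- c(1, 3, 2, 8)
  rp <- resolve_priors(prior_spec(), X, y)
  expect_equal(unname(rp$coef_sds["(Intercept)"]), 2.5 * sd(y))
  expect_equal(unname(rp$coef_sds["x"]), 2.5 * sd(y) / sd(X[, "x"]))
  expect_equal(rp$error_sd_rate, 1 / sd(y))
  expect_equal(unname(rp$coef_means["(Intercept)"]), mean(y))
  # autoscale off: scales pass through untouched
  rp0 <- resolve_priors(prior_spec(coef_sds = 1.5, autoscale = FALSE), X, y)
  expect_equal(unname(rp0$coef_sds), c(1.5, 1.5))
  expect_equal(rp0$error_sd_rate, 1)
})

test_that("prior-only sampling reproduces the resolved prior moments", {
  tr <- small_trial(seed = 61)
  ep <- derive_endpoints(tr$visits, tr$mems_events)
  fit <- quick_fit(ep, priors = build_informative_priors(), seed = 2,
                   prior_only = TRUE)
  n_draws <- prod(dim(fit$draws)[1:2])
  for (j in fit$coef_names) {
    d <- as.vector(fit$draws[, , j])
    m <- fit$priors_resolved$coef_means[j]
    s <- fit$priors_resolved$coef_sds[j]
    expect_lt(abs(mean(d) - m), 3 * s / sqrt(n_draws))
    expect_lt(abs(sd(d) / s - 1), 0.1)
  }
  # residual SD prior: exponential(rate) has mean 1/rate
  sig <- as.vector(fit$draws[, , ".sigma"])
  rate <- fit$priors_resolved$error_sd_rate
  expect_lt(abs(mean(sig) - 1 / rate), 3 * (1 / rate) / sqrt(n_draws / 10))
})

test_that("near-degenerate priors pin the posterior to the prior means", {
  tr <- small_trial(seed = 62)
  ep <- derive_endpoints(tr$visits, tr$mems_events)
  pri <- build_informative_priors()
  pri$coef_sds <- 1e-3
  fit <- quick_fit(ep, priors = pri, seed = 3)
  expect_equal(unname(fit$summary$median[seq_along(fit$coef_names)]),
               unname(pri$coef_means[fit$coef_names]), tolerance = 1e-2)
})

test_that("EMM coding identity and exceedance-probability consistency hold", {
  tr <- small_trial(seed = 63)
  ep <- derive_endpoints(tr$visits, tr$mems_events)
  fit <- quick_fit(ep, seed = 4)
  # reference cell (placebo, earliest week) is the intercept draw exactly
  ref <- fit$emm[fit$emm$arm == "placebo" & fit$emm$week == 2, ]
  expect_equal(ref$median, fit$summary$median[1])
  expect_equal(ref$ci95_lower, fit$summary$ci95_lower[1])
  # pr_exceed equals one minus the empirical CDF of the difference at zero
  for (wk in c(2, 4, 8)) {
    pc <- posterior_contrasts(fit, wk)
    expect_equal(pc$pr_exceed, 1 - ecdf(pc$draws)(0))
    expect_equal(pc$pr_exceed, unname(fit$pr_exceed[as.character(wk)]))
  }
  expect_error(posterior_contrasts(fit, 5), "not in the fitted model")
  # the QIDS week-8 change difference is the interaction draw itself
  fq <- fit_lmm(tr$visits, model_spec("qids"), default_priors(), seed = 4)
  pcq <- posterior_contrasts(fq, 8)
  expect_equal(median(pcq$interaction_draws),
               fq$summary$median[fq$summary$parameter == "armMPH:week8"])
})

test_that("arm-symmetric outcomes give symmetric treatment contrasts", {
  # identical outcome vectors in both arms (flat at 80% plus a small noise
  # floor, mirrored across arms): the likelihood carries no arm information,
  # so the contrasts center at 0 and Pr(MPH > placebo) sits at one half
  ep <- expand.grid(participant_id = sprintf("P%02d", 1:20),
                    visit_week = c(2, 4, 8), stringsAsFactors = FALSE)
  ep$arm <- rep(rep(c("placebo", "MPH"), each = 10), 3)
  set.seed(15)
  noise <- rnorm(30, 0, 0.5)
  idx <- (match(ep$visit_week, c(2, 4, 8)) - 1) * 10 +
    (as.integer(sub("P", "", ep$participant_id)) - 1) %% 10 + 1
  ep$pill_count_pct <- 80 + noise[idx]
  fit <- quick_fit(ep, seed = 5)
  for (wk in c(2, 4, 8)) {
    expect_lt(abs(fit$pr_exceed[as.character(wk)] - 0.5), 0.1)
  }
  expect_lt(abs(median(posterior_contrasts(fit, 8)$draws)), 0.2)
})

test_that("a known adherence deficit is detected as a low exceedance probability", {
  # MPH generated ~10 points lower throughout: Pr(MPH > placebo) at week 8
  # must fall below one half
  cfg <- generator_config(
    prob_placebo = c(`2` = 0.85, `4` = 0.85, `8` = 0.85),
    mph_logit_offsets = c(`2` = -0.7, `4` = -0.7, `8` = -0.7),
    n_dropouts = 0, seed = 88)
  tr <- generate_trial(cfg)
  ep <- derive_endpoints(tr$visits, tr$mems_events)
  fit <- quick_fit(ep, seed = 6)
  expect_lt(fit$pr_exceed[["8"]], 0.5)
})

test_that("rank-deficient designs and unknown outcomes are rejected", {
  tr <- small_trial(seed = 64)
  ep <- derive_endpoints(tr$visits, tr$mems_events)
  ep$arm <- "MPH"  # single-arm data: treatment column collapses
  expect_error(quick_fit(ep, seed = 1), "rank-deficient")
  expect_error(model_spec("banana"))
})
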