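test_that("pill-count percentage evaluates the dispensing formula exactly", {
  expect_equal(pill_count_pct(28, 28, days = 28), 0)
  expect_equal(pill_count_pct(28, 0, days = 28), 100)
  expect_equal(pill_count_pct(28, 7, days = 28), 75)
  # late return: value exceeds 100 and is reported as computed
  expect_gt(pill_count_pct(30, 0, days = 28), 100)
  # dates are an equivalent way to give the span
  expect_equal(pill_count_pct(14, 7, "2020-01-01", "2020-01-15"), 50)
  expect_error(pill_count_pct(14, 7, "2020-01-15", "2020-01-01"), "after")
  expect_error(pill_count_pct(14, 20, days = 14), "remaining")
})

test_that("pill-count percentage is linear in pills remaining", {
  rem <- 0:14
  v <- pill_count_pct(14, rem, days = 14)
  expect_equal(diff(v), rep(-100 / 14, 14))
})

test_that("MEMS on-schedule percentage handles perfect and half dosing", {
  # 14 days at exactly 08:00: zero-residual line, all on schedule
  expect_equal(mems_on_schedule_pct(mems_times(rep(8, 14)),
                                    "2020-03-01", "2020-03-14"), 100)
  # dosing stops after day 7: days without openings count as missed
  expect_equal(mems_on_schedule_pct(mems_times(rep(8, 7)),
                                    "2020-03-01", "2020-03-14"), 50)
})

test_that("the +/- 6 h window is boundary-inclusive against a brute-force oracle", {
  oracle <- function(hours, window = 6) {
    d <- seq_along(hours) - 1
    fit <- lm(hours ~ d)
    100 * sum(abs(resid(fit)) <= window + 1e-9) / length(hours)
  }
  # balanced alternation (02,14,14,02 repeating) has zero OLS slope, so every
  # residual is exactly 6 h: inclusive window keeps all 16 days
  balanced <- rep(c(2, 14, 14, 2), 4)
  expect_equal(oracle(balanced), 100)
  expect_equal(mems_on_schedule_pct(mems_times(balanced),
                                    "2020-03-01", "2020-03-16"), 100)
  # strict 02/14 alternation over 14 days tilts the OLS line, pushing the
  # extreme-leverage days past 6 h: 8 of 14 remain within the window
  tilted <- rep(c(2, 14), 7)
  expect_equal(oracle(tilted), 100 * 8 / 14)
  expect_equal(mems_on_schedule_pct(mems_times(tilted),
                                    "2020-03-01", "2020-03-14"),
               100 * 8 / 14)
})

test_that("MEMS endpoint is invariant to a uniform clock shift", {
  set.seed(8)
  hours <- pmin(22, pmax(5, 9 + rnorm(14, 0, 3)))
  base <- mems_on_schedule_pct(mems_times(hours), "2020-03-01", "2020-03-14")
  for (shift in c(-3, 2.5)) {
    expect_equal(
      mems_on_schedule_pct(mems_times(hours + shift),
                           "2020-03-01", "2020-03-14"), base)
  }
})

test_that("MEMS edge cases: duplicates, sparse logs, out-of-schedule events", {
  # several openings on one day: only the first counts as the dose
  two_a_day <- sort(c(mems_times(rep(8, 10)), mems_times(rep(15, 10))))
  expect_equal(mems_on_schedule_pct(two_a_day, "2020-03-01", "2020-03-10"),
               100)
  expect_warning(
    out <- mems_on_schedule_pct(mems_times(8), "2020-03-01", "2020-03-14"),
    "fewer than 2")
  expect_equal(as.numeric(out), 0)
  expect_error(
    mems_on_schedule_pct(mems_times(rep(8, 5)), "2020-03-02", "2020-03-04"),
    "outside")
})

test_that("QIDS remission and response follow the protocol cut-offs", {
  expect_true(qids_remission(5))
  expect_false(qids_remission(6))
  expect_true(qids_remission(6, threshold = 6))  # configurable cut-off
  expect_true(qids_response(9, baseline = 18))   # exactly 50%
  expect_false(qids_response(9, baseline = 17))  # 9 > 8.5
  expect_error(qids_remission(30), "\\[0, 27\\]")
  expect_error(qids_response(-1, 18), "\\[0, 27\\]")
})

test_that("ITT imputation zeroes scheduled visits from the withdrawal week on", {
  rec <- expand.grid(participant_id = c("A", "B"), visit_week = c(2, 4, 8),
                     stringsAsFactors = FALSE)
  rec$pill_count_pct <- 80
  rec$mems_pct <- 70
  # no withdrawals: unchanged values
  out0 <- itt_impute(rec, NULL)
  expect_equal(sort(out0$pill_count_pct), sort(rec$pill_count_pct))
  expect_false(any(out0$imputed))
  # withdrawal at week 3: weeks 4 and 8 imputed, week 2 kept
  out <- itt_impute(rec, c(A = 3))
  a <- out[out$participant_id == "A", ]
  expect_equal(a$pill_count_pct[a$visit_week == 2], 80)
  expect_equal(a$pill_count_pct[a$visit_week %in% c(4, 8)], c(0, 0))
  expect_equal(a$imputed[order(a$visit_week)], c(FALSE, TRUE, TRUE))
  expect_false(any(out$imputed[out$participant_id == "B"]))
})

test_that("after imputation every participant has every scheduled visit", {
  set.seed(21)
  for (i in 1:5) {
    ids <- sprintf("P%02d", 1:20)
    n_wd <- sample(0:6, 1)
    wd <- setNames(sample(c(2, 3, 4, 6), n_wd, replace = TRUE),
                   sample(ids, n_wd))
    present <- lapply(ids, function(id) {
      weeks <- c(2, 4, 8)
      if (id %in% names(wd)) weeks <- weeks[weeks < wd[id]]
      if (!length(weeks)) return(NULL)
      data.frame(participant_id = id, visit_week = weeks,
                 pill_count_pct = 75, mems_pct = 75)
    })
    rec <- do.call(rbind, present)
    out <- itt_impute(rec, wd, participants = ids)
    expect_equal(nrow(out), 20 * 3)
    expect_false(any(is.na(out$pill_count_pct)))
    expect_equal(sum(out$imputed),
                 sum(vapply(wd, function(w) sum(c(2, 4, 8) >= w), numeric(1))))
  }
})

test_that("derive_endpoints builds the full long-format endpoint table", {
  tr <- small_trial(n = 20, seed = 303, dropouts = 4)
  ep <- derive_endpoints(tr$visits, tr$mems_events)
  expect_equal(nrow(ep), 60)
  expect_setequal(unique(ep$visit_week), c(2, 4, 8))
  expect_true(all(ep$mems_pct >= 0 & ep$mems_pct <= 100))
  expect_true(all(table(ep$participant_id) == 3))
  # imputed rows are zero on both endpoints
  expect_true(all(ep$pill_count_pct[ep$imputed] == 0))
  expect_true(all(ep$mems_pct[ep$imputed] == 0))
  # withdrawn participants have all visits from their withdrawal week imputed
  wd <- tr$truth$withdrawal_weeks
  for (id in names(wd)) {
    rows <- ep[ep$participant_id == id, ]
    expect_true(all(rows$imputed[rows$visit_week >= wd[id]]))
  }
})
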