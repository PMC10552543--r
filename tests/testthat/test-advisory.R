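# Exceedance classification, confusion statistics, and daily advisory
# scheduling including simulated weekly sampling.

test_that("exceedance is strict: the threshold itself does not exceed", {
  tm <- hours(3)
  f <- tracer_field(tm, c(0, 1000), rbind(c(5e-4, 0), c(1e-3, 0), c(0, 0)))
  x <- exceedance(f, 5e-4)
  expect_identical(x$x, rbind(c(FALSE, FALSE), c(TRUE, FALSE),
                              c(FALSE, FALSE)))
  zero <- tracer_field(tm, c(0, 1000), matrix(0, 3, 2))
  expect_false(any(exceedance(zero, 5e-4)$x))
  expect_equal(sum(exceedance(f, 5e-4)$x), 1L)
})

test_that("confusion counts and the derived rates follow their definitions", {
  set.seed(41)
  p <- matrix(runif(200) < 0.3, 20, 10)
  cc <- confusion(p, p)
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(agreement(cc), 1)
  inv <- confusion(!p, p)
  expect_equal(inv$tp + inv$tn, 0)
  # direct arithmetic
  cc2 <- confusion_counts(tp = 3, fp = 2, fn = 1, tn = 10)
  expect_equal(sensitivity(cc2), 0.75)
  expect_equal(specificity(cc2), 10 / 12)
  expect_equal(agreement(cc2), 13 / 16)
  expect_equal(specificity(confusion_counts(1, 5, 1, 5)), 0.5)
  expect_equal(sensitivity(confusion_counts(4, 1, 0, 2)), 1)
  # undefined denominators are NaN with a reason, never silent zero
  s <- sensitivity(confusion_counts(0, 3, 0, 7))
  expect_true(is.nan(s))
  expect_match(attr(s, "reason"), "positives")
  expect_error(confusion(p, p[1:10, ]), "shapes")
})

test_that("a single exceedance hour triggers that day's advisory only", {
  tm <- hours(72, "2018-03-01")
  x <- matrix(FALSE, 72, 2)
  x[30, 1] <- TRUE                      # 2018-03-02 05:00
  bf <- structure(list(time = tm, y = c(0, 1000), x = x),
                  class = "binary_field")
  adv <- daily_advisory(bf)
  expect_identical(adv$a[, 1], c(FALSE, TRUE, FALSE))
  expect_false(any(adv$a[, 2]))
})

test_that("advisories at the day boundary land on different days", {
  tm <- hours(49, "2018-03-01")
  x1 <- matrix(FALSE, 49, 1); x1[24, 1] <- TRUE    # 23:00 day 1
  x2 <- matrix(FALSE, 49, 1); x2[25, 1] <- TRUE    # 00:00 day 2
  a1 <- daily_advisory(structure(list(time = tm, y = 0, x = x1),
                                 class = "binary_field"))
  a2 <- daily_advisory(structure(list(time = tm, y = 0, x = x2),
                                 class = "binary_field"))
  expect_identical(a1$a[, 1], c(TRUE, FALSE, FALSE))
  expect_identical(a2$a[, 1], c(FALSE, TRUE, FALSE))
})

test_that("weekly sampling schedule matches the brute-force oracle", {
  truth <- toy_truth(n_hours = 4 * 168, ny = 2, seed = 43)
  for (h in c(0, 1, 13, 99, 167)) {
    got <- weekly_sampling_advisory(truth, h)
    want <- brute_weekly(truth, h)
    expect_identical(got$a, want$a)
  }
  expect_error(weekly_sampling_advisory(truth, 168), "0-167")
  expect_error(weekly_sampling_advisory(truth, -1), "0-167")
})

test_that("weekly sampling saturates and stays silent appropriately", {
  tm <- hours(3 * 168, "2018-01-01")
  always <- structure(list(time = tm, y = 0,
                           x = matrix(TRUE, 3 * 168, 1)),
                      class = "binary_field")
  adv <- weekly_sampling_advisory(always, 0)
  # first sample processed next day: day 1 has no advisory, rest do
  expect_false(adv$a[1, 1])
  expect_true(all(adv$a[-1, 1]))
  never <- structure(list(time = tm, y = 0,
                          x = matrix(FALSE, 3 * 168, 1)),
                     class = "binary_field")
  expect_false(any(weekly_sampling_advisory(never, 80)$a))
})

test_that("a one-day plume between sampling hours is missed entirely", {
  tm <- hours(4 * 168, "2018-01-01")
  x <- matrix(FALSE, 4 * 168, 1)
  x[169:192, 1] <- TRUE                 # all of day 8
  truth <- structure(list(time = tm, y = 0, x = x), class = "binary_field")
  adv <- weekly_sampling_advisory(truth, 48)   # samples land on other days
  ideal <- daily_advisory(truth)
  acc <- advisory_accuracy(adv, ideal)
  expect_equal(acc$sensitivity, 0)      # the event is never detected
})

test_that("weekly-periodic truth yields a weekly-periodic advisory schedule", {
  tm <- hours(6 * 168, "2018-01-01")
  x <- matrix(FALSE, 6 * 168, 1)
  x[rep(0:5 * 168, each = 24) + 25:48, 1] <- TRUE  # day 2 of every week
  truth <- structure(list(time = tm, y = 0, x = x), class = "binary_field")
  for (h in c(30, 100)) {
    a <- weekly_sampling_advisory(truth, h)$a[, 1]
    weeks <- matrix(a[8:35], 7)          # weeks 2-5, after the lead-in
    expect_true(all(weeks == weeks[, 1]))
  }
  # a sampling hour inside the plume day detects it every week
  det <- weekly_sampling_advisory(truth, 30)$a   # hour 30 = day 2, 06:00
  expect_true(any(det))
})

test_that("model-informed advisories from the truth field itself are ideal", {
  truth <- toy_truth(n_hours = 3 * 168, ny = 3, seed = 44)
  ideal <- daily_advisory(truth)
  model_informed <- daily_advisory(truth)
  acc <- advisory_accuracy(model_informed, ideal)
  expect_equal(acc$accuracy_pct, rep(100, 3))
})

test_that("advisory accuracy counts matching days", {
  days <- as.Date("2018-01-01") + 0:9
  ideal <- structure(list(day = days, y = 0,
                          a = matrix(c(TRUE, rep(FALSE, 9)), 10, 1)),
                     class = "daily_advisory")
  never <- structure(list(day = days, y = 0, a = matrix(FALSE, 10, 1)),
                     class = "daily_advisory")
  expect_equal(advisory_accuracy(never, ideal)$accuracy_pct, 90)
  expect_equal(advisory_accuracy(ideal, ideal)$accuracy_pct, 100)
  # seeded random candidate agrees with direct enumeration
  set.seed(45)
  cand <- structure(list(day = days, y = 0,
                         a = matrix(runif(10) < 0.5, 10, 1)),
                    class = "daily_advisory")
  want <- 100 * mean(cand$a == ideal$a)
  expect_equal(advisory_accuracy(cand, ideal)$accuracy_pct, want)
  expect_error(advisory_accuracy(cand, structure(
    list(day = days + 1, y = 0, a = never$a), class = "daily_advisory")),
    "aligned")
})

test_that("the sampling-hour sweep brackets every single-hour schedule", {
  truth <- toy_truth(n_hours = 3 * 168, ny = 2, seed = 46)
  sw <- sampling_hour_sweep(truth)
  expect_equal(dim(sw$accuracy), c(168L, 2L))
  one <- advisory_accuracy(weekly_sampling_advisory(truth, 77),
                           daily_advisory(truth))$accuracy_pct
  expect_true(all(one >= sw$summary$min - 1e-9))
  expect_true(all(one <= sw$summary$max + 1e-9))
  expect_equal(sw$accuracy[78, ], one)
})
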