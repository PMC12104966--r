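test_that("excluding disappeared animals leaves 45 of 50 periods", {
  per <- fifty_periods()
  rec <- to_survival_records(per)
  expect_equal(nrow(rec), 45L)
  expect_equal(sum(duplicated(rec$animal_id)) <= 1, TRUE)
  # both periods of the recaptured animal enter independently when kept
  expect_equal(sum(per$animal_id == "lx01"), 2L)
})

test_that("record policies map end statuses to events as documented", {
  per <- data.frame(animal_id = c("a", "b", "c", "d"),
                    group = "translocated",
                    start = as.Date("2020-01-01"),
                    end = as.Date("2020-01-01") + c(100, 200, 300, 400),
                    end_status = c("alive", "natural_mortality",
                                   "roadkill", "disappeared"))
  d0 <- to_survival_records(per)
  expect_equal(d0$event[match(c("a", "b", "c"), d0$animal_id)],
               c(0L, 1L, 1L))
  expect_false("d" %in% d0$animal_id)
  dc <- to_survival_records(per, policy = "disappeared_censored")
  expect_equal(dc$event[dc$animal_id == "d"], 0L)
  hc <- to_survival_records(per, policy = "human_caused_only")
  expect_equal(hc$event[match(c("b", "c"), hc$animal_id)], c(0L, 1L))
  per$end_status[1] <- "vanished"
  expect_error(to_survival_records(per), "invalid end_status")
  per$end_status[1] <- "alive"
  per$end[1] <- as.Date("2019-01-01")
  expect_error(to_survival_records(per), "before it starts")
})

test_that("product-limit estimates match a hand computation", {
  km <- kaplan_meier(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))
  none <- kaplan_meier(c(5, 7), c(0, 0))
  expect_true(all(none$survival == 1))
  # with no censoring KM is the empirical survival function
  tt <- c(1, 3, 3, 7, 9)
  km2 <- kaplan_meier(tt, rep(1, 5))
  for (i in seq_along(km2$time))
    expect_equal(km2$survival[i], mean(tt > km2$time[i]))
  expect_equal(km_survival_at(km2, 0.5), 1)
  expect_equal(km_survival_at(km2, 3), 2 / 5)
})

test_that("curves match the survival package on random censored data", {
  skip_if_not_installed("survival")
  set.seed(62)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    time <- round(rexp(n, 1 / 300)) + 1
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1
    km <- kaplan_meier(time, event)
    or <- km_oracle(time, event)
    expect_equal(km$survival, or$surv, tolerance = 1e-10)
    pos <- or$surv > 0
    expect_equal(km$se[pos], or$std.err[pos], tolerance = 1e-10)
  }
})

test_that("log-rank matches a hand-worked two-group table and survdiff", {
  skip_if_not_installed("survival")
  # classic toy: group A times 1,2 (events), group B times 2,3 (events)
  time <- c(1, 2, 2, 3); event <- c(1, 1, 1, 1)
  grp <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, grp)
  # hand table: t=1 n=4 d=1 (nA=2): E_A += 1/2; t=2 n=3 d=2 (nA=1):
  # E_A += 2/3; t=3 n=1 d=1 (nA=0). O_A = 2, E_A = 7/6
  expect_equal(unname(lr$expected["A"]), 7 / 6, tolerance = 1e-12)
  expect_equal(unname(lr$observed["A"]), 2)
  sd_ref <- survival::survdiff(
    survival::Surv(time, event) ~ grp)
  expect_equal(lr$statistic, sd_ref$chisq, tolerance = 1e-10)

  set.seed(63)
  for (rep in 1:15) {
    n <- sample(10:60, 1)
    time <- round(rexp(n, 1 / 200)) + 1
    event <- rbinom(n, 1, 0.5)
    grp <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    lr <- logrank_test(time, event, grp)
    sd_ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(lr$statistic, sd_ref$chisq, tolerance = 1e-8)
    expect_equal(lr$df, length(unique(grp)) - 1)
  }
})

test_that("log-rank is invariant to rescaling the time unit", {
  set.seed(64)
  time <- round(rexp(30, 1 / 100)) + 1
  event <- rbinom(30, 1, 0.6)
  grp <- rep(c("x", "y"), 15)
  a <- logrank_test(time, event, grp)
  b <- logrank_test(time * 24, event, grp)  # days -> hours
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # two groups with identical data carry no signal
  c2 <- logrank_test(c(time, time), c(event, event),
                     rep(c("u", "v"), each = 30))
  expect_equal(c2$statistic, 0, tolerance = 1e-12)
})
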