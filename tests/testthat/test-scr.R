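test_that("half-normal detection has the right closed-form shape", {
  expect_equal(detection_prob(0, 0.3, 2500), 0.3)
  # half-height at sigma * sqrt(2 ln 2)
  expect_equal(detection_prob(2500 * sqrt(2 * log(2)), 0.3, 2500),
               0.15)
  expect_true(all(diff(detection_prob(seq(0, 1e4, 100), 0.2, 2000)) < 0))
})

test_that("single-cell single-trap conditioning collapses to certainty", {
  # one cell at distance 0, one trap, one occasion, one detection:
  # P(history | detected) = p / p = 1, so the NLL is 0
  traps <- data.frame(session = "Y1", trap_id = "T1", x = 0, y = 0,
                      location_type = "marking_site",
                      n_occasions_active = 1L)
  dets <- data.frame(session = "Y1", individual_id = "a", sex = "female",
                     trap_id = "T1", occasion = 1L)
  cd <- capture_data(dets, traps)
  grid <- structure(data.frame(x = 0, y = 0), cell = 1000, buffer = 1000,
                    area_km2 = 1, class = c("state_space", "data.frame"))
  par <- c(p0_logit = -1, log_sigma = 7)
  expect_equal(scr_nll(par, cd, grid, scr_model_spec()), 0,
               tolerance = 1e-12)
})

test_that("likelihood equals exhaustive enumeration on tiny instances", {
  set.seed(43)
  grid <- structure(data.frame(x = c(0, 2000, 0, 2000),
                               y = c(0, 0, 2000, 2000)),
                    cell = 2000, buffer = 2000, area_km2 = 16,
                    class = c("state_space", "data.frame"))
  traps <- data.frame(session = "Y1",
                      trap_id = c("T1", "T2", "T3"),
                      x = c(500, 1500, 1000), y = c(500, 1500, 200),
                      location_type = c("marking_site", "forest_road",
                                        "other"),
                      n_occasions_active = 3L)
  dets <- data.frame(
    session = "Y1",
    individual_id = c("a", "a", "a", "b", "b"),
    sex = c("female", "female", "female", "male", "male"),
    trap_id = c("T1", "T1", "T2", "T3", "T1"),
    occasion = c(1L, 3L, 2L, 1L, 2L))
  cd <- capture_data(dets, traps)
  spec <- scr_model_spec(p0 = c("sex", "type", "b"), sigma = "sex")
  par <- c(p0_logit = -0.8, p0_male = 0.5, p0_forest_road = -0.4,
           p0_other = -0.9, p0_b = 0.7, log_sigma = log(1200),
           log_sigma_male = 0.2)
  ours <- scr_nll(par, cd, grid, spec)
  oracle <- scr_nll_oracle(
    list(eta0 = -0.8, beta_male = 0.5, beta_type = c(0, -0.4, -0.9),
         beta_b = 0.7, log_sigma = log(1200), beta_sigma_male = 0.2),
    dets, traps, grid, n_occasions = 3L)
  expect_equal(ours, oracle, tolerance = 1e-10)

  # and without any covariates
  spec0 <- scr_model_spec()
  par0 <- c(p0_logit = -1.1, log_sigma = log(900))
  oracle0 <- scr_nll_oracle(
    list(eta0 = -1.1, beta_male = 0, beta_type = c(0, 0, 0), beta_b = 0,
         log_sigma = log(900), beta_sigma_male = 0),
    dets, traps, grid, n_occasions = 3L)
  expect_equal(scr_nll(par0, cd, grid, spec0), oracle0, tolerance = 1e-10)
})

test_that("a positive behavioral response raises post-capture detection", {
  lp_naive <- plogis(-1) * exp(-0.5)
  lp_resp <- plogis(-1 + 0.8) * exp(-0.5)
  expect_gt(lp_resp, lp_naive)
})

test_that("fitting recovers parameters and bounds abundance below by counts", {
  traps <- make_trap_grid(6, 6, 2500)
  grid <- build_state_space(traps, buffer = 7500, cell = 2500)
  sim <- simulate_scr_dataset(seed = 7, traps = traps, grid = grid,
                              density = 2, p0 = 0.15, sigma = 2500,
                              n_sessions = 2, n_occasions = 8)
  fit <- fit_scr(sim$data, grid)
  expect_true(fit$converged)
  ab <- fit$abundance
  expect_true(all(ab$N >= ab$n_obs))
  expect_true(all(ab$lcl_N <= ab$N & ab$N <= ab$ucl_N))
  # sigma recovered within a generous factor on one realization
  expect_equal(exp(fit$par[["log_sigma"]]), 2500, tolerance = 0.35)
})

test_that("a simulated 2x male detection odds ratio is recovered", {
  traps <- make_trap_grid(8, 8, 2500)
  grid <- build_state_space(traps, buffer = 7500, cell = 2500)
  cover <- 0; nrep <- 12
  for (r in seq_len(nrep)) {
    sim <- simulate_scr_dataset(seed = 2000 + r, traps = traps,
                                grid = grid, density = 2, p0 = 0.1,
                                sigma = 2500, n_sessions = 2,
                                n_occasions = 10,
                                beta_sex_p0 = log(2))
    fit <- fit_scr(sim$data, grid, scr_model_spec(p0 = "sex"))
    est <- fit$par[["p0_male"]]; se <- fit$se[["p0_male"]]
    if (!is.na(se) && abs(est - log(2)) <= 1.96 * se) cover <- cover + 1
  }
  expect_gte(cover, 10)
})

test_that("density is stable once the buffer exceeds three sigma", {
  traps <- make_trap_grid(8, 8, 2500)
  grid <- build_state_space(traps, buffer = 7500, cell = 2500)
  sim <- simulate_scr_dataset(seed = 77, traps = traps, grid = grid,
                              density = 2, p0 = 0.15, sigma = 2500,
                              n_sessions = 2, n_occasions = 10)
  f1 <- fit_scr(sim$data, grid, hessian = FALSE)
  wide <- build_state_space(sim$data$traps, buffer = 12500, cell = 2500)
  f2 <- fit_scr(sim$data, wide, hessian = FALSE)
  d1 <- f1$abundance$D[f1$abundance$session == "overall"]
  d2 <- f2$abundance$D[f2$abundance$session == "overall"]
  expect_lt(abs(d2 - d1) / d1, 0.02)
})

test_that("AIC weights follow the closed form and sum to one", {
  mk <- function(aic, k) structure(list(AIC = aic, n_par = k,
                                        logLik = (2 * k - aic) / 2),
                                   class = "scr_fit")
  one <- aic_table(list(only = mk(100, 3)))
  expect_equal(one$weight, 1)
  two <- aic_table(list(a = mk(100, 3), b = mk(100, 4)))
  expect_equal(two$weight, c(0.5, 0.5))
  three <- aic_table(list(a = mk(100, 3), b = mk(102, 4), c = mk(104, 5)))
  w <- exp(-c(0, 2, 4) / 2); w <- w / sum(w)
  expect_equal(three$weight, w, tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.665, 0.245, 0.090))
  expect_equal(sum(three$weight), 1, tolerance = 1e-12)
})

test_that("the seasonal filter keeps the cross-year window and is idempotent", {
  rec <- data.frame(date = as.Date(c("2020-08-14", "2020-08-15",
                                     "2020-12-31", "2021-01-10",
                                     "2021-02-15", "2021-02-16",
                                     "2021-05-01")),
                    id = letters[1:7])
  out <- seasonal_filter(rec)
  expect_setequal(out$id, c("b", "c", "d", "e"))
  expect_equal(out$session[out$id == "b"], 2020)
  expect_equal(out$session[out$id == "c"], 2020)  # Dec 31 of year Y
  expect_equal(out$session[out$id == "d"], 2020)  # Jan 10 of year Y+1
  expect_equal(out$session[out$id == "e"], 2020)
  expect_equal(seasonal_filter(out), out)
})

test_that("turnover is the redetected share of each year's individuals", {
  ys <- list(`2019` = c("a", "b", "c"), `2020` = c("b", "c", "d"),
             `2021` = c("b", "c", "d"))
  tv <- turnover(ys)
  expect_equal(tv$proportion, c(2 / 3, 1))
  expect_equal(turnover(list(`1` = "a", `2` = "b"))$proportion, 0)
  expect_equal(turnover(list(`1` = c("a", "b"),
                             `2` = c("a", "b")))$proportion, 1)
})
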