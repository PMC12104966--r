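test_that("the full synthetic bundle is byte-identical under one seed", {
  small <- list(drift = list(n_generations = 6L, ne = 8L,
                             immigrants = list(generation = 4L,
                                               n_dinaric = 3L,
                                               n_alpine = 3L,
                                               n_excluded = 1L)),
                scr = list(n_sessions = 1L, n_occasions = 4L,
                           density = 2),
                tracks = list(n_animals = 1L, n_kills = 5L),
                survival = list(n_per_group = 5L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- do.call(generate_synthetic_inputs, c(list(seed = 9L, out_dir = d1),
                                             small))
  m2 <- do.call(generate_synthetic_inputs, c(list(seed = 9L, out_dir = d2),
                                             small))
  expect_equal(m1$md5, m2$md5)
  m3 <- do.call(generate_synthetic_inputs, c(list(seed = 10L,
                                                  out_dir = d1), small))
  expect_false(all(m3$md5 == m1$md5))
})

test_that("without drift generations the sample stays at source diversity", {
  dr <- simulate_drift_population(seed = 3, n_founders = 60,
                                  n_generations = 0L)
  he <- expected_heterozygosity(dr$table)$mean
  expect_equal(he, 0.592, tolerance = 0.05)
  expect_true(all(dr$truth$generation == 0))
})

test_that("drift at small size erodes heterozygosity over generations", {
  dr <- simulate_drift_population(seed = 4, n_generations = 25L, ne = 10L)
  tab <- dr$table
  early <- genotype_table(as.data.frame(
    tab[dr$truth$generation <= 1, ]), loci = loci(tab))
  late <- genotype_table(as.data.frame(
    tab[dr$truth$generation >= 24, ]), loci = loci(tab))
  expect_gt(expected_heterozygosity(early)$mean,
            expected_heterozygosity(late)$mean)
})

test_that("immigrant alleles are disjoint and flagged with no false positives", {
  dr <- simulate_drift_population(
    seed = 5, n_generations = 8L, ne = 10L,
    immigrants = list(generation = 5L, n_dinaric = 4L, n_alpine = 2L))
  tab <- dr$table
  pre <- dr$truth$generation < 5 & dr$truth$group == "remnant"
  ref <- genotype_table(as.data.frame(tab[pre, ]), loci = loci(tab))
  cand <- genotype_table(as.data.frame(tab[!pre, ]), loci = loci(tab))
  sc <- private_alleles(ref, cand)
  flagged <- sc$flagged$individual_id[sc$flagged$f1_candidate]
  carrier_groups <- dr$truth$group[match(flagged, dr$truth$individual_id)]
  # every flagged animal is an immigrant or carries immigrant ancestry
  expect_true(all(carrier_groups %in% c("translocated", "offspring_f1",
                                        "offspring_later")))
  # all immigrants themselves are flagged (their alleles are all private)
  imm <- dr$truth$individual_id[dr$truth$group == "translocated"]
  expect_true(all(imm %in% flagged))
})

test_that("excluded immigrants never appear as parents", {
  dr <- simulate_drift_population(
    seed = 6, n_generations = 8L, ne = 10L,
    immigrants = list(generation = 5L, n_dinaric = 3L, n_alpine = 0L,
                      n_excluded = 2L))
  excluded <- dr$truth$individual_id[dr$truth$excluded]
  expect_length(excluded, 2L)
  expect_false(any(excluded %in% c(dr$truth$mother_id,
                                   dr$truth$father_id)))
})

test_that("detection-free SCR settings yield empty capture histories", {
  tr <- make_trap_grid(3, 3, 2500)
  grid <- build_state_space(tr, buffer = 5000, cell = 2500)
  sim <- simulate_scr_dataset(seed = 6, traps = tr, grid = grid,
                              density = 3, p0 = 0, n_sessions = 1)
  expect_equal(nrow(sim$data$detections), 0L)
})

test_that("per-individual detection counts match the analytic expectation", {
  tr <- make_trap_grid(4, 4, 2500)
  grid <- build_state_space(tr, buffer = 5000, cell = 2500)
  p0 <- 0.2; sigma <- 2500; K <- 6
  sim <- simulate_scr_dataset(seed = 7, traps = tr, grid = grid,
                              density = 60, p0 = p0, sigma = sigma,
                              n_sessions = 1, n_occasions = K)
  # E[detections | center s] = K * sum_j p(d_sj); average over the
  # uniform center distribution, including never-detected individuals
  half <- 1250
  exp_cell <- sapply(seq_len(nrow(grid)), function(m) {
    d2 <- (grid$x[m] - tr$x)^2 + (grid$y[m] - tr$y)^2
    K * sum(p0 * exp(-d2 / (2 * sigma^2)))
  })
  expected <- mean(exp_cell)
  n_total <- sum(sim$truth$N)
  observed <- nrow(sim$data$detections) / n_total
  expect_equal(observed, expected, tolerance = 0.15)
})

test_that("kill-free tracks rarely produce clusters at the default criteria", {
  n_with <- sum(vapply(1:20, function(s)
    nrow(find_clusters(simulate_track(seed = 400 + s, n_kills = 0,
                                      duration_days = 30)$track)) > 0,
    logical(1)))
  expect_lte(n_with / 20, 0.05)
})

test_that("survival generator supports median recovery and log-rank power", {
  # KM median at n = 500 recovers ln(2)/hazard within ~2 SE
  h <- 1 / 300
  sv <- simulate_survival(seed = 12, groups = c(g = h),
                          n_per_group = 500L, max_follow_days = 2000)
  rec <- to_survival_records(sv$periods)
  km <- kaplan_meier(rec$time, rec$event)
  med_idx <- which(km$survival <= 0.5)[1]
  med <- km$time[med_idx]
  # delta method: se(median) ~ se(S at median) / (hazard * S)
  se_med <- km$se[med_idx] / (h * 0.5)
  expect_lt(abs(med - log(2) / h), 2 * se_med)

  # a doubled hazard is detected by the log-rank test with high power
  set.seed(13)
  pow <- 0
  for (r in 1:500) {
    n <- 200
    t1 <- rexp(n, h); t2 <- rexp(n, 2 * h)
    c1 <- runif(n, 0, 600); c2 <- runif(n, 0, 600)
    p <- logrank_test(c(pmin(t1, c1), pmin(t2, c2)),
                      as.integer(c(t1 <= c1, t2 <= c2)),
                      rep(c("a", "b"), each = n))$p_value
    if (p < 0.05) pow <- pow + 1
  }
  expect_gt(pow / 500, 0.80)
})

test_that("track truth and zero-hazard survival behave as configured", {
  sim <- simulate_track(seed = 8, n_kills = 6)
  expect_equal(nrow(sim$truth), 6L)
  expect_true(all(diff(as.numeric(sim$track$timestamp)) > 0))
  expect_true(all(sim$truth$end_time >= sim$truth$time))

  sv <- simulate_survival(seed = 9, groups = c(a = 0, b = 0),
                          n_per_group = 10L)
  expect_true(all(sv$periods$end_status == "alive"))
  rec <- to_survival_records(sv$periods)
  expect_equal(sum(rec$event), 0L)
})
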