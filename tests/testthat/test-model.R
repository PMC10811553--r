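test_that("Poisson impulse train has the right mean count and is reproducible", {
  expect_length(sample_impulse_train(7, 0, seed = 1)$arrival_times, 0L)
  expect_error(sample_impulse_train(0, 1000), "positive")
  expect_error(sample_impulse_train(7, -1), "non-negative")

  a <- sample_impulse_train(7, 60000, seed = 42)$arrival_times
  b <- sample_impulse_train(7, 60000, seed = 42)$arrival_times
  expect_identical(a, b)
  expect_true(all(diff(a) > 0) && all(a >= 0) && all(a <= 60000))

  # mean count over 200 replicate seeds vs the Poisson mean 7/s * 600 s = 4200
  counts <- vapply(1:200, function(s)
    length(sample_impulse_train(7, 600000, seed = s)$arrival_times), 0L)
  se <- sqrt(4200 / 200) # Poisson variance = mean, averaged over replicates
  expect_lt(abs(mean(counts) - 4200), 3 * se)
})

test_that("node response matches the closed-form refractory/delay curves", {
  p <- pathway_params(r_min = 300, delta_r = 150, tau_r = 120,
                      d_min = 10, delta_d = 30, tau_d = 90)
  never <- list(last_activation_time = NA_real_, last_refractory_period = 0)

  # first-ever impulse: fully recovered limit
  r0 <- node_response(never, 1000, p)
  expect_false(r0$blocked)
  expect_equal(r0$R, 450, tolerance = 1e-12)
  expect_equal(r0$D, 10, tolerance = 1e-12)

  # tdia = 0: exponent collapses to e^0
  st <- list(last_activation_time = 1000, last_refractory_period = 450)
  r1 <- node_response(st, 1450, p)
  expect_equal(r1$tdia, 0)
  expect_false(r1$blocked)
  expect_equal(r1$R, 300, tolerance = 1e-12)
  expect_equal(r1$D, 40, tolerance = 1e-12)

  # tdia = tau_R: direct evaluation
  r2 <- node_response(st, 1450 + 120, p)
  expect_equal(r2$R, 300 + 150 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(r2$D, 10 + 30 * exp(-120 / 90), tolerance = 1e-12)

  # still refractory: blocked, state untouched
  r3 <- node_response(st, 1200, p)
  expect_true(r3$blocked)
  expect_identical(r3$state, st)
})

test_that("coupling refractory period is the mean of the ten shortest intervals", {
  expect_equal(coupling_refractory_from_rr(rep(600, 10)), 600)
  rr <- 300 + 10 * (0:19)
  expect_equal(coupling_refractory_from_rr(rr), 345) # mean(300..390)
  set.seed(5)
  expect_equal(coupling_refractory_from_rr(sample(rr)), 345)
  expect_error(coupling_refractory_from_rr(rep(500, 9)), "at least 10")
})

test_that("simulation respects refractoriness, conservation and the logged closed forms", {
  th <- default_truth_params()
  cpl <- coupling_config(350)

  empty <- simulate_avn(th, cpl, numeric(0))
  expect_length(empty$beat_times, 0L)
  expect_length(empty$rr, 0L)

  train <- sample_impulse_train(7, 120000, seed = 7)
  sim <- simulate_avn(th, cpl, train, log_activations = TRUE)

  # every RR interval at least the coupling refractory period
  expect_true(all(sim$rr >= cpl$refractory_period))
  # each beat traces back to one atrial impulse
  expect_lte(length(sim$beat_times), length(train$arrival_times))
  expect_equal(sim$n_fp + sim$n_sp, length(sim$beat_times))

  # recomputing the closed forms from the logged diastolic intervals
  lg <- sim$log
  fp <- lg$node <= 10
  R_expect <- ifelse(is.infinite(lg$tdia),
                     ifelse(fp, th["fp_rmin"] + th["fp_dr"],
                            th["sp_rmin"] + th["sp_dr"]),
                     ifelse(fp,
                            th["fp_rmin"] + th["fp_dr"] * (1 - exp(-lg$tdia / th["fp_taur"])),
                            th["sp_rmin"] + th["sp_dr"] * (1 - exp(-lg$tdia / th["sp_taur"]))))
  D_expect <- ifelse(is.infinite(lg$tdia),
                     ifelse(fp, th["fp_dmin"], th["sp_dmin"]),
                     ifelse(fp,
                            th["fp_dmin"] + th["fp_dd"] * exp(-lg$tdia / th["fp_taud"]),
                            th["sp_dmin"] + th["sp_dd"] * exp(-lg$tdia / th["sp_taud"])))
  expect_equal(lg$R, unname(R_expect), tolerance = 1e-12)
  expect_equal(lg$D, unname(D_expect), tolerance = 1e-12)

  # no node re-activates within its own realized refractory period
  for (nd in unique(lg$node)) {
    sub <- lg[lg$node == nd, ]
    if (nrow(sub) > 1)
      expect_true(all(diff(sub$time) >= head(sub$R, -1)))
  }
})

test_that("raising both minimal refractory periods never increases the beat count", {
  cpl <- coupling_config(300)
  train <- sample_impulse_train(7, 300000, seed = 11)
  th <- as.numeric(default_truth_params())
  counts <- vapply(c(0, 100, 200, 300), function(bump) {
    th2 <- th
    th2[c(1, 7)] <- th2[c(1, 7)] + bump
    length(simulate_avn(th2, cpl, train)$beat_times)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("an effectively blocked slow pathway reduces the model to the fast chain", {
  th <- as.numeric(default_truth_params())
  th[7] <- 1e7 # slow-pathway refractory period outlives the recording
  cpl <- coupling_config(350)
  train <- sample_impulse_train(7, 300000, seed = 3)
  sim <- simulate_avn(th, cpl, train)
  # SP conducts at most its first volley, then stays refractory
  expect_lte(sim$n_sp, 2L)
  expect_lt(sim$n_sp / (sim$n_fp + sim$n_sp), 0.01)
})

test_that("miniature network matches the independent step-by-step reference", {
  set.seed(20)
  n_match <- 0L
  for (rep in 1:100) {
    theta <- random_theta()
    cpl_rp <- runif(1, 250, 400)
    lam <- runif(1, 4, 10)
    arr <- sample_impulse_train(lam, 10000)$arrival_times
    ref <- reference_sim_1pp(arr, theta, cpl_rp)
    got <- simulate_avn(theta, coupling_config(cpl_rp), arr,
                        nodes_per_pathway = 1L)
    expect_equal(got$beat_times, ref$beat_times, tolerance = 1e-9)
    expect_identical(as.integer(got$beat_source), ref$beat_source)
    n_match <- n_match + 1L
  }
  expect_identical(n_match, 100L)
})

test_that("RR series CSV dialects round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  rr <- c(500, 520, 480)
  write_rr_csv(rr, f)
  expect_equal(read_rr_csv(f)$rr, rr)
  write.csv(data.frame(beat_time_ms = c(0, 500, 1020, 1500)), f,
            row.names = FALSE)
  expect_equal(read_rr_csv(f)$rr, c(500, 520, 480))
})
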