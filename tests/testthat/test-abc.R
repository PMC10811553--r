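# forge a ranked GA population around a centre vector
forge_ga_pop <- function(centre, n = 30L, spread = 20, fitness = NULL,
                         seed = 1) {
  set.seed(seed)
  b <- avn_bounds("GA")
  v <- t(vapply(seq_len(n), function(i) {
    clip_to <- pmin(pmax(centre + rnorm(12, 0, spread), b$lower), b$upper)
    clip_to
  }, numeric(12)))
  colnames(v) <- theta_names()
  if (is.null(fitness)) fitness <- sort(runif(n, 0.1, 2))
  structure(list(vectors = v, fitness = fitness, segment_index = 1L),
            class = "ga_population")
}

test_that("thresholds are the errors of fixed GA ranks and are non-increasing", {
  pop <- forge_ga_pop(as.numeric(default_truth_params()), n = 300L,
                      fitness = as.numeric(1:300))
  sched <- thresholds_from_ga(pop)
  expect_equal(as.numeric(sched), c(10, 8, 5, 3, 1, 1, 1, 1))
  expect_true(all(diff(as.numeric(sched)) <= 0))
  # the final threshold is the best GA error
  expect_equal(sched[[8]], pop$fitness[1])
  small <- forge_ga_pop(as.numeric(default_truth_params()), n = 8L,
                        fitness = as.numeric(1:8))
  expect_error(thresholds_from_ga(small), "at least 10")
})

test_that("particle initialization draws around the five fittest GA vectors", {
  centre <- as.numeric(default_truth_params())
  pop <- forge_ga_pop(centre, n = 30L)
  init <- initialize_particles(pop, n_particles = 100L, seed = 2)
  expect_identical(dim(init$particles), c(100L, 12L))
  expect_equal(init$weights, rep(0.01, 100))
  b <- avn_bounds("ABC")
  expect_true(all(sweep(init$particles, 2, b$lower, ">=")) &&
                all(sweep(init$particles, 2, b$upper, "<=")))
  expect_identical(init$iteration, 1L)

  # zero spread in the top 25 collapses every draw onto the GA means
  degen <- pop
  degen$vectors <- matrix(centre, 30L, 12L, byrow = TRUE,
                          dimnames = list(NULL, theta_names()))
  init0 <- initialize_particles(degen, n_particles = 100L, seed = 3)
  expect_true(all(apply(init0$particles, 1, function(r)
    all(r == centre))))

  # sampling oracle: block means approach their GA means at 1/sqrt(n) rate.
  # The centre sits far from every box face (no rejection truncation) and
  # has clearly ordered refractory periods (no canonical label swaps).
  mid_centre <- c(700, 500, 260, 20, 50, 260,   # fast block, rmin 700
                  300, 500, 260, 42, 50, 260)   # slow block, rmin 300
  mid <- forge_ga_pop(mid_centre, n = 30L, spread = 2, seed = 14)
  big <- initialize_particles(mid, n_particles = 5000L, seed = 4)
  sig <- cov(mid$vectors[1:25, ])
  for (u in 1:5) {
    blk <- big$particles[((u - 1) * 1000 + 1):(u * 1000), ]
    se <- sqrt(diag(sig) / 1000)
    expect_true(all(abs(colMeans(blk) - mid$vectors[u, ]) <=
                      3.5 * pmax(se, 1e-9)))
  }
})

test_that("inverse-mixture weights match a direct density evaluation", {
  centre <- as.numeric(default_truth_params())
  pop <- forge_ga_pop(centre, n = 30L)
  init <- initialize_particles(pop, n_particles = 20L, seed = 5)
  # put all ancestral mass on one particle
  init$weights <- c(1, rep(0, 19))
  set.seed(6)
  nxt <- pmc_iteration(init, threshold = 1,
                       distance_fn = function(theta) 0.5)
  # w_v proportional to 1 / N(theta_anc | theta_v, Sigma_kernel)
  anc <- init$particles[1, ]
  dens <- vapply(seq_len(20), function(v) {
    x <- anc - nxt$particles[v, ]
    S <- init$kernel_cov
    exp(-0.5 * drop(x %*% solve(S, x))) /
      sqrt((2 * pi)^12 * det(S))
  }, 0)
  expect_equal(nxt$weights, (1 / dens) / sum(1 / dens), tolerance = 1e-8)
  expect_equal(sum(nxt$weights), 1)
  expect_true(all(nxt$errors < 1))
})

test_that("proposals outside the ABC box are rejected before simulation", {
  b <- avn_bounds("ABC")
  corner <- b$upper - 0.5 * (b$upper - b$lower) * 1e-3 # hugging the bound
  particles <- matrix(rep(corner, 25), 25, 12, byrow = TRUE,
                      dimnames = list(NULL, theta_names()))
  particles <- particles + matrix(rnorm(25 * 12, 0, 1), 25, 12)
  particles <- t(apply(particles, 1, pmin, b$upper))
  init <- structure(list(particles = particles,
                         weights = rep(1 / 25, 25),
                         errors = rep(NA_real_, 25),
                         iteration = 1L,
                         kernel_cov = diag(rep(100, 12))),
                    class = "particle_population")
  seen_out_of_bounds <- FALSE
  set.seed(7)
  nxt <- pmc_iteration(init, threshold = 1, distance_fn = function(theta) {
    if (!all(theta >= b$lower & theta <= b$upper))
      seen_out_of_bounds <<- TRUE
    0.5
  }, bounds = b)
  expect_false(seen_out_of_bounds)
  expect_true(all(sweep(nxt$particles, 2, b$lower, ">=")) &&
                all(sweep(nxt$particles, 2, b$upper, "<=")))
  expect_gt(nxt$n_proposals, 25) # some proposals had to be discarded
})

test_that("the sampler stalls loudly instead of looping forever", {
  centre <- as.numeric(default_truth_params())
  pop <- forge_ga_pop(centre, n = 30L)
  init <- initialize_particles(pop, n_particles = 10L, seed = 8)
  expect_error(
    pmc_iteration(init, threshold = 1e-9,
                  distance_fn = function(theta) 1, max_proposals = 200),
    class = "abc_stall")
})

test_that("PMC recovers the analytic posterior mean on a conjugate toy", {
  # Gaussian mean inference: prior N(0, 5^2), one observation ybar = 1.5
  # with known sd 0.5; simulator draws ybar_sim ~ N(theta, 0.5^2) and the
  # distance is |ybar_sim - ybar|. As the threshold shrinks the sampler
  # targets the conjugate posterior.
  mu0 <- 0; s0 <- 5; s <- 0.5; ybar <- 1.5
  post_mean <- ybar * s0^2 / (s0^2 + s^2)
  post_var <- 1 / (1 / s0^2 + 1 / s^2)

  set.seed(9)
  np <- 100L
  particles <- matrix(rnorm(np, mu0, s0), ncol = 1,
                      dimnames = list(NULL, "theta"))
  init <- structure(list(particles = particles,
                         weights = rep(1 / np, np),
                         errors = rep(NA_real_, np),
                         iteration = 1L,
                         kernel_cov = 2 * cov(particles)),
                    class = "particle_population")
  bounds <- list(lower = -50, upper = 50)
  fin <- abc_pmc(init,
                 thresholds = c(3, 1.5, 0.8, 0.4, 0.25, 0.15),
                 distance_fn = function(th) abs(rnorm(1, th, s) - ybar),
                 bounds = bounds,
                 prior_density = function(th) dnorm(th, mu0, s0))
  w <- fin$weights
  m <- sum(w * fin$particles[, 1])
  ess <- 1 / sum(w^2)
  mc_se <- sqrt(post_var / ess)
  expect_lt(abs(m - post_mean), 3 * mc_se)
  expect_equal(sum(w), 1)
  expect_true(all(fin$errors < 0.15))
})

test_that("widening the thresholds widens the particle cloud", {
  mu0 <- 0; s0 <- 5; s <- 0.5; ybar <- 1.5
  sched <- c(3, 1.5, 0.8, 0.4, 0.25, 0.15)
  run_toy <- function(thresholds, seed) {
    set.seed(seed)
    np <- 60L
    particles <- matrix(rnorm(np, mu0, s0), ncol = 1)
    init <- structure(list(particles = particles,
                           weights = rep(1 / np, np),
                           errors = rep(NA_real_, np), iteration = 1L,
                           kernel_cov = 2 * cov(particles)),
                      class = "particle_population")
    fin <- abc_pmc(init, thresholds,
                   distance_fn = function(th) abs(rnorm(1, th, s) - ybar),
                   bounds = list(lower = -50, upper = 50))
    var(fin$particles[, 1])
  }
  wins <- vapply(1:5, function(seed)
    run_toy(sched * 10, seed) >= run_toy(sched, seed + 100), TRUE)
  expect_gte(sum(wins), 4L) # stochastic: allow one inversion
})

test_that("a fixed master seed replays the AV-node ABC stage exactly", {
  set.seed(10)
  seg <- make_synth_segment(duration = 60000)
  # rank a small GA population by real simulated errors so the thresholds
  # are achievable
  pop <- forge_ga_pop(as.numeric(default_truth_params()), n = 30L,
                      spread = 10, seed = 11)
  hist <- poincare_histogram(seg$rr)
  cpl <- coupling_config(350)
  fit <- vapply(seq_len(30), function(i) {
    sim <- simulate_avn(pop$vectors[i, ], cpl,
                        sample_impulse_train(7, 60000))
    epsilon_error(hist, poincare_histogram(sim$rr))$epsilon
  }, 0)
  ord <- order(fit)
  pop$vectors <- pop$vectors[ord, ]; pop$fitness <- fit[ord]

  a <- run_abc(pop, seg, cpl, n_particles = 10L, seed = 123)
  b <- run_abc(pop, seg, cpl, n_particles = 10L, seed = 123)
  expect_identical(a$particles, b$particles)
  expect_identical(a$errors, b$errors)
  expect_equal(sum(a$weights), 1)
  # every final particle beats the best GA vector
  expect_true(all(a$errors < pop$fitness[1]))
  bx <- avn_bounds("ABC")
  expect_true(all(sweep(a$particles, 2, bx$lower, ">=")) &&
                all(sweep(a$particles, 2, bx$upper, "<=")))
})
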