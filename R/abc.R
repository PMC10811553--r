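# multivariate normal helpers via Cholesky (hot path of the PMC loop)
chol_safe <- function(sigma, ranges) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    sigma <- sigma + diag(1e-6 * ranges^2, nrow(sigma))
    ch <- chol(sigma)
  }
  ch
}

rmvn_chol <- function(mu, ch) {
  drop(mu + rnorm(length(mu)) %*% ch)
}

# density of each row of X under N(mu, Sigma) with Sigma = t(ch) %*% ch
dmvn_chol <- function(X, mu, ch) {
  d <- ncol(X)
  z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  logdet <- 2 * sum(log(diag(ch)))
  exp(-0.5 * colSums(z^2) - 0.5 * (d * log(2 * pi) + logdet))
}

#' Error thresholds for the ABC iterations from the GA population
#'
#' The acceptance threshold of PMC iteration j is the Poincare error of a
#' fixed rank in the final GA population: ranks 10, 8, 5, 3 for iterations
#' 1-4 and rank 1 (the best GA vector) for iterations 5-8. The schedule is
#' non-increasing, and because the final threshold is the best GA error,
#' every particle of the final population beats the fittest GA vector.
#'
#' @param ga_pop Ranked \code{ga_population} with evaluated fitness.
#' @return Numeric vector \code{T_1..T_8} of class \code{abc_thresholds}.
#' @export
thresholds_from_ga <- function(ga_pop) {
  fit <- ga_pop$fitness
  if (length(fit) < 10L || any(is.na(fit[1:10])))
    stop("need a ranked GA population with at least 10 evaluated vectors")
  if (is.unsorted(fit[1:10]))
    stop("GA fitness must be sorted ascending")
  structure(fit[c(10L, 8L, 5L, 3L, 1L, 1L, 1L, 1L)], class = "abc_thresholds")
}

#' Initialize the ABC particle population from the GA result
#'
#' Particles are drawn in equal shares from five normal distributions
#' centred on the five fittest GA vectors, with a common covariance equal to
#' the covariance of the 25 fittest GA vectors. Draws falling outside the
#' ABC box are redrawn. Weights start uniform, and the first transition
#' kernel covariance is twice the covariance of the initial particles.
#'
#' @param ga_pop Ranked \code{ga_population} with >= 25 vectors.
#' @param n_particles Number of particles (divisible by 5; default 100).
#' @param bounds ABC box from [avn_bounds("ABC")].
#' @param seed Integer seed.
#' @return List of class \code{particle_population} with \code{particles}
#'   (matrix), \code{weights} (uniform simplex), \code{errors} (NA at
#'   initialization), \code{iteration = 1}, and \code{kernel_cov}.
#' @export
initialize_particles <- function(ga_pop, n_particles = 100L,
                                 bounds = avn_bounds("ABC"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- ga_pop$vectors
  if (nrow(v) < 25L) stop("need at least 25 ranked GA vectors")
  n_particles <- as.integer(n_particles)
  if (n_particles %% 5L != 0L) stop("n_particles must be divisible by 5")
  sigma_init <- cov(v[1:25, , drop = FALSE])
  ranges <- bounds$upper - bounds$lower
  zero_cov <- all(sigma_init == 0)
  ch <- if (zero_cov) NULL else chol_safe(sigma_init, ranges)
  per <- n_particles %/% 5L
  parts <- matrix(NA_real_, n_particles, 12L)
  row <- 1L
  for (u in 1:5) {
    mu <- v[u, ]
    for (q in seq_len(per)) {
      if (zero_cov) {
        parts[row, ] <- canonicalize_theta(mu)
      } else {
        repeat {
          cand <- rmvn_chol(mu, ch)
          if (in_bounds(cand, bounds)) break
        }
        parts[row, ] <- canonicalize_theta(cand)
      }
      row <- row + 1L
    }
  }
  colnames(parts) <- theta_names()
  kc <- 2 * cov(parts)
  structure(list(particles = parts,
                 weights = rep(1 / n_particles, n_particles),
                 errors = rep(NA_real_, n_particles),
                 iteration = 1L,
                 kernel_cov = kc),
            class = "particle_population")
}

#' One population-Monte-Carlo iteration
#'
#' Repeats until \code{n_particles} acceptances: an ancestor is sampled by
#' weight from the previous population, perturbed with the Gaussian
#' transition kernel \code{N(0, kernel_cov)}, rejected outright when outside
#' the ABC box, otherwise scored with one fresh simulation and accepted when
#' its error is below the iteration threshold. Accepted particles receive
#' the inverse-mixture weights
#' \deqn{w_v \propto \Big[\sum_k w_k^{prev}\,
#'   N(\theta_k^{prev} \mid \theta_v, \Sigma_{prev})\Big]^{-1},}
#' normalized to a simplex, and the kernel covariance is updated to twice
#' the covariance of the accepted particles.
#'
#' @param prev \code{particle_population} of the previous iteration.
#' @param threshold Acceptance threshold for this iteration.
#' @param distance_fn Function \code{theta -> error}; for the AV-node
#'   problem this wraps one model simulation plus the Poincare error, but
#'   any simulator/distance pair can be plugged in.
#' @param bounds Box prior support.
#' @param max_proposals Stall guard: error (class \code{abc_stall}) when the
#'   iteration uses this many proposals without filling the population.
#' @param prior_density Optional function \code{theta -> density} entering
#'   the weight numerator; the default (NULL) is a uniform prior on the box,
#'   for which the numerator is constant and drops out.
#' @return The next \code{particle_population} (errors recorded, iteration
#'   advanced, \code{n_proposals} attached).
#' @export
pmc_iteration <- function(prev, threshold, distance_fn,
                          bounds = avn_bounds("ABC"), max_proposals = 1e5,
                          prior_density = NULL) {
  stopifnot(threshold > 0)
  np <- nrow(prev$particles)
  d <- ncol(prev$particles)
  ranges <- bounds$upper - bounds$lower
  ch <- chol_safe(prev$kernel_cov, ranges)
  acc <- matrix(NA_real_, np, d)
  errs <- numeric(np)
  proposals <- 0L
  n_acc <- 0L
  # proposals are iid given the previous population, so they are drawn in
  # batches: ancestors by weight, one Gaussian perturbation each, the
  # out-of-bounds ones discarded without simulation
  batch <- 256L
  while (n_acc < np) {
    if (proposals >= max_proposals)
      stop(structure(class = c("abc_stall", "error", "condition"),
                     list(message = sprintf(
                       "ABC stalled: %d proposals, %d/%d acceptances at threshold %.4g",
                       proposals, n_acc, np, threshold),
                       call = sys.call())))
    nb <- min(batch, max_proposals - proposals)
    anc <- sample.int(np, nb, replace = TRUE, prob = prev$weights)
    cand <- prev$particles[anc, , drop = FALSE] +
      matrix(rnorm(nb * d), nb, d) %*% ch
    proposals <- proposals + nb
    ok <- cand >= matrix(bounds$lower, nb, d, byrow = TRUE) &
      cand <= matrix(bounds$upper, nb, d, byrow = TRUE)
    for (i in which(rowSums(ok) == d)) {
      e <- distance_fn(cand[i, ])
      if (is.finite(e) && e < threshold) {
        n_acc <- n_acc + 1L
        acc[n_acc, ] <- cand[i, ]
        errs[n_acc] <- e
        if (n_acc == np) break
      }
    }
  }
  colnames(acc) <- colnames(prev$particles)
  w <- vapply(seq_len(np), function(v) {
    num <- if (is.null(prior_density)) 1 else prior_density(acc[v, ])
    num / sum(prev$weights * dmvn_chol(prev$particles, acc[v, ], ch))
  }, 0)
  w <- w / sum(w)
  structure(list(particles = acc, weights = w, errors = errs,
                 iteration = prev$iteration + 1L,
                 kernel_cov = 2 * cov(acc),
                 n_proposals = proposals),
            class = "particle_population")
}

#' Generic ABC population Monte Carlo
#'
#' Runs [pmc_iteration()] over a threshold schedule starting from an
#' initialized population. The simulator and distance enter only through
#' \code{distance_fn}, so the sampler can be checked against analytically
#' tractable problems.
#'
#' @param init Initial \code{particle_population}.
#' @param thresholds Thresholds for the successive iterations (one per
#'   iteration actually run).
#' @param distance_fn Function \code{theta -> error}.
#' @param bounds Box prior support.
#' @param max_proposals Per-iteration stall guard.
#' @param prior_density Optional prior density for the weight numerator
#'   (see [pmc_iteration()]).
#' @return Final \code{particle_population}; total proposal count in
#'   \code{total_proposals}.
#' @export
abc_pmc <- function(init, thresholds, distance_fn,
                    bounds = avn_bounds("ABC"), max_proposals = 1e5,
                    prior_density = NULL) {
  pop <- init
  total <- 0L
  for (T_j in thresholds) {
    pop <- pmc_iteration(pop, T_j, distance_fn, bounds, max_proposals,
                         prior_density)
    total <- total + pop$n_proposals
  }
  pop$total_proposals <- total
  pop
}

#' Refine a GA result into posterior particles for one segment
#'
#' Full ABC stage for one RR segment: thresholds from the ranked GA
#' population, particle initialization around the five fittest GA vectors,
#' then PMC iterations 2..8 (iteration 1 is the initialization itself, so
#' the first threshold of the schedule is never used as an acceptance gate).
#' Each proposal is scored by one fresh stochastic simulation of the
#' segment's duration at the segment's atrial rate.
#'
#' @param ga_pop Ranked \code{ga_population} for the segment.
#' @param segment Included segment (provides the observed histogram, the
#'   rate and the duration).
#' @param coupling Coupling-node configuration.
#' @param n_particles Particles (default 100).
#' @param bounds ABC box.
#' @param seed Integer seed.
#' @param max_proposals Per-iteration stall guard.
#' @return Final \code{particle_population} (posterior sample for the
#'   segment; every error is below the best GA error).
#' @export
run_abc <- function(ga_pop, segment, coupling, n_particles = 100L,
                    bounds = avn_bounds("ABC"), seed = NULL,
                    max_proposals = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  target_hist <- poincare_histogram(segment$rr)
  dur <- segment$end - segment$start
  lambda <- segment$lambda_hat
  distance_fn <- function(theta) {
    train <- sample_impulse_train(lambda, dur)
    sim <- simulate_avn(theta, coupling, train)
    sim_hist <- poincare_histogram(sim$rr)
    if (sim_hist$n_pairs == 0L) return(Inf)
    epsilon_error(target_hist, sim_hist)$epsilon
  }
  sched <- thresholds_from_ga(ga_pop)
  init <- initialize_particles(ga_pop, n_particles, bounds)
  abc_pmc(init, sched[-1L], distance_fn, bounds, max_proposals)
}

#' Write a particle population to CSV
#'
#' @param pop \code{particle_population}.
#' @param path CSV path (12 parameter columns + weight + epsilon).
#' @return The path, invisibly.
#' @export
write_particles_csv <- function(pop, path) {
  d <- as.data.frame(pop$particles)
  d$weight <- pop$weights
  d$epsilon <- pop$errors
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
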