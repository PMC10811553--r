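#' Genetic-algorithm configuration
#'
#' Defaults for the problem-specific dynamic GA: 300 parameter vectors,
#' tournament selection of size 2, two-point crossover with probability 0.8,
#' creep mutation (per-gene probability 0.2, Gaussian step with sd equal to
#' 5 % of the gene's search range), replacement of the least-fit 10 % by
#' fresh latin-hypercube immigrants each generation, and elitism of one. The
#' per-segment generation budget is dynamic, between 2 and 7, driven by the
#' Poincare-histogram difference between consecutive segments; the first
#' (cold-start) segment gets a larger fixed budget.
#'
#' @param population_size Number of parameter vectors.
#' @param tournament_size Tournament size for selection.
#' @param crossover_probability Probability of two-point crossover per pair.
#' @param creep_rate Per-gene mutation probability.
#' @param creep_sd_fraction Mutation step sd as a fraction of the gene range.
#' @param immigrant_fraction Fraction of the population replaced by fresh
#'   latin-hypercube samples each generation.
#' @param min_generations,max_generations Dynamic budget limits.
#' @param first_segment_generations Budget for the cold-start segment.
#' @return List of class \code{ga_config}.
#' @export
ga_config <- function(population_size = 300L, tournament_size = 2L,
                      crossover_probability = 0.8, creep_rate = 0.2,
                      creep_sd_fraction = 0.05, immigrant_fraction = 0.1,
                      min_generations = 2L, max_generations = 7L,
                      first_segment_generations = 30L) {
  stopifnot(min_generations <= max_generations,
            crossover_probability >= 0, crossover_probability <= 1,
            creep_rate >= 0, creep_rate <= 1,
            immigrant_fraction >= 0, immigrant_fraction <= 1)
  structure(list(population_size = as.integer(population_size),
                 tournament_size = as.integer(tournament_size),
                 crossover_probability = crossover_probability,
                 creep_rate = creep_rate,
                 creep_sd_fraction = creep_sd_fraction,
                 immigrant_fraction = immigrant_fraction,
                 min_generations = as.integer(min_generations),
                 max_generations = as.integer(max_generations),
                 first_segment_generations = as.integer(first_segment_generations)),
            class = "ga_config")
}

lhs_sample <- function(n, bounds) {
  u <- lhs::randomLHS(n, 12L)
  sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower, "+")
}

#' Initialize a GA population by latin hypercube sampling
#'
#' @param bounds GA parameter box from [avn_bounds("GA")].
#' @param config A [ga_config()].
#' @param seed Integer seed.
#' @return List of class \code{ga_population} with \code{vectors} (matrix,
#'   one row per parameter vector, canonical column order), \code{fitness}
#'   (NA until evaluated; kept sorted ascending after evolution) and
#'   \code{segment_index}.
#' @export
initialize_population <- function(bounds = avn_bounds("GA"),
                                  config = ga_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- lhs_sample(config$population_size, bounds)
  colnames(v) <- theta_names()
  structure(list(vectors = v,
                 fitness = rep(NA_real_, config$population_size),
                 segment_index = NA_integer_),
            class = "ga_population")
}

#' Dynamic generation budget from the segment-to-segment histogram change
#'
#' The number of generations spent on a segment grows with the
#' Poincare-histogram difference to the previous segment, relative to the
#' running median of past differences:
#' \code{g = clip(round(2 + 5 * dP / (2 * median(past dP))), 2, 7)}. The rule
#' is monotone in \code{dP}, scale-free, returns the minimum budget for an
#' unchanged histogram, and saturates at 7 once \code{dP} reaches twice the
#' running median.
#'
#' @param delta_p Histogram difference between the previous segment and this
#'   one (non-negative).
#' @param history Numeric vector of past differences (the median is taken
#'   over it; when empty, \code{delta_p} itself seeds the median).
#' @param config A [ga_config()] for the budget limits.
#' @return Integer generation count.
#' @export
generations_for_segment <- function(delta_p, history = numeric(0),
                                    config = ga_config()) {
  stopifnot(delta_p >= 0)
  med <- if (length(history)) median(history) else delta_p
  g <- if (med <= 0) {
    if (delta_p > 0) config$max_generations else config$min_generations
  } else {
    round(2 + 5 * delta_p / (2 * med))
  }
  as.integer(min(max(g, config$min_generations), config$max_generations))
}

# fitness = Poincare error of one fresh stochastic simulation per vector
ga_fitness <- function(theta, target_hist, lambda, duration, coupling) {
  train <- sample_impulse_train(lambda, duration)
  sim <- simulate_avn(theta, coupling, train)
  sim_hist <- poincare_histogram(sim$rr)
  if (sim_hist$duration <= 0 || sim_hist$n_pairs == 0L) return(Inf)
  epsilon_error(target_hist, sim_hist)$epsilon
}

two_point_crossover <- function(a, b) {
  cuts <- sort(sample.int(11L, 2L)) # cut after genes cuts[1], cuts[2]
  mid <- (cuts[1] + 1):cuts[2]
  ca <- a; cb <- b
  ca[mid] <- b[mid]; cb[mid] <- a[mid]
  list(ca, cb)
}

#' Evolve a GA population on one segment
#'
#' Each generation: every vector is scored by the Poincare error of one
#' fresh stochastic simulation against the segment histogram (the elite's
#' cached fitness is reused mid-run); parents are chosen by tournament;
#' two-point crossover and creep mutation (clipped to the GA box) produce
#' offspring; the least-fit fraction is replaced by fresh latin-hypercube
#' immigrants; the best vector survives unchanged. The final generation
#' re-scores the whole population, elite included, so the returned fitness
#' values are identically distributed fresh draws — the ABC stage derives
#' its acceptance thresholds from them. The returned \code{trace} records
#' the best error seen so far (non-increasing) and the per-generation
#' median.
#'
#' @param pop A \code{ga_population}.
#' @param target_hist \code{poincare_hist} of the observed segment.
#' @param lambda Atrial rate for the segment (impulses/s).
#' @param duration Simulated duration per fitness evaluation (ms).
#' @param coupling Coupling-node configuration.
#' @param generations Number of generations (>= 1).
#' @param config A [ga_config()].
#' @param bounds GA box.
#' @param seed Integer seed.
#' @return The evolved \code{ga_population}, ranked by ascending fitness.
#' @export
evolve <- function(pop, target_hist, lambda, duration, coupling,
                   generations, config = ga_config(),
                   bounds = avn_bounds("GA"), seed = NULL) {
  stopifnot(generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  # work on the canonical label half-space (see canonicalize_theta): the
  # pathway-swap symmetry otherwise splits the population across two mirror
  # modes of equal fitness
  v <- canonicalize_theta(pop$vectors)
  n <- nrow(v)
  fit <- rep(NA_real_, n)
  rng <- bounds$upper - bounds$lower
  trace_best <- trace_median <- numeric(generations)
  best_so_far <- Inf

  for (g in seq_len(generations)) {
    # the carried elite's cached fitness is reused mid-run, but the last
    # generation re-scores everything: the returned fitness values must be
    # identically distributed fresh draws, because the ABC stage reads its
    # acceptance thresholds off them (a cached running minimum would be an
    # extreme order statistic no proposal could realistically beat)
    final_gen <- g == generations
    for (i in seq_len(n)) {
      if (!final_gen && !is.na(fit[i])) next
      fit[i] <- ga_fitness(v[i, ], target_hist, lambda, duration, coupling)
    }
    ord <- order(fit)
    v <- v[ord, , drop = FALSE]
    fit <- fit[ord]
    best_so_far <- min(best_so_far, fit[1L])
    trace_best[g] <- best_so_far
    trace_median[g] <- median(fit[is.finite(fit)])
    if (final_gen) break

    # selection + variation
    pick <- function() {
      cand <- sample.int(n, config$tournament_size)
      cand[which.min(fit[cand])]
    }
    child <- matrix(NA_real_, n, 12L)
    i <- 1L
    while (i <= n) {
      p1 <- v[pick(), ]; p2 <- v[pick(), ]
      if (runif(1) < config$crossover_probability) {
        cr <- two_point_crossover(p1, p2)
        p1 <- cr[[1]]; p2 <- cr[[2]]
      }
      child[i, ] <- p1
      if (i + 1L <= n) child[i + 1L, ] <- p2
      i <- i + 2L
    }
    # creep mutation
    mut <- matrix(runif(n * 12L) < config$creep_rate, n, 12L)
    step <- matrix(rnorm(n * 12L), n, 12L) *
      matrix(rng * config$creep_sd_fraction, n, 12L, byrow = TRUE)
    child[mut] <- child[mut] + step[mut]
    child <- t(apply(child, 1L, clip_to_bounds, bounds = bounds))
    # immigration into the worst slots (children are unranked; use the tail)
    n_imm <- floor(config$immigrant_fraction * n)
    if (n_imm > 0)
      child[(n - n_imm + 1L):n, ] <- lhs_sample(n_imm, bounds)
    child <- canonicalize_theta(child)
    # elitism: best-so-far survives with its cached fitness
    child[1L, ] <- v[1L, ]
    elite_fit <- fit[1L]
    v <- child
    fit <- rep(NA_real_, n)
    fit[1L] <- elite_fit
  }
  colnames(v) <- theta_names()
  pop$vectors <- v
  pop$fitness <- fit
  pop$trace <- data.frame(generation = seq_len(generations),
                          best = trace_best, median = trace_median)
  pop
}

#' Run the dynamic GA over all included segments of a recording
#'
#' The population is warm-started: each segment continues from the previous
#' included segment's final population. The first included segment is
#' initialized by latin hypercube sampling and given the cold-start budget;
#' later segments get 2-7 generations from [generations_for_segment()]
#' driven by the consecutive-segment histogram difference. Excluded
#' segments are skipped without touching the carried state.
#'
#' @param segments Segment list from [preprocess_recording()] (rates
#'   attached).
#' @param coupling Coupling-node configuration.
#' @param config A [ga_config()].
#' @param bounds GA box.
#' @param seed Integer master seed.
#' @return List with one entry per included segment: the ranked
#'   \code{ga_population} (with \code{segment_index}, \code{generations} and
#'   \code{delta_p} recorded).
#' @export
run_over_segments <- function(segments, coupling, config = ga_config(),
                              bounds = avn_bounds("GA"), seed = 1L) {
  set.seed(seed)
  out <- list()
  pop <- NULL
  prev_hist <- NULL
  dp_history <- numeric(0)
  for (s in segments) {
    if (!s$included) next
    hist <- poincare_histogram(s$rr)
    if (is.null(pop)) {
      pop <- initialize_population(bounds, config)
      gens <- config$first_segment_generations
      dp <- NA_real_
    } else {
      dp <- segment_difference(prev_hist, hist)
      gens <- generations_for_segment(dp, dp_history, config)
      dp_history <- c(dp_history, dp)
    }
    dur <- s$end - s$start
    pop <- evolve(pop, hist, s$lambda_hat, dur, coupling, gens,
                  config, bounds)
    pop$segment_index <- s$index
    pop$generations <- gens
    pop$delta_p <- dp
    out[[length(out) + 1L]] <- pop
    prev_hist <- hist
  }
  out
}
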