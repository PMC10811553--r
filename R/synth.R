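#' Physiologically plausible default ground-truth parameters
#'
#' A parameter vector inside the GA box producing a fast pathway with a long
#' refractory period and short per-node delay, and a dominant slow pathway
#' with a shorter refractory period and longer delay, in line with invasive
#' dual-pathway measurements and the magnitudes the fitted model recovers
#' from Holter data (fast-pathway refractory periods around 0.7-1 s,
#' slow-pathway around 0.3-0.4 s, total slow-pathway delay around 0.5 s).
#'
#' @return An [avn_params()] vector.
#' @export
default_truth_params <- function() {
  avn_params(
    fp = pathway_params(r_min = 700, delta_r = 250, tau_r = 120,
                        d_min = 6, delta_d = 15, tau_d = 120),
    sp = pathway_params(r_min = 300, delta_r = 120, tau_r = 100,
                        d_min = 45, delta_d = 35, tau_d = 100))
}

#' Ground-truth parameter trajectory over a recording
#'
#' Produces one parameter vector per 5-min block (the stepping unit of the
#' 50 %-overlap segmentation). Profiles: \code{stationary} keeps theta
#' constant; \code{diurnal} modulates the refractory parameters up and the
#' delay parameters down at night with a 24-h sinusoid (trough of the
#' refractory modulation at 14:00, peak at 02:00-06:00, matching the
#' direction seen in patients); \code{switching} jumps between the base
#' value and a scaled copy at given blocks, emulating patients with high
#' short-term variability. Values are clipped to the GA box (with a warning
#' if clipping occurs).
#'
#' @param n_blocks Number of 5-min blocks.
#' @param profile One of "stationary", "diurnal", "switching".
#' @param base Base parameter vector (default [default_truth_params()]).
#' @param amplitude Relative modulation amplitude for the diurnal profile
#'   (default 0.15) or the relative jump size for switching (default 0.3).
#' @param jump_blocks Block indices at which the switching profile toggles.
#' @param recording_start_hour Clock hour of block 1 (default 8).
#' @return Matrix, one row per block, canonical column order.
#' @export
generate_theta_trajectory <- function(n_blocks,
                                      profile = c("stationary", "diurnal",
                                                  "switching"),
                                      base = default_truth_params(),
                                      amplitude = NULL,
                                      jump_blocks = NULL,
                                      recording_start_hour = 8) {
  profile <- match.arg(profile)
  base <- as.numeric(as_avn_params(base))
  traj <- matrix(base, n_blocks, 12L, byrow = TRUE)
  rp_cols <- c(1:3, 7:9) # rmin, dr, taur of both pathways
  cd_cols <- c(4:6, 10:12)
  if (profile == "diurnal") {
    if (is.null(amplitude)) amplitude <- 0.15
    hour <- (recording_start_hour + (seq_len(n_blocks) - 1) / 12) %% 24
    # cosine peaking at 04:00 (night), trough at 16:00
    mod <- cos(2 * pi * (hour - 4) / 24)
    traj[, rp_cols] <- traj[, rp_cols] * (1 + amplitude * mod)
    traj[, cd_cols] <- traj[, cd_cols] * (1 - amplitude * mod)
  } else if (profile == "switching") {
    if (is.null(amplitude)) amplitude <- 0.3
    if (is.null(jump_blocks)) jump_blocks <- ceiling(n_blocks / 2)
    state <- cumsum(seq_len(n_blocks) %in% jump_blocks) %% 2 == 1
    traj[state, rp_cols] <- traj[state, rp_cols] * (1 + amplitude)
  }
  b <- avn_bounds("GA")
  clipped <- traj < matrix(b$lower, n_blocks, 12, byrow = TRUE) |
    traj > matrix(b$upper, n_blocks, 12, byrow = TRUE)
  if (any(clipped)) {
    warning("trajectory clipped to the GA parameter box")
    traj <- t(apply(traj, 1, clip_to_bounds, bounds = b))
  }
  colnames(traj) <- theta_names()
  traj
}

#' Synthetic atrial-fibrillatory-rate trend
#'
#' Mean-reverting (AR(1)/Ornstein-Uhlenbeck-style) minute series around a
#' physiological AF atrial rate, with occasional missing minutes.
#'
#' @param n_minutes Trend length.
#' @param mean_afr Mean rate in fibrillations per minute (default 420, i.e.
#'   7 Hz).
#' @param sd_afr Stationary standard deviation of the minute noise (default
#'   15).
#' @param reversion AR(1) coefficient toward the mean (default 0.9).
#' @param missing_prob Probability that a minute is missing (default 0.02).
#' @return Data frame with \code{minute} (0-based) and \code{afr} (NA =
#'   missing).
#' @export
generate_afr_trend <- function(n_minutes, mean_afr = 420, sd_afr = 15,
                               reversion = 0.9, missing_prob = 0.02) {
  innov_sd <- sd_afr * sqrt(1 - reversion^2)
  x <- numeric(n_minutes)
  x[1] <- rnorm(1, 0, sd_afr)
  for (i in seq_len(n_minutes)[-1])
    x[i] <- reversion * x[i - 1] + rnorm(1, 0, innov_sd)
  afr <- mean_afr + x
  if (missing_prob > 0) {
    miss <- runif(n_minutes) < missing_prob
    if (all(miss)) miss[1] <- FALSE
    afr[miss] <- NA_real_
  }
  data.frame(minute = seq_len(n_minutes) - 1L, afr = afr)
}

#' Sample demographics for feature-table tests
#'
#' Mirrors the modelled population: age ~ N(71, 9), 35 % women, weight ~
#' N(85, 15) kg, height ~ N(175, 10) cm. Gender is coded 1 = woman,
#' 0 = man.
#'
#' @param n Number of patients.
#' @return Data frame with age, gender, weight, height.
#' @export
sample_demographics <- function(n = 1L) {
  data.frame(age = round(rnorm(n, 71, 9)),
             gender = rbinom(n, 1, 0.35),
             weight = round(rnorm(n, 85, 15)),
             height = round(rnorm(n, 175, 10)))
}

#' Generate a synthetic recording from a ground-truth trajectory
#'
#' Simulates the network model block by block (5-min blocks, the stepping
#' unit of the segmentation) under the given parameter trajectory, with the
#' Poisson atrial rate taken from a synthetic AFR trend. Beats are
#' concatenated across blocks; the per-block activation logs are pooled
#' into per-segment truth property samples (segment s = blocks s and s+1),
#' so the generator's own realized refractory periods and delays are
#' available as the recovery target. Optionally, silent minutes (dropped
#' beats) can be injected to exercise the noise filter.
#'
#' @param trajectory Matrix from [generate_theta_trajectory()].
#' @param afr AFR trend from [generate_afr_trend()] covering the recording;
#'   generated with defaults when NULL.
#' @param coupling Coupling configuration; when NULL, the refractory period
#'   is fixed from the ten shortest simulated RR intervals of a pilot block
#'   at the base parameters.
#' @param silent_minutes Integer minute indices (0-based) whose beats are
#'   deleted, emulating undetected beats under noise.
#' @param seed Integer master seed.
#' @return List of class \code{ground_truth_recording}: \code{beat_times},
#'   \code{rr}, \code{afr}, \code{coupling}, \code{trajectory},
#'   \code{truth_samples} (per segment, \code{property_samples}),
#'   \code{duration}, \code{demographics}, \code{master_seed}.
#' @export
generate_recording <- function(trajectory, afr = NULL, coupling = NULL,
                               silent_minutes = integer(0), seed = 1L) {
  set.seed(seed)
  n_blocks <- nrow(trajectory)
  block_ms <- 300000
  duration <- n_blocks * block_ms
  if (is.null(afr))
    afr <- generate_afr_trend(n_minutes = n_blocks * 5L)
  if (is.null(coupling)) {
    pilot <- simulate_avn(trajectory[1, ],
                          coupling_config(refractory_period = 250),
                          sample_impulse_train(7, block_ms))
    coupling <- coupling_config(coupling_refractory_from_rr(pilot$rr))
  }
  beat_times <- vector("list", n_blocks)
  block_logs <- vector("list", n_blocks)
  block_counts <- matrix(0L, n_blocks, 2,
                         dimnames = list(NULL, c("n_fp", "n_sp")))
  for (b in seq_len(n_blocks)) {
    start <- (b - 1L) * block_ms
    mins <- (b - 1L) * 5L + 0:4
    v <- afr$afr[match(mins, afr$minute)]
    v <- v[!is.na(v)]
    lam <- if (length(v)) mean(v) / 60 else 7
    train <- sample_impulse_train(lam, block_ms)
    sim <- simulate_avn(trajectory[b, ], coupling, train,
                        log_activations = TRUE)
    # conduction delay can push the last beats past the block end; keep
    # each block's beats inside its own window so concatenation stays
    # strictly increasing
    beat_times[[b]] <- sim$beat_times[sim$beat_times < block_ms] + start
    block_logs[[b]] <- sim$log
    block_counts[b, ] <- c(sim$n_fp, sim$n_sp)
  }
  bt <- unlist(beat_times)
  bt <- bt[bt < duration]
  if (length(silent_minutes)) {
    minute_of <- floor(bt / 60000)
    bt <- bt[!(minute_of %in% silent_minutes)]
  }
  # per-segment truth: pool the two blocks each 10-min segment covers
  n_seg <- max(n_blocks - 1L, 0L)
  truth_samples <- lapply(seq_len(n_seg), function(s) {
    lg <- rbind(block_logs[[s]], block_logs[[s + 1L]])
    fp <- lg$node <= 10L
    structure(list(r_fp = lg$R[fp], r_sp = lg$R[!fp],
                   d_fp = lg$D[fp], d_sp = lg$D[!fp],
                   n_fp = sum(block_counts[s:(s + 1L), "n_fp"]),
                   n_sp = sum(block_counts[s:(s + 1L), "n_sp"])),
              class = "property_samples")
  })
  structure(list(beat_times = bt, rr = diff(bt), afr = afr,
                 coupling = coupling, trajectory = trajectory,
                 truth_samples = truth_samples, duration = duration,
                 demographics = sample_demographics(1L),
                 master_seed = seed),
            class = "ground_truth_recording")
}

#' Ground-truth parameter recovery study
#'
#' Generates synthetic patients, runs the full estimation chain (segmenting
#' and filtering, GA, ABC, property reduction) at a configurable reduced
#' scale, and reports how well the estimated property distributions recover
#' the generator's own realized properties: the relative error of the
#' slow-pathway refractory-period mode, whether the 5-95 % band covers the
#' truth mode, and the achieved GA and ABC errors.
#'
#' @param n_patients Number of synthetic patients.
#' @param profile Trajectory profile (see [generate_theta_trajectory()]).
#' @param n_blocks Blocks per recording (n_blocks - 1 segments).
#' @param config GA configuration (use a small population for desk-scale
#'   runs).
#' @param n_particles ABC particles.
#' @param seed Integer master seed.
#' @return Data frame, one row per patient x segment: truth and estimated
#'   slow-pathway refractory mode, relative mode error, band coverage
#'   flags for all four properties, GA and ABC best errors.
#' @export
recovery_study <- function(n_patients = 3L, profile = "stationary",
                           n_blocks = 3L,
                           config = ga_config(population_size = 60L,
                                              first_segment_generations = 15L),
                           n_particles = 20L, seed = 1L) {
  rows <- list()
  for (pat in seq_len(n_patients)) {
    pat_seed <- seed + 1000L * pat
    set.seed(pat_seed)
    traj <- generate_theta_trajectory(n_blocks, profile)
    rec <- generate_recording(traj, seed = pat_seed)
    pre <- preprocess_recording(rec$beat_times, rec$afr, rec$duration)
    ga_out <- run_over_segments(pre$segments, rec$coupling, config,
                                seed = pat_seed)
    for (k in seq_along(ga_out)) {
      pop <- ga_out[[k]]
      seg <- pre$segments[[pop$segment_index]]
      abc_pop <- run_abc(pop, seg, rec$coupling, n_particles)
      props <- properties_from_particles(abc_pop, seg$lambda_hat,
                                         rec$coupling,
                                         duration = seg$end - seg$start)
      est <- summarize_properties(props, seg$index)
      truth <- summarize_properties(rec$truth_samples[[pop$segment_index]],
                                    pop$segment_index)
      cover <- vapply(c("r_fp", "r_sp", "d_fp", "d_sp"), function(p) {
        isTRUE(truth$phi_max[p] >= est$phi_5[p] &&
               truth$phi_max[p] <= est$phi_95[p])
      }, TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pat, segment = pop$segment_index,
        truth_r_sp_mode = unname(truth$phi_max["r_sp"]),
        est_r_sp_mode = unname(est$phi_max["r_sp"]),
        rel_mode_error_r_sp =
          abs(est$phi_max[["r_sp"]] - truth$phi_max[["r_sp"]]) /
          truth$phi_max[["r_sp"]],
        covers_r_fp = cover[["r_fp"]], covers_r_sp = cover[["r_sp"]],
        covers_d_fp = cover[["d_fp"]], covers_d_sp = cover[["d_sp"]],
        ga_best_eps = pop$fitness[1], abc_best_eps = min(abc_pop$errors),
        sp_ratio_truth = with(rec$truth_samples[[pop$segment_index]],
                              n_sp / (n_fp + n_sp)),
        sp_ratio_est = est$sp_ratio)
    }
  }
  do.call(rbind, rows)
}

#' Write the ground truth of a synthetic recording as JSON
#'
#' @param rec A \code{ground_truth_recording}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(rec, path) {
  jsonlite::write_json(
    list(master_seed = rec$master_seed,
         coupling = rec$coupling,
         duration = rec$duration,
         trajectory = as.data.frame(rec$trajectory),
         demographics = rec$demographics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
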