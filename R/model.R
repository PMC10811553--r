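#' Sample a Poisson atrial impulse train
#'
#' During atrial fibrillation the atrial input to the AV node is modelled as
#' a homogeneous Poisson process with mean arrival rate lambda, so
#' inter-arrival times are exponential with mean \code{1000/rate} ms.
#'
#' @param rate Mean arrival rate in impulses per second (the atrial
#'   fibrillatory rate divided by 60 when given per minute).
#' @param duration Length of the train in ms.
#' @param seed Integer seed; the train is reproducible given the seed.
#' @return List of class \code{impulse_train} with \code{arrival_times}
#'   (strictly increasing, within \code{[0, duration]}), \code{rate},
#'   \code{duration} and \code{seed}.
#' @export
sample_impulse_train <- function(rate, duration, seed = NULL) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  if (!is.numeric(duration) || duration < 0) stop("duration must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  if (duration > 0) {
    # draw in chunks until the train passes `duration`
    mean_gap <- 1000 / rate
    n_guess <- max(16L, ceiling(duration / mean_gap * 1.2) + 10L)
    t <- cumsum(rexp(n_guess, rate = rate / 1000))
    while (t[length(t)] < duration)
      t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate = rate / 1000)))
    times <- t[t <= duration]
  }
  structure(list(arrival_times = times, rate = rate, duration = duration,
                 seed = seed),
            class = "impulse_train")
}

#' Refractory-period and conduction-delay response of a single node
#'
#' Evaluates the closed-form node update for one incoming impulse: with
#' diastolic interval \code{tdia = arrival - (t_last + R_last)},
#' \deqn{R = R_{min} + \Delta R (1 - e^{-\tilde t/\tau_R}),\qquad
#'       D = D_{min} + \Delta D\, e^{-\tilde t/\tau_D}.}
#' A negative diastolic interval means the node is still refractory and
#' blocks the impulse (state unchanged); \code{tdia = 0} conducts. A node
#' that has never been activated responds in the fully recovered limit
#' (\code{R = rmin + dr}, \code{D = dmin}).
#'
#' @param state List with \code{last_activation_time} (ms, or \code{NA} if
#'   never activated) and \code{last_refractory_period} (ms).
#' @param arrival Impulse arrival time (ms).
#' @param params A [pathway_params()] vector.
#' @return List with \code{blocked} (logical), \code{R}, \code{D} (ms, NA
#'   when blocked), \code{tdia}, and the advanced \code{state}.
#' @export
node_response <- function(state, arrival, params) {
  p <- unclass(params)
  if (is.na(state$last_activation_time)) {
    tdia <- Inf
  } else {
    if (arrival < state$last_activation_time)
      stop("arrival precedes the last activation")
    tdia <- arrival - (state$last_activation_time +
                       state$last_refractory_period)
  }
  if (tdia < 0)
    return(list(blocked = TRUE, R = NA_real_, D = NA_real_, tdia = tdia,
                state = state))
  if (is.infinite(tdia)) {
    R <- p[["rmin"]] + p[["dr"]]
    D <- p[["dmin"]]
  } else {
    R <- p[["rmin"]] + p[["dr"]] * (1 - exp(-tdia / p[["taur"]]))
    D <- p[["dmin"]] + p[["dd"]] * exp(-tdia / p[["taud"]])
  }
  list(blocked = FALSE, R = R, D = D, tdia = tdia,
       state = list(last_activation_time = arrival,
                    last_refractory_period = R))
}

#' Coupling-node refractory period from the data
#'
#' The coupling node (His bundle / Purkinje system) has its refractory period
#' fixed to the mean of the ten shortest RR intervals of the observed series;
#' its conduction delay is fixed at 60 ms.
#'
#' @param rr Numeric vector of RR intervals (ms), at least 10.
#' @return Mean of the 10 smallest intervals (ms).
#' @export
coupling_refractory_from_rr <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 10L)
    stop("need at least 10 RR intervals to fix the coupling refractory period")
  mean(sort(rr)[1:10])
}

#' Simulate the dual-pathway AV-node network
#'
#' Event-driven simulation of the 21-node network: two 10-node pathway chains
#' (fast and slow), mutually connected at their distal ends, both feeding a
#' coupling node with fixed refractory period and a fixed 60 ms delay to the
#' ventricles. Atrial impulses are delivered simultaneously to the first node
#' of each chain; a non-refractory node transmits to all neighbours with its
#' realized conduction delay and then turns refractory, so impulses can also
#' travel retrogradely between the chain ends and within the chains. Blocked
#' impulses do not alter node state (no fatigue). Ventricular beat times are
#' coupling-node activation times plus the coupling delay; RR intervals are
#' their successive differences.
#'
#' @param params An [avn_params()] vector (or plain numeric 12-vector in
#'   canonical order).
#' @param coupling List with \code{refractory_period} and
#'   \code{conduction_delay} in ms (see [coupling_refractory_from_rr()];
#'   delay defaults to 60).
#' @param train An [sample_impulse_train()] object, or a numeric vector of
#'   arrival times (ms).
#' @param nodes_per_pathway Nodes per chain; 10 for the full model, smaller
#'   for miniature test networks.
#' @param log_activations Keep the per-node activation log (time, diastolic
#'   interval, realized R and D) needed for the parameter reduction.
#' @return List of class \code{avn_sim} with \code{rr} (intervals, ms),
#'   \code{beat_times}, \code{beat_source} (1 = fast, 2 = slow pathway),
#'   \code{n_fp}, \code{n_sp}, and, when requested, \code{log} (data frame
#'   with node, time, tdia, R, D; node indices 1..m are the fast chain,
#'   m+1..2m the slow chain).
#' @export
simulate_avn <- function(params, coupling, train, nodes_per_pathway = 10L,
                         log_activations = FALSE) {
  theta <- as.numeric(params)
  if (length(theta) != 12L) stop("params must have 12 elements")
  arr <- if (is.list(train)) train$arrival_times else as.numeric(train)
  if (length(arr) && any(diff(arr) <= 0))
    stop("arrival times must be strictly increasing")
  if (is.null(coupling$conduction_delay)) coupling$conduction_delay <- 60
  if (!is.numeric(coupling$refractory_period) ||
      coupling$refractory_period <= 0)
    stop("coupling refractory period must be positive")
  res <- .simulate_avn_cpp(arr, theta, coupling$refractory_period,
                           coupling$conduction_delay,
                           as.integer(nodes_per_pathway),
                           isTRUE(log_activations))
  res$nodes_per_pathway <- as.integer(nodes_per_pathway)
  class(res) <- "avn_sim"
  res
}

#' Default coupling-node configuration
#'
#' @param refractory_period Refractory period in ms.
#' @param conduction_delay Fixed delay to the ventricles in ms (default 60).
#' @return List usable as the \code{coupling} argument of [simulate_avn()].
#' @export
coupling_config <- function(refractory_period, conduction_delay = 60) {
  list(refractory_period = refractory_period,
       conduction_delay = conduction_delay)
}

#' Read and write RR-interval series CSV
#'
#' Two accepted single-column dialects: beat occurrence times (ms, column
#' \code{beat_time_ms}) or interval lengths (ms, column \code{rr_ms}). The
#' writer emits intervals.
#'
#' @param path File path.
#' @param rr Numeric vector of RR intervals (ms), for writing.
#' @return \code{read_rr_csv}: list with \code{rr} (intervals) and
#'   \code{beat_times} (NULL unless the file stored beat times).
#' @export
read_rr_csv <- function(path) {
  d <- read.csv(path)
  if ("rr_ms" %in% names(d))
    return(list(rr = as.numeric(d$rr_ms), beat_times = NULL))
  if ("beat_time_ms" %in% names(d)) {
    bt <- as.numeric(d$beat_time_ms)
    return(list(rr = diff(bt), beat_times = bt))
  }
  stop("RR CSV must have a column 'rr_ms' or 'beat_time_ms'")
}

#' @rdname read_rr_csv
#' @export
write_rr_csv <- function(rr, path) {
  write.csv(data.frame(rr_ms = as.numeric(rr)), path, row.names = FALSE)
  invisible(path)
}
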