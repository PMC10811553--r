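# Independent step-by-step reference simulator for the miniature network
# with ONE node per pathway (FP node, SP node, coupling node). Written as a
# plain vector-scan event loop (no priority queue, no shared code with the
# package's engine) so it can serve as an oracle for simulate_avn().
#
# Topology for m = 1: the two pathway nodes are each other's only pathway
# neighbour (they are simultaneously entry and distal nodes) and both feed
# the coupling node; the coupling node does not re-emit.
reference_sim_1pp <- function(arrivals, theta, cpl_rp, cpl_cd = 60) {
  FP <- 1L; SP <- 2L; CPL <- 3L
  ev_t <- rep(arrivals, each = 2)
  ev_node <- rep(c(FP, SP), length(arrivals))
  ev_ord <- seq_along(ev_t)
  ev_from <- rep(0L, length(ev_t))
  next_ord <- length(ev_t) + 1L

  last_t <- c(NA_real_, NA_real_, NA_real_)
  last_r <- c(0, 0, 0)
  t_cap <- (if (length(arrivals)) max(arrivals) else 0) + 10000

  par_of <- function(node) if (node == FP) theta[1:6] else theta[7:12]

  beats <- numeric(0)
  beat_src <- integer(0)

  while (length(ev_t) > 0) {
    # earliest event; ties by node index then insertion order
    key <- order(ev_t, ev_node, ev_ord)
    i <- key[1]
    t <- ev_t[i]; node <- ev_node[i]; from <- ev_from[i]
    ev_t <- ev_t[-i]; ev_node <- ev_node[-i]
    ev_ord <- ev_ord[-i]; ev_from <- ev_from[-i]
    if (t > t_cap) next

    if (is.na(last_t[node])) {
      tdia <- Inf
    } else {
      tdia <- t - (last_t[node] + last_r[node])
      if (tdia < 0) next
    }

    if (node == CPL) {
      last_t[node] <- t; last_r[node] <- cpl_rp
      beats <- c(beats, t + cpl_cd)
      beat_src <- c(beat_src, if (from == FP) 1L else 2L)
      next
    }

    p <- par_of(node) # rmin, dr, taur, dmin, dd, taud
    if (is.infinite(tdia)) {
      R <- p[1] + p[2]; D <- p[4]
    } else {
      R <- p[1] + p[2] * (1 - exp(-tdia / p[3]))
      D <- p[4] + p[5] * exp(-tdia / p[6])
    }
    last_t[node] <- t; last_r[node] <- R

    other <- if (node == FP) SP else FP
    for (dest in c(other, CPL)) {
      ev_t <- c(ev_t, t + D); ev_node <- c(ev_node, dest)
      ev_ord <- c(ev_ord, next_ord); ev_from <- c(ev_from, node)
      next_ord <- next_ord + 1L
    }
  }
  list(beat_times = beats, beat_source = beat_src)
}

# random GA-box parameter vector
random_theta <- function() {
  b <- avn_bounds("GA")
  runif(12, b$lower, b$upper)
}

# quick synthetic 10-min segment simulated from known parameters
make_synth_segment <- function(theta = default_truth_params(),
                               lambda = 7, duration = 600000,
                               coupling = coupling_config(350),
                               index = 1L) {
  train <- sample_impulse_train(lambda, duration)
  sim <- simulate_avn(theta, coupling, train)
  list(index = index, start = 0, end = duration, rr = sim$rr,
       beat_times = sim$beat_times, included = TRUE, reason = "",
       lambda_hat = lambda)
}

# forge a Poincare histogram with given occupied-bin counts and duration
forge_hist <- function(counts_at, duration) {
  h <- poincare_histogram(numeric(0), duration = duration)
  for (k in names(counts_at)) h$counts[as.integer(k)] <- counts_at[[k]]
  h$n_pairs <- sum(h$counts)
  h$duration <- duration
  h
}
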