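#' Poincare histogram of an RR-interval series
#'
#' Successive pairs of RR intervals (RR_n, RR_{n+1}) are counted into a
#' two-dimensional grid covering 250-1800 ms in 50 ms steps on both axes
#' (31 x 31 = 961 bins, half-open \code{[lo, lo+50)}). Pairs with either
#' coordinate outside the grid are dropped, not clipped.
#'
#' @param rr Numeric vector of RR intervals (ms).
#' @param duration Series duration in ms; defaults to \code{sum(rr)}. Kept on
#'   the histogram because the error function normalizes by the duration
#'   ratio of the two series.
#' @return List of class \code{poincare_hist} with \code{counts} (integer
#'   961-vector, row-major over the first-interval axis), \code{edges}
#'   (\code{seq(250, 1800, 50)}), \code{n_pairs} (in-range pairs) and
#'   \code{duration}.
#' @export
poincare_histogram <- function(rr, duration = sum(rr)) {
  rr <- as.numeric(rr)
  edges <- seq(250, 1800, by = 50)
  nb <- length(edges) - 1L # 31
  counts <- integer(nb * nb)
  if (length(rr) >= 2L) {
    a <- rr[-length(rr)]
    b <- rr[-1L]
    ia <- findInterval(a, edges, rightmost.closed = FALSE)
    ib <- findInterval(b, edges, rightmost.closed = FALSE)
    ok <- ia >= 1L & ia <= nb & ib >= 1L & ib <= nb &
      a < edges[nb + 1L] & b < edges[nb + 1L]
    if (any(ok)) {
      idx <- (ia[ok] - 1L) * nb + ib[ok]
      tab <- tabulate(idx, nbins = nb * nb)
      counts <- as.integer(tab)
    }
  }
  structure(list(counts = counts, edges = edges, n_pairs = sum(counts),
                 duration = as.numeric(duration)),
            class = "poincare_hist")
}

#' Poincare-histogram error between observed and simulated series
#'
#' The chi-square-style distance
#' \deqn{\epsilon = \frac1K \sum_{k=1}^{K}
#'   \frac{(x_k - \tilde x_k / t_{norm})^2}{x_k},}
#' with \code{x_k} the observed and \code{x_tilde_k} the simulated bin
#' counts, \code{K = 961}, and \code{t_norm} the simulated duration divided
#' by the observed duration (so a longer simulation is scaled down rather
#' than penalized). Bins with \code{x_k = 0} are skipped, as is conventional
#' for chi-square distances over observed-occupied cells.
#'
#' @param observed,simulated \code{poincare_hist} objects on the same grid.
#' @return List of class \code{avn_error} with \code{epsilon} and
#'   \code{t_norm}.
#' @export
epsilon_error <- function(observed, simulated) {
  stopifnot(inherits(observed, "poincare_hist"),
            inherits(simulated, "poincare_hist"))
  if (!identical(observed$edges, simulated$edges))
    stop("histograms are not on the same grid")
  if (observed$n_pairs == 0L)
    stop("observed histogram is empty: the error is undefined")
  if (!is.finite(observed$duration) || observed$duration <= 0)
    stop("observed duration must be positive")
  t_norm <- simulated$duration / observed$duration
  K <- length(observed$counts)
  x <- observed$counts
  xs <- simulated$counts
  occ <- x > 0L
  eps <- sum((x[occ] - xs[occ] / t_norm)^2 / x[occ]) / K
  structure(list(epsilon = eps, t_norm = t_norm), class = "avn_error")
}

#' Poincare-histogram difference between consecutive segments
#'
#' The same distance as [epsilon_error()], applied with the current
#' segment's histogram as observed and the following segment's as simulated.
#' Used to set the per-segment generation budget of the genetic algorithm.
#' Note the distance is not symmetric in its arguments.
#'
#' @param seg_a Current segment's \code{poincare_hist}.
#' @param seg_b Following segment's \code{poincare_hist}.
#' @return The scalar difference (non-negative).
#' @export
segment_difference <- function(seg_a, seg_b) {
  epsilon_error(seg_a, seg_b)$epsilon
}

#' Serialize a Poincare histogram to CSV (with a JSON sidecar for the grid)
#'
#' @param hist A \code{poincare_hist}.
#' @param path CSV path; the sidecar is written to \code{paste0(path, ".json")}.
#' @return The CSV path, invisibly.
#' @export
write_poincare_csv <- function(hist, path) {
  nb <- length(hist$edges) - 1L
  occ <- which(hist$counts > 0L)
  d <- data.frame(bin_row = (occ - 1L) %/% nb + 1L,
                  bin_col = (occ - 1L) %% nb + 1L,
                  count = hist$counts[occ])
  write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(edges = hist$edges, duration = hist$duration,
                            n_pairs = hist$n_pairs),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
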