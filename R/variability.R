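# time-of-day helpers: segment membership is by window start time,
# recording start clock given in hours (default 8:00)
segment_hour <- function(start_ms, recording_start_hour = 8) {
  (recording_start_hour + start_ms / 3600000) %% 24
}

in_day <- function(h) h >= 9 & h < 21   # 09:00-21:00
in_night <- function(h) h >= 2 & h < 6  # 02:00-06:00

#' Diurnal variability of the property trend
#'
#' Per property, the mean of the per-segment density mode \code{phi_max}
#' over daytime segments (09:00-21:00) divided by its mean over nighttime
#' segments (02:00-06:00). Membership is decided by segment start time. A
#' ratio below 1 means the property is larger at night (typical for the
#' refractory periods, which lengthen during sleep).
#'
#' @param trend Data frame from [property_trend()] with a \code{start_ms}
#'   column.
#' @param recording_start_hour Clock hour of recording start (default 8).
#' @return Named 4-vector (r_fp, r_sp, d_fp, d_sp); NA when either window
#'   holds no segment.
#' @export
diurnal_variability <- function(trend, recording_start_hour = 8) {
  h <- segment_hour(trend$start_ms, recording_start_hour)
  props <- c("r_fp", "r_sp", "d_fp", "d_sp")
  out <- setNames(rep(NA_real_, 4), props)
  day <- in_day(h); night <- in_night(h)
  if (!any(day) || !any(night)) return(out)
  for (p in props) {
    x <- trend[[paste0(p, "_max")]]
    out[p] <- mean(x[day], na.rm = TRUE) / mean(x[night], na.rm = TRUE)
  }
  out
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Maximal separation between the empirical cumulative distribution
#' functions of two samples; symmetric, in [0, 1].
#'
#' @param a,b Numeric samples.
#' @return The KS statistic.
#' @export
ks_distance <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

#' Short-term variability of the property distributions
#'
#' Per property, the mean two-sample KS distance between the pooled
#' property samples of consecutive segments (adjacent in the 50 %-overlap
#' sequence, i.e. 5 min apart; pairs broken by an excluded segment are
#' skipped, not bridged).
#'
#' @param samples_by_segment List of \code{property_samples}, one per
#'   segment.
#' @param segment_indices Integer positions of the segments in the overlap
#'   sequence (defaults to 1..n, i.e. all consecutive); only pairs with
#'   index difference 1 contribute.
#' @return Named 4-vector of mean KS distances; NA with < 2 adjacent
#'   segments.
#' @export
short_term_variability <- function(samples_by_segment,
                                   segment_indices = seq_along(samples_by_segment)) {
  props <- c("r_fp", "r_sp", "d_fp", "d_sp")
  out <- setNames(rep(NA_real_, 4), props)
  n <- length(samples_by_segment)
  if (n < 2L) return(out)
  adj <- which(diff(segment_indices) == 1L)
  if (!length(adj)) return(out)
  for (p in props) {
    ks <- vapply(adj, function(i) {
      ks_distance(samples_by_segment[[i]][[p]],
                  samples_by_segment[[i + 1L]][[p]])
    }, 0)
    out[p] <- mean(ks, na.rm = TRUE)
  }
  out
}

#' Paired day-versus-night tests across patients
#'
#' For each property, tests whether a per-patient quantity (the mean
#' density mode, the 90 % credibility width, or the short-term KS distance)
#' differs between day and night, using the Wilcoxon signed-rank test.
#' Shapiro-Wilk normality p-values for the paired differences are reported
#' alongside (the non-parametric test is motivated by their typical
#' non-normality).
#'
#' @param day,night Numeric matrices or data frames, patients in rows,
#'   properties in columns (paired by row).
#' @return Data frame with one row per column: n, Shapiro-Wilk p of the
#'   differences, and Wilcoxon signed-rank p.
#' @export
day_night_tests <- function(day, night) {
  day <- as.matrix(day); night <- as.matrix(night)
  stopifnot(identical(dim(day), dim(night)))
  nm <- colnames(day)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(day)))
  rows <- lapply(seq_len(ncol(day)), function(j) {
    ok <- is.finite(day[, j]) & is.finite(night[, j])
    d <- day[ok, j] - night[ok, j]
    n <- sum(ok)
    if (n < 5L)
      return(data.frame(metric = nm[j], n = n, shapiro_p = NA_real_,
                        wilcoxon_p = NA_real_, sufficient = FALSE))
    sp <- if (length(unique(d)) > 1L) shapiro.test(d)$p.value else NA_real_
    wp <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(day[ok, j], night[ok, j],
                                   paired = TRUE)$p.value)
    data.frame(metric = nm[j], n = n, shapiro_p = sp, wilcoxon_p = wp,
               sufficient = TRUE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation between a patient metric and drug outcome
#'
#' Rank correlation between a per-patient variability metric and the
#' relative heart-rate reduction under a drug. Pairs with a missing outcome
#' are dropped; p-values are reported uncorrected (exploratory framing).
#'
#' @param metric,outcome Paired numeric vectors per patient.
#' @return List with \code{rho}, \code{p} and \code{n}.
#' @export
outcome_correlation <- function(metric, outcome) {
  ok <- is.finite(metric) & is.finite(outcome)
  if (sum(ok) < 5L) stop("need at least 5 paired observations")
  if (length(unique(metric[ok])) < 2L)
    stop("metric is constant: rank correlation undefined")
  ct <- suppressWarnings(cor.test(metric[ok], outcome[ok],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

feature_windows <- function() c("day", "night", "h24")

#' Names of the 66 feature-table columns, in canonical order
#'
#' @return Character vector of length 66.
#' @export
feature_names <- function() {
  props <- c("r_fp", "r_sp", "d_fp", "d_sp")
  ms <- c("mean", "sd")
  blk <- function(prefix) {
    unlist(lapply(feature_windows(), function(w)
      unlist(lapply(props, function(p) paste(prefix, w, p, ms, sep = "_")))))
  }
  c(blk("phimax"), blk("credwidth"),
    unlist(lapply(feature_windows(), function(w)
      paste("spratio", w, ms, sep = "_"))),
    paste0("ddv_", props), paste0("dks_", props),
    c("age", "gender", "weight", "height"))
}

#' Build the per-patient 66-column feature table
#'
#' The statistical properties of one patient's trend: mean and standard
#' deviation of the four per-segment density modes over day, night and the
#' full 24 h (24 columns); likewise for the per-segment 90 % credibility
#' width \code{phi_95 - phi_5} (24 columns); mean and sd of the
#' slow-pathway share over the three windows (6 columns); the four diurnal
#' ratios (4); the four short-term KS means (4); and age, gender (0/1),
#' weight, height (4). Missing demographics leave their columns NA; the row
#' is still emitted.
#'
#' @param trend Data frame from [property_trend()] with \code{start_ms}.
#' @param ddv 4-vector from [diurnal_variability()].
#' @param dks 4-vector from [short_term_variability()].
#' @param demographics List/row with age, gender, weight, height.
#' @param recording_start_hour Clock hour of recording start (default 8).
#' @return One-row data frame with exactly the 66 columns of
#'   [feature_names()], in order.
#' @export
build_feature_table <- function(trend, ddv, dks, demographics = list(),
                                recording_start_hour = 8) {
  h <- segment_hour(trend$start_ms, recording_start_hour)
  masks <- list(day = in_day(h), night = in_night(h),
                h24 = rep(TRUE, length(h)))
  props <- c("r_fp", "r_sp", "d_fp", "d_sp")
  out <- list()
  agg <- function(x, mask) {
    x <- x[mask & is.finite(x)]
    if (!length(x)) c(NA_real_, NA_real_)
    else c(mean(x), if (length(x) > 1L) sd(x) else 0)
  }
  for (w in names(masks)) for (p in props) {
    v <- agg(trend[[paste0(p, "_max")]], masks[[w]])
    out[[paste("phimax", w, p, "mean", sep = "_")]] <- v[1]
    out[[paste("phimax", w, p, "sd", sep = "_")]] <- v[2]
  }
  for (w in names(masks)) for (p in props) {
    width <- trend[[paste0(p, "_95")]] - trend[[paste0(p, "_5")]]
    v <- agg(width, masks[[w]])
    out[[paste("credwidth", w, p, "mean", sep = "_")]] <- v[1]
    out[[paste("credwidth", w, p, "sd", sep = "_")]] <- v[2]
  }
  for (w in names(masks)) {
    v <- agg(trend$sp_ratio, masks[[w]])
    out[[paste("spratio", w, "mean", sep = "_")]] <- v[1]
    out[[paste("spratio", w, "sd", sep = "_")]] <- v[2]
  }
  for (p in props) out[[paste0("ddv_", p)]] <- unname(ddv[p])
  for (p in props) out[[paste0("dks_", p)]] <- unname(dks[p])
  for (d in c("age", "gender", "weight", "height"))
    out[[d]] <- if (is.null(demographics[[d]])) NA_real_
                else as.numeric(demographics[[d]])
  d <- as.data.frame(out)
  stopifnot(identical(names(d), feature_names()))
  d
}
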