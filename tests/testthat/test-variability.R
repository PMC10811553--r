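make_trend <- function(n_seg, r_fp_max, start0_ms = 0) {
  data.frame(segment_index = seq_len(n_seg),
             r_fp_max = r_fp_max,
             r_fp_5 = r_fp_max - 100, r_fp_95 = r_fp_max + 100,
             r_sp_max = r_fp_max / 2,
             r_sp_5 = r_fp_max / 2 - 50, r_sp_95 = r_fp_max / 2 + 50,
             d_fp_max = 8, d_fp_5 = 6, d_fp_95 = 10,
             d_sp_max = 55, d_sp_5 = 50, d_sp_95 = 60,
             sp_ratio = 0.8,
             start_ms = start0_ms + (seq_len(n_seg) - 1) * 300000)
}

test_that("diurnal variability is the day/night ratio of the density mode", {
  # 24 h of segments starting 08:00; constant trend -> ratio 1
  tr <- make_trend(287, rep(800, 287))
  expect_equal(unname(diurnal_variability(tr)),
               rep(1, 4))

  # day mean 800, night mean 1000 -> 0.8 for R^FP
  h <- (8 + tr$start_ms / 3600000) %% 24
  night <- h >= 2 & h < 6
  tr2 <- tr
  tr2$r_fp_max <- ifelse(night, 1000, 800)
  dv <- diurnal_variability(tr2)
  expect_equal(unname(dv["r_fp"]), 0.8)

  # invariant under a common positive rescaling of the trend
  tr3 <- tr2
  for (p in c("r_fp", "r_sp", "d_fp", "d_sp"))
    tr3[[paste0(p, "_max")]] <- tr3[[paste0(p, "_max")]] * 3.7
  expect_equal(diurnal_variability(tr3), dv)

  # a recording with no night window leaves the metric undefined
  short <- make_trend(10, rep(800, 10)) # 08:00-09:00 only
  expect_true(all(is.na(diurnal_variability(short))))
})

test_that("KS distance matches hand-computed values and is symmetric", {
  expect_equal(ks_distance(1:10, 1:10), 0)
  expect_equal(ks_distance(1:5, 101:105), 1)
  expect_equal(ks_distance(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  a <- rnorm(50); b <- rnorm(60, 1)
  expect_equal(ks_distance(a, b), ks_distance(b, a))
  expect_true(ks_distance(a, b) >= 0 && ks_distance(a, b) <= 1)
  # agrees with the standard two-sample statistic
  expect_equal(ks_distance(a, b),
               unname(suppressWarnings(ks.test(a, b)$statistic)))
})

test_that("short-term variability averages KS over adjacent segments only", {
  mk <- function(x) structure(list(r_fp = x, r_sp = x, d_fp = x, d_sp = x,
                                   n_fp = 1L, n_sp = 1L),
                              class = "property_samples")
  same <- lapply(1:4, function(i) mk(c(1, 2, 3, 4)))
  expect_equal(unname(short_term_variability(same)), rep(0, 4))

  disjoint <- lapply(1:4, function(i) mk(if (i %% 2) 1:4 else 101:104))
  expect_equal(unname(short_term_variability(disjoint)), rep(1, 4))

  two <- list(mk(c(1, 2, 3, 4)), mk(c(3, 4, 5, 6)))
  expect_equal(unname(short_term_variability(two)), rep(0.5, 4))

  # a gap in the segment sequence breaks the pair instead of bridging it
  gap <- short_term_variability(list(mk(1:4), mk(5:8), mk(9:12)),
                                segment_indices = c(1L, 2L, 4L))
  expect_equal(unname(gap), rep(1, 4)) # only the 1-2 pair contributes
  expect_true(all(is.na(short_term_variability(list(mk(1:4))))))
})

test_that("day-night Wilcoxon tests behave under null, shift and antisymmetry", {
  # identical day and night: no signed differences, p = 1
  x <- matrix(rnorm(47 * 2, 800, 100), 47, 2,
              dimnames = list(NULL, c("r_fp", "r_sp")))
  r <- day_night_tests(x, x)
  expect_equal(r$wilcoxon_p, c(1, 1))

  # a +100 ms day-night shift at n = 47 is detected almost surely
  set.seed(21)
  hits <- 0L
  for (i in 1:100) {
    day <- matrix(rnorm(47, 800, 50), 47, 1, dimnames = list(NULL, "m"))
    night <- day + 100 + matrix(rnorm(47, 0, 50), 47, 1)
    if (day_night_tests(day, night)$wilcoxon_p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  # antisymmetric differences: the test stays near its null
  d <- c(rep(10, 10), rep(-10, 10))
  day <- matrix(500 + d, 20, 1, dimnames = list(NULL, "m"))
  night <- matrix(500, 20, 1)
  expect_gt(day_night_tests(day, night)$wilcoxon_p, 0.9)

  # too few pairs is reported, not guessed
  few <- day_night_tests(matrix(1:3, 3, 1), matrix(4:6, 3, 1))
  expect_false(few$sufficient)
})

test_that("outcome correlation is a Spearman rank correlation with null calibration", {
  y <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10)
  expect_equal(outcome_correlation(y, y)$rho, 1)
  expect_equal(outcome_correlation(-y, y)$rho, -1)
  expect_error(outcome_correlation(rep(1, 10), y), "constant")
  expect_error(outcome_correlation(y[1:4], y[1:4]), "at least 5")

  # independent metric and outcome at n = 48: |rho| below the 5 % critical
  # value (~0.285) in roughly 95 % of replicates
  set.seed(22)
  inside <- vapply(1:1000, function(i) {
    abs(cor(rnorm(48), rnorm(48), method = "spearman")) < 0.29
  }, TRUE)
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.99)
})

test_that("the feature table has exactly the 66 frozen columns", {
  nm <- feature_names()
  expect_length(nm, 66L)
  # frozen canonical order: mode block, credibility block, SP share,
  # diurnal, short-term, demographics
  expect_identical(nm[1:2], c("phimax_day_r_fp_mean", "phimax_day_r_fp_sd"))
  expect_identical(nm[25], "credwidth_day_r_fp_mean")
  expect_identical(nm[49:50], c("spratio_day_mean", "spratio_day_sd"))
  expect_identical(nm[55:58], paste0("ddv_", c("r_fp", "r_sp", "d_fp", "d_sp")))
  expect_identical(nm[59:62], paste0("dks_", c("r_fp", "r_sp", "d_fp", "d_sp")))
  expect_identical(nm[63:66], c("age", "gender", "weight", "height"))

  tr <- make_trend(287, rep(800, 287))
  ddv <- diurnal_variability(tr)
  dks <- setNames(rep(0.3, 4), c("r_fp", "r_sp", "d_fp", "d_sp"))
  ft <- build_feature_table(tr, ddv, dks,
                            list(age = 71, gender = 1, weight = 80,
                                 height = 175))
  expect_identical(names(ft), nm)
  expect_identical(ncol(ft), 66L)
  # constant trend: every sd column is zero
  expect_true(all(ft[grepl("_sd$", nm)] == 0))
  expect_equal(ft$age, 71)

  # missing demographics leave columns NA but the row is emitted
  ft2 <- build_feature_table(tr, ddv, dks, list())
  expect_true(all(is.na(ft2[, 63:66])))
  expect_identical(ncol(ft2), 66L)

  # credibility-width columns equal an independent recomputation
  set.seed(23)
  tr2 <- make_trend(287, rnorm(287, 800, 60))
  tr2$r_fp_5 <- tr2$r_fp_max - runif(287, 50, 150)
  tr2$r_fp_95 <- tr2$r_fp_max + runif(287, 50, 150)
  ft3 <- build_feature_table(tr2, ddv, dks, list())
  w <- tr2$r_fp_95 - tr2$r_fp_5
  expect_equal(ft3$credwidth_h24_r_fp_mean, mean(w))
  expect_equal(ft3$credwidth_h24_r_fp_sd, sd(w))
  h <- (8 + tr2$start_ms / 3600000) %% 24
  day <- h >= 9 & h < 21
  expect_equal(ft3$credwidth_day_r_fp_mean, mean(w[day]))
})
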