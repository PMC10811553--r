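#' Load and validate a pipeline run configuration
#'
#' YAML or JSON. Recognized fields (all optional, defaults shown):
#' \code{seed} (1), \code{n_blocks} (4, synthetic stage), \code{profile}
#' ("stationary"), \code{population_size} (300), \code{first_segment_generations}
#' (30), \code{n_particles} (100), \code{recording_start_hour} (8), and
#' \code{scale} — a convenience factor in (0, 1] multiplying the GA
#' population and particle count for desk-scale runs.
#'
#' @param path Config file (.yaml/.yml/.json), or NULL for pure defaults.
#' @return Validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  defaults <- list(seed = 1L, n_blocks = 4L, profile = "stationary",
                   population_size = 300L, first_segment_generations = 30L,
                   n_particles = 100L, recording_start_hour = 8,
                   scale = 1)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$scale > 0, cfg$scale <= 1, cfg$n_particles >= 5,
            cfg$population_size >= 30)
  cfg$population_size <-
    max(30L, as.integer(round(cfg$population_size * cfg$scale)))
  cfg$n_particles <-
    as.integer(max(5 * ceiling(cfg$n_particles * cfg$scale / 5), 10))
  structure(cfg, class = "run_config")
}

stage_manifest <- function(run_dir, stage, cfg, inputs = character(0)) {
  man <- list(stage = stage, seed = cfg$seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("avnode")),
              inputs = inputs)
  jsonlite::write_json(man, file.path(run_dir,
                                      paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

require_artifact <- function(run_dir, file, produced_by) {
  p <- file.path(run_dir, file)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run the '%s' stage first",
                 file, produced_by))
  p
}

#' Run one stage of the estimation pipeline
#'
#' Stages, in order: \code{synth} (write a synthetic recording),
#' \code{preprocess} (segment, filter, attach rates), \code{fit-ga},
#' \code{fit-abc}, \code{reduce}, \code{variability}, \code{report}. Every
#' stage reads only the artifacts of earlier stages from \code{run_dir},
#' writes its own as CSV/JSON, and records a manifest; re-running a stage
#' with the same config and seed reproduces its outputs.
#'
#' @param command Stage name.
#' @param run_dir Run directory (created if absent).
#' @param config A \code{run_config} (or path handed to
#'   [read_run_config()]).
#' @return Invisibly, the paths written by the stage.
#' @export
avn_pipeline <- function(command = c("synth", "preprocess", "fit-ga",
                                     "fit-abc", "reduce", "variability",
                                     "report"),
                         run_dir, config = read_run_config()) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  set.seed(cfg$seed)
  paths <- character(0)

  if (command == "synth") {
    traj <- generate_theta_trajectory(cfg$n_blocks, cfg$profile)
    rec <- generate_recording(traj, seed = cfg$seed)
    write_rr_csv(rec$rr, file.path(run_dir, "rr.csv"))
    write.csv(data.frame(beat_time_ms = rec$beat_times),
              file.path(run_dir, "beats.csv"), row.names = FALSE)
    write_afr_csv(rec$afr, file.path(run_dir, "afr.csv"))
    write_truth_json(rec, file.path(run_dir, "truth_synthetic.json"))
    write.csv(rec$demographics, file.path(run_dir, "demographics.csv"),
              row.names = FALSE)
    paths <- c("rr.csv", "beats.csv", "afr.csv", "truth_synthetic.json",
               "demographics.csv")
  } else if (command == "preprocess") {
    beats <- read_rr_csv(require_artifact(run_dir, "beats.csv", "synth"))
    afr <- read_afr_csv(require_artifact(run_dir, "afr.csv", "synth"))
    truth <- jsonlite::read_json(file.path(run_dir, "truth_synthetic.json"),
                                 simplifyVector = TRUE)
    pre <- preprocess_recording(beats$beat_times, afr, truth$duration)
    write.csv(segment_table(pre$segments),
              file.path(run_dir, "segments.csv"), row.names = FALSE)
    paths <- "segments.csv"
  } else if (command == "fit-ga") {
    pre <- reload_segments(run_dir)
    gc <- ga_config(population_size = cfg$population_size,
                    first_segment_generations = cfg$first_segment_generations)
    ga_out <- run_over_segments(pre$segments, pre$coupling, gc,
                                seed = cfg$seed)
    for (pop in ga_out) {
      f <- sprintf("ga_segment_%03d.csv", pop$segment_index)
      d <- as.data.frame(pop$vectors)
      d$epsilon <- pop$fitness
      write.csv(d, file.path(run_dir, f), row.names = FALSE)
      paths <- c(paths, f)
    }
  } else if (command == "fit-abc") {
    pre <- reload_segments(run_dir)
    ga_files <- list.files(run_dir, "^ga_segment_\\d+\\.csv$")
    if (!length(ga_files))
      stop("missing artifact 'ga_segment_*.csv': run the 'fit-ga' stage first")
    for (f in ga_files) {
      idx <- as.integer(sub("^ga_segment_(\\d+)\\.csv$", "\\1", f))
      d <- read.csv(file.path(run_dir, f))
      pop <- structure(list(vectors = as.matrix(d[, theta_names()]),
                            fitness = d$epsilon,
                            segment_index = idx),
                       class = "ga_population")
      seg <- pre$segments[[idx]]
      abc_pop <- run_abc(pop, seg, pre$coupling, cfg$n_particles,
                         seed = cfg$seed + idx)
      out <- sprintf("abc_segment_%03d.csv", idx)
      write_particles_csv(abc_pop, file.path(run_dir, out))
      paths <- c(paths, out)
    }
  } else if (command == "reduce") {
    pre <- reload_segments(run_dir)
    abc_files <- list.files(run_dir, "^abc_segment_\\d+\\.csv$")
    if (!length(abc_files))
      stop("missing artifact 'abc_segment_*.csv': run the 'fit-abc' stage first")
    summaries <- list(); starts <- numeric(0); samples <- list()
    for (f in abc_files) {
      idx <- as.integer(sub("^abc_segment_(\\d+)\\.csv$", "\\1", f))
      d <- read.csv(file.path(run_dir, f))
      seg <- pre$segments[[idx]]
      props <- properties_from_particles(as.matrix(d[, theta_names()]),
                                         seg$lambda_hat, pre$coupling,
                                         duration = seg$end - seg$start,
                                         seed = cfg$seed + idx)
      summaries[[length(summaries) + 1L]] <- summarize_properties(props, idx)
      starts <- c(starts, seg$start)
      samples[[length(samples) + 1L]] <- props
    }
    trend <- property_trend(summaries, starts)
    write.csv(trend, file.path(run_dir, "property_trend.csv"),
              row.names = FALSE)
    saveRDS_samples_csv(samples, trend$segment_index, run_dir)
    paths <- "property_trend.csv"
  } else if (command == "variability") {
    trend <- read.csv(require_artifact(run_dir, "property_trend.csv",
                                       "reduce"))
    samples <- reload_samples(run_dir, trend$segment_index)
    ddv <- diurnal_variability(trend, cfg$recording_start_hour)
    dks <- short_term_variability(samples, trend$segment_index)
    demo <- read.csv(require_artifact(run_dir, "demographics.csv", "synth"))
    feats <- build_feature_table(trend, ddv, dks, as.list(demo[1, ]),
                                 cfg$recording_start_hour)
    write.csv(feats, file.path(run_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(list(ddv = as.list(ddv), dks = as.list(dks)),
                         file.path(run_dir, "variability.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c("features.csv", "variability.json")
  } else if (command == "report") {
    trend <- read.csv(require_artifact(run_dir, "property_trend.csv",
                                       "reduce"))
    rep <- trend_report(trend, cfg$recording_start_hour)
    write.csv(rep, file.path(run_dir, "report.csv"), row.names = FALSE)
    paths <- "report.csv"
  }
  stage_manifest(run_dir, command, cfg, paths)
  invisible(file.path(run_dir, paths))
}

# rebuild segment objects (with rates) from the synth + preprocess artifacts
reload_segments <- function(run_dir) {
  beats <- read_rr_csv(require_artifact(run_dir, "beats.csv", "synth"))
  tab <- read.csv(require_artifact(run_dir, "segments.csv", "preprocess"))
  truth <- jsonlite::read_json(file.path(run_dir, "truth_synthetic.json"),
                               simplifyVector = TRUE)
  segs <- segment_series(beats$beat_times, truth$duration)
  for (i in seq_along(segs)) {
    segs[[i]]$included <- tab$included[i]
    segs[[i]]$lambda_hat <- tab$lambda_hat[i]
  }
  list(segments = segs,
       coupling = coupling_config(truth$coupling$refractory_period,
                                  truth$coupling$conduction_delay))
}

saveRDS_samples_csv <- function(samples, indices, run_dir) {
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    n <- max(lengths(s[c("r_fp", "r_sp", "d_fp", "d_sp")]))
    pad <- function(x) c(x, rep(NA_real_, n - length(x)))
    d <- data.frame(r_fp = pad(s$r_fp), r_sp = pad(s$r_sp),
                    d_fp = pad(s$d_fp), d_sp = pad(s$d_sp))
    f <- file.path(run_dir, sprintf("samples_segment_%03d.csv", indices[i]))
    write.csv(d, f, row.names = FALSE)
  }
}

reload_samples <- function(run_dir, indices) {
  lapply(indices, function(idx) {
    d <- read.csv(file.path(run_dir, sprintf("samples_segment_%03d.csv",
                                             idx)))
    structure(list(r_fp = d$r_fp[!is.na(d$r_fp)],
                   r_sp = d$r_sp[!is.na(d$r_sp)],
                   d_fp = d$d_fp[!is.na(d$d_fp)],
                   d_sp = d$d_sp[!is.na(d$d_sp)],
                   n_fp = NA_integer_, n_sp = NA_integer_),
              class = "property_samples")
  })
}

#' Population-style summary of a property trend
#'
#' Rows for the density-mode level and the 90 % credibility width over the
#' full 24 h, daytime and nighttime windows, one column per AV-node
#' property (delays reported as total pathway delay, i.e. per-node x 10).
#'
#' @param trend Data frame from [property_trend()] with \code{start_ms}.
#' @param recording_start_hour Clock hour of recording start.
#' @return Data frame with columns quantity, window, r_fp, r_sp,
#'   d_fp_total, d_sp_total.
#' @export
trend_report <- function(trend, recording_start_hour = 8) {
  h <- segment_hour(trend$start_ms, recording_start_hour)
  masks <- list(h24 = rep(TRUE, length(h)), day = in_day(h),
                night = in_night(h))
  rows <- list()
  for (q in c("phi_max", "credwidth")) for (w in names(masks)) {
    val <- function(p) {
      x <- if (q == "phi_max") trend[[paste0(p, "_max")]]
      else trend[[paste0(p, "_95")]] - trend[[paste0(p, "_5")]]
      mean(x[masks[[w]]], na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = q, window = w,
      r_fp = val("r_fp"), r_sp = val("r_sp"),
      d_fp_total = total_cd(val("d_fp")),
      d_sp_total = total_cd(val("d_sp")))
  }
  do.call(rbind, rows)
}
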