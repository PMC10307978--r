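PIPELINE_STAGES <- c("train", "stimuli", "responses", "correlations",
                     "distances", "decoding", "report")

CONFIG_KEYS <- c("profile", "seed", "out_dir", "conditions", "orientations",
                 "decoders", "noise_sigma", "n_samples", "static_steps",
                 "hidden", "iterations", "repetitions", "minibatch",
                 "n_scenes", "steps", "bptt", "stages", "resume")

#' Named run profiles
#'
#' `smoke` is the continuous-integration scale (32 units per hidden
#' level, 500 iterations, minibatch 20, two bar orientations, naive
#' Bayes + LDA); `desk` a reduced desk-scale replication (64 units,
#' 2000 iterations, minibatch 100, all orientations and decoders);
#' `full` the full-scale study settings (10^4 iterations x 5 optimizer
#' restarts, minibatch 100).
#'
#' @param profile profile name.
#' @return Named list of pipeline configuration defaults.
#' @export
profile_config <- function(profile = c("smoke", "desk", "full")) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile, seed = 1L, out_dir = "stec_run",
    conditions = c("stec", "sec", "tec"),
    noise_sigma = 0.1, n_samples = 300L, static_steps = 41L,
    steps = 9L, bptt = FALSE, stages = PIPELINE_STAGES, resume = TRUE)
  switch(profile,
    smoke = utils::modifyList(base, list(
      hidden = c(32L, 32L), iterations = 500L, repetitions = 1L,
      minibatch = 20L, n_scenes = 20L,
      orientations = c(0, pi / 2), decoders = c("naive_bayes", "lda"))),
    desk = utils::modifyList(base, list(
      hidden = c(64L, 64L), iterations = 2000L, repetitions = 1L,
      minibatch = 100L, n_scenes = 50L,
      orientations = bar_orientations(), decoders = decoder_names())),
    full = utils::modifyList(base, list(
      hidden = c(64L, 64L), iterations = 10000L, repetitions = 5L,
      minibatch = 100L, n_scenes = 500L,
      orientations = bar_orientations(), decoders = decoder_names())))
}

validate_config <- function(config) {
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  bad_stage <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad_stage))
    stop_invalid("unknown stage(s): %s", paste(bad_stage, collapse = ", "))
  config
}

artifact <- function(manifest, stage, path) {
  manifest$artifacts[[length(manifest$artifacts) + 1L]] <-
    list(stage = stage, path = path,
         md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the full study pipeline
#'
#' Orchestrates the end-to-end run: train the three coding conditions
#' (balanced, spatial-only, temporal-only), generate the bar-stimulus
#' suite, collect position responses, then the correlation, distance and
#' decoding analyses, and finally the directional report. Every stage
#' writes its artifacts under `out_dir` and registers them (with MD5
#' checksums) in the returned manifest; with `resume = TRUE` a stage
#' whose artifacts already exist is skipped.
#'
#' @param config named list overriding [profile_config()] values, or a
#'   path to a YAML/JSON file of such overrides.
#' @param profile base profile name.
#' @return An `stec_manifest` list: config snapshot, master seed,
#'   substream seeds, artifact table, stage timings, package version.
#' @export
run_pipeline <- function(config = list(), profile = "smoke") {
  if (is.character(config) && length(config) == 1)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  profile <- config$profile %||% profile
  cfg <- validate_config(utils::modifyList(profile_config(profile),
                                           as.list(config)))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  manifest <- list(config = cfg, seed = seed,
                   substreams = list(
                     train = substream_seed(seed, "train"),
                     analysis = substream_seed(seed, "analysis"),
                     noise_train = substream_seed(seed, "noise-train"),
                     noise_test = substream_seed(seed, "noise-test")),
                   artifacts = list(), timings = list(),
                   version = as.character(utils::packageVersion("stec")))
  fits <- list()
  pth <- function(...) file.path(cfg$out_dir, paste0(...))
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    manifest$timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))
    res
  }

  if ("train" %in% cfg$stages) timed("train", {
    for (cond in cfg$conditions) {
      base <- pth("params_", cond)
      if (cfg$resume && file.exists(paste0(base, ".bin")) &&
          file.exists(paste0(base, ".json"))) {
        fits[[cond]] <- list(params = load_params(base))
      } else {
        fit <- train_network(
          objective_config(cond),
          training_config(iterations = cfg$iterations,
                          repetitions = cfg$repetitions,
                          minibatch = cfg$minibatch, steps = cfg$steps,
                          hidden = cfg$hidden, n_scenes = cfg$n_scenes,
                          bptt = cfg$bptt,
                          seed = manifest$substreams$train))
        save_params(fit, base)
        utils::write.csv(fit$trace, pth("trace_", cond, ".csv"),
                         row.names = FALSE)
        fits[[cond]] <- fit
      }
      manifest <- artifact(manifest, "train", paste0(base, ".bin"))
      manifest <- artifact(manifest, "train", paste0(base, ".json"))
    }
  }) else stop_invalid("stage 'train' is required by all later stages")
  get_params <- function(cond) fits[[cond]]$params

  if ("stimuli" %in% cfg$stages) timed("stimuli", {
    smooth <- make_smooth_bar_sequences()
    jsonlite::write_json(list(
      n_smooth_sequences = length(smooth),
      frames_per_sequence = length(smooth[[1]]$frames),
      n_positions = N_POSITIONS,
      n_orientations = length(bar_orientations()),
      n_random_per_orientation = N_POSITIONS,
      chance_position = 1 / 9, chance_orientation = 1 / 8),
      pth("stimuli_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest <- artifact(manifest, "stimuli", pth("stimuli_summary.json"))
  })

  need_responses <- any(c("responses", "correlations", "distances") %in%
                          cfg$stages)
  responses <- list()
  if (need_responses) timed("responses", {
    for (cond in cfg$conditions) {
      for (th in cfg$orientations) {
        key <- sprintf("%s_th%.3f", cond, th)
        responses[[key]] <- list(
          moving = collect_position_responses(get_params(cond), th,
                                              "smooth_fwd"),
          static = collect_position_responses(get_params(cond), th, "static",
                                              static_steps = cfg$static_steps))
      }
    }
    f <- pth("responses_index.json")
    jsonlite::write_json(list(keys = names(responses)), f,
                         auto_unbox = TRUE, digits = NA)
    manifest <- artifact(manifest, "responses", f)
  })

  if ("correlations" %in% cfg$stages) timed("correlations", {
    rows <- list()
    for (cond in cfg$conditions) for (th in cfg$orientations) {
      mv <- responses[[sprintf("%s_th%.3f", cond, th)]]$moving
      traj <- run_network(get_params(cond),
                          make_smooth_bar_sequences(th)[[1]])
      for (hier in names(mv$responses)) {
        utc <- unit_trajectory_correlations(traj, hier)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, hierarchy = hier, orientation = th,
          mean_adjacent_correlation =
            mean_adjacent_correlation(mv, hier),
          frac_sig_pos = utc$frac_sig_pos,
          median_abs_r = stats::median(utc$abs_r),
          n_excluded_pairs = utc$n_excluded)
      }
    }
    f <- pth("correlations.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    manifest <- artifact(manifest, "correlations", f)
  })

  if ("distances" %in% cfg$stages) timed("distances", {
    rows <- list()
    for (cond in cfg$conditions) for (th in cfg$orientations) {
      rset <- responses[[sprintf("%s_th%.3f", cond, th)]]
      for (hier in names(rset$moving$responses)) {
        D <- static_vs_moving_distance(rset$static, rset$moving, hier)
        tr <- distance_offset_trend(D)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, hierarchy = hier, orientation = th,
          mean_diagonal = mean(diag(D)), offset_rho = tr$rho)
      }
    }
    f <- pth("distances.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    manifest <- artifact(manifest, "distances", f)
  })

  if ("decoding" %in% cfg$stages) timed("decoding", {
    rows <- list()
    for (cond in cfg$conditions) {
      for (task in c("position", "orientation")) {
        r <- run_decoding(get_params(cond), task, cfg$decoders,
                          cfg$noise_sigma, n_samples = cfg$n_samples,
                          static_steps = cfg$static_steps,
                          seed = manifest$substreams$analysis)
        r$condition <- cond; r$train_kind <- "static"
        rows[[length(rows) + 1L]] <- r
      }
      r <- moving_vs_moving_decode(get_params(cond), "position",
                                   cfg$decoders, cfg$noise_sigma,
                                   n_samples = cfg$n_samples,
                                   seed = manifest$substreams$analysis)
      r$condition <- cond; r$train_kind <- "moving"
      rows[[length(rows) + 1L]] <- r
    }
    f <- pth("decoding.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    manifest <- artifact(manifest, "decoding", f)
  })

  class(manifest) <- "stec_manifest"
  if ("report" %in% cfg$stages) timed("report", {
    rep <- pipeline_report(manifest)
    f <- pth("report.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
    manifest <- artifact(manifest, "report", f)
  })

  jsonlite::write_json(unclass(manifest), pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' @export
print.stec_manifest <- function(x, ...) {
  cat(sprintf("<stec_manifest> profile=%s seed=%d; stages: %s\n",
              x$config$profile, x$seed,
              paste(names(x$timings), collapse = ", ")))
  invisible(x)
}

read_stage_csv <- function(manifest, name) {
  f <- file.path(manifest$config$out_dir, name)
  if (!file.exists(f)) return(NULL)
  utils::read.csv(f)
}

#' Summarize a pipeline run as directional checks
#'
#' Emits the property-check table for the five headline directional
#' claims — adjacent-position correlation, unit-pair correlation
#' structure, static-vs-moving distance, static-to-moving decoding, and
#' moving-to-moving decoding — each comparing the balanced regime to the
#' relevant control, plus the headline stimulus counts. A check whose
#' stage did not run is marked `"not run"`.
#'
#' @param manifest an `stec_manifest` from [run_pipeline()].
#' @return A list with `checks` (data frame: check, comparison, value_a,
#'   value_b, pass) and `counts`.
#' @export
pipeline_report <- function(manifest) {
  cors <- read_stage_csv(manifest, "correlations.csv")
  dists <- read_stage_csv(manifest, "distances.csv")
  decs <- read_stage_csv(manifest, "decoding.csv")
  checks <- list()
  add <- function(check, comparison, a, b, pass)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, comparison = comparison,
      value_a = a, value_b = b,
      pass = if (is.na(pass)) "not run" else as.character(pass))
  cmean <- function(df, cond, col)
    if (is.null(df)) NA_real_ else mean(df[[col]][df$condition == cond])
  add("adjacent_position_correlation", "stec > sec",
      cmean(cors, "stec", "mean_adjacent_correlation"),
      cmean(cors, "sec", "mean_adjacent_correlation"),
      if (is.null(cors)) NA else
        cmean(cors, "stec", "mean_adjacent_correlation") >
        cmean(cors, "sec", "mean_adjacent_correlation"))
  add("unit_pair_significant_positive", "stec > sec",
      cmean(cors, "stec", "frac_sig_pos"), cmean(cors, "sec", "frac_sig_pos"),
      if (is.null(cors)) NA else
        cmean(cors, "stec", "frac_sig_pos") > cmean(cors, "sec", "frac_sig_pos"))
  add("static_vs_moving_distance", "stec < sec",
      cmean(dists, "stec", "mean_diagonal"),
      cmean(dists, "sec", "mean_diagonal"),
      if (is.null(dists)) NA else
        cmean(dists, "stec", "mean_diagonal") <
        cmean(dists, "sec", "mean_diagonal"))
  sm <- function(cond) {
    if (is.null(decs)) return(NA_real_)
    d <- decs[decs$train_kind == "static" & decs$condition == cond, ]
    mean(d$accuracy)
  }
  add("static_to_moving_decoding", "stec > sec", sm("stec"), sm("sec"),
      if (is.null(decs)) NA else sm("stec") > sm("sec"))
  mm <- function(cond) {
    if (is.null(decs)) return(NA_real_)
    d <- decs[decs$train_kind == "moving" & decs$condition == cond, ]
    mean(d$accuracy)
  }
  add("moving_to_moving_decoding", "stec > tec", mm("stec"), mm("tec"),
      if (is.null(decs)) NA else mm("stec") > mm("tec"))
  counts_file <- file.path(manifest$config$out_dir, "stimuli_summary.json")
  counts <- if (file.exists(counts_file))
    jsonlite::read_json(counts_file, simplifyVector = TRUE)
  else "not run"
  list(checks = do.call(rbind, checks), counts = counts,
       seed = manifest$seed, profile = manifest$config$profile)
}
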