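# Reduced-scale trained networks shared across test files. Training is
# expensive, so each (condition, seed) pair is fitted lazily and cached
# for the duration of the test run. The scale (32 units per hidden
# level, 3000 iterations, minibatch 20) is the package's reduced
# replication scale; see the methods vignette for what this scale does
# and does not show.

.fit_cache <- new.env(parent = emptyenv())

TEST_SEEDS <- c(201L, 202L, 203L)

smoke_training <- function(seed) {
  training_config(iterations = 3000L, repetitions = 1L, minibatch = 20L,
                  hidden = c(32L, 32L), n_scenes = 20L, seed = seed,
                  bptt = FALSE)
}

smoke_fit <- function(condition, seed) {
  key <- paste0(condition, "_", seed)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- train_network(objective_config(condition),
                                       smoke_training(seed))
  .fit_cache[[key]]
}

# Analysis summaries per fit, also cached (response collection over all
# orientations is itself non-trivial).
smoke_metrics <- function(condition, seed,
                          orientations = bar_orientations()) {
  key <- paste0("metrics_", condition, "_", seed)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  fit <- smoke_fit(condition, seed)
  rows <- list()
  for (th in orientations) {
    mv <- collect_position_responses(fit$params, th, "smooth_fwd")
    st <- collect_position_responses(fit$params, th, "static")
    traj <- run_network(fit$params, make_smooth_bar_sequences(th)[[1]])
    for (hier in c("lower", "upper")) {
      u <- unit_trajectory_correlations(traj, hier)
      D <- static_vs_moving_distance(st, mv, hier)
      rows[[length(rows) + 1L]] <- data.frame(
        orientation = th, hierarchy = hier,
        adj_corr = mean_adjacent_correlation(mv, hier),
        frac_sig_pos = u$frac_sig_pos,
        median_abs_r = stats::median(u$abs_r),
        diag_dist = mean(diag(D)),
        offset_rho = distance_offset_trend(D)$rho,
        step_change = mean(abs(diff(traj$hidden[[hier]]))),
        mean_resp = mean(traj$hidden[[hier]][-1, ]))
    }
  }
  .fit_cache[[key]] <- do.call(rbind, rows)
  .fit_cache[[key]]
}

# Tiny architecture for fast exact-arithmetic tests.
toy_params <- function(input = 4L, hidden = c(2L, 2L), seed = 7L)
  init_params(input_size = input, hidden = hidden, seed = seed)

# Shared decoding evaluations for the acceptance checks (cached; the
# response generation is the expensive part).
decoding_table <- function() {
  if (!is.null(.fit_cache$dec6)) return(.fit_cache$dec6)
  rows <- list()
  for (cond in c("stec", "sec")) for (s in TEST_SEEDS) {
    fit <- smoke_fit(cond, s)
    for (task in c("position", "orientation")) {
      r <- run_decoding(fit$params, task, c("naive_bayes", "lda"),
                        noise_sigma = 0.1, seed = s)
      r$cond <- cond; r$seed <- s
      rows[[length(rows) + 1L]] <- r
    }
  }
  .fit_cache$dec6 <- do.call(rbind, rows)
  .fit_cache$dec6
}

moving_decoding_table <- function() {
  if (!is.null(.fit_cache$dec7)) return(.fit_cache$dec7)
  rows <- list()
  for (cond in c("stec", "tec")) for (s in TEST_SEEDS) {
    fit <- smoke_fit(cond, s)
    r <- moving_vs_moving_decode(fit$params, "position", decoder_names(),
                                 noise_sigma = 0.1, seed = s)
    r$cond <- cond; r$seed <- s
    rows[[length(rows) + 1L]] <- r
  }
  .fit_cache$dec7 <- do.call(rbind, rows)
  .fit_cache$dec7
}
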