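task_classes <- function(task, orientation = 0) {
  switch(task,
    position = list(classes = paste0("pos", 16:24),
                    stimuli = lapply(16:24, function(p)
                      list(orientation = orientation, position = p,
                           label = paste0("pos", p)))),
    orientation = {
      stim <- list()
      for (k in 0:7) for (p in 19:21)
        stim[[length(stim) + 1L]] <-
          list(orientation = k * pi / 8, position = p, label = paste0("ori", k))
      list(classes = paste0("ori", 0:7), stimuli = stim)
    },
    stop_invalid("task must be 'position' or 'orientation'"))
}

#' Build noise-augmented decoding responses
#'
#' Generates the response samples used for decoding. Every presented
#' frame receives fresh i.i.d. Gaussian pixel noise (standard deviation
#' `noise_sigma`, not clipped), and the network is run on the noisy
#' sequence:
#'
#' * `kind = "static"`: each task stimulus (bar at one orientation and
#'   position) is presented for `static_steps` steps, `n_samples`
#'   independent times; the final-step hidden responses are the samples.
#' * `kind = "moving"`: the smooth forward and backward sequences are run
#'   `n_samples` times (alternating direction); the hidden response at a
#'   task position's *encoding step* — the first state driven by the
#'   frame showing it — is that position's sample, so each stimulus
#'   again contributes `n_samples` samples.
#'
#' The position task uses the 9 centered bars (positions 16-24) of one
#' orientation (chance 1/9); the orientation task uses the 3 centered
#' bars (19-21) of each of the 8 orientations (chance 1/8).
#'
#' @param params trained `stec_params`.
#' @param task `"position"` or `"orientation"`.
#' @param kind `"static"` or `"moving"`.
#' @param noise_sigma noise standard deviation.
#' @param n_samples samples per stimulus (study design: 300).
#' @param orientation bar angle for the position task.
#' @param static_steps static presentation length.
#' @param seed substream seed; use different seeds for train and test
#'   sets so their noise draws are disjoint.
#' @return List with `x` (named list of samples-by-units matrices, one
#'   per hidden level), `y` (labels), `task`, `kind`, `seed`.
#' @export
decoding_responses <- function(params, task = c("position", "orientation"),
                               kind = c("static", "moving"),
                               noise_sigma = 0.1, n_samples = 300L,
                               orientation = 0, static_steps = 41L,
                               seed = 1L) {
  task <- match.arg(task); kind <- match.arg(kind)
  check_params(params)
  H <- length(params$sizes) - 1L
  n_in <- params$sizes[1]
  spec <- task_classes(task, orientation)
  xs <- lapply(seq_len(H), function(h) NULL)
  ys <- character(0)

  if (kind == "static") {
    frame_rows <- do.call(rbind, lapply(spec$stimuli, function(s)
      as.vector(rasterize_bar(s$orientation, s$position))))
    final <- cpp_static_responses(params$W_bu, params$W_rec, params$W_td,
                                  params$W_gen, params$b, params$b_gen,
                                  frame_rows, n_samples, static_steps,
                                  noise_sigma,
                                  substream_seed(seed, paste0("static-", task)))
    for (h in seq_len(H)) xs[[h]] <- final[[h]]
    ys <- unlist(lapply(spec$stimuli, function(s) rep(s$label, n_samples)))
  } else {
    orientations <- unique(vapply(spec$stimuli, `[[`, numeric(1), "orientation"))
    for (th in orientations) {
      barmat <- do.call(rbind, lapply(0:(N_POSITIONS - 1L),
        function(p) as.vector(rasterize_bar(th, p))))
      fwd <- rep(c(TRUE, FALSE), length.out = n_samples)
      hidden <- cpp_moving_responses(params$W_bu, params$W_rec, params$W_td,
                                     params$W_gen, params$b, params$b_gen,
                                     barmat, fwd, noise_sigma,
                                     substream_seed(seed,
                                       sprintf("moving-%s-%.4f", task, th)))
      for (s in Filter(function(s) s$orientation == th, spec$stimuli)) {
        # encoding-step readout: the first state driven by the frame that
        # shows position p (fwd: state p+2; bwd: state 42-p)
        st_f <- s$position + 2L
        st_b <- N_POSITIONS - s$position + 1L
        for (h in seq_len(H)) {
          samp <- hidden[[h]][[st_f]]
          samp[!fwd, ] <- hidden[[h]][[st_b]][!fwd, , drop = FALSE]
          xs[[h]] <- rbind(xs[[h]], samp)
        }
        ys <- c(ys, rep(s$label, n_samples))
      }
    }
  }
  names(xs) <- hierarchy_names(H)
  list(x = xs, y = factor(ys, levels = spec$classes), task = task,
       kind = kind, noise_sigma = noise_sigma, seed = seed)
}

#' Run a full decoding evaluation
#'
#' Builds a noise-augmented training set and an independently augmented
#' test set, then fits and scores each requested decoder on each hidden
#' level separately. The study's main probe trains on static-bar
#' responses and tests on moving-bar responses; `train_kind = test_kind
#' = "moving"` gives the moving-vs-moving control.
#'
#' @param params trained `stec_params`.
#' @param task `"position"` or `"orientation"`.
#' @param decoders subset of [decoder_names()].
#' @param noise_sigma noise standard deviation (study grid: 0.025, 0.05,
#'   0.1, 0.2, 0.4).
#' @param train_kind,test_kind `"static"` or `"moving"`.
#' @param n_samples samples per stimulus per set.
#' @param orientation bar angle for the position task.
#' @param static_steps static presentation length.
#' @param seed master seed; train/test noise substreams are derived from
#'   it and must differ.
#' @param train_seed,test_seed explicit substream seeds (must differ;
#'   identical seeds would leak train noise into the test set).
#' @return Data frame with one row per (hierarchy, decoder):
#'   task, decoder, hierarchy, noise_sigma, accuracy, chance, n_train,
#'   n_test.
#' @export
run_decoding <- function(params, task = c("position", "orientation"),
                         decoders = c("naive_bayes", "lda"),
                         noise_sigma = 0.1,
                         train_kind = "static", test_kind = "moving",
                         n_samples = 300L, orientation = 0,
                         static_steps = 41L, seed = 1L,
                         train_seed = substream_seed(seed, "noise-train"),
                         test_seed = substream_seed(seed, "noise-test")) {
  task <- match.arg(task)
  if (train_seed == test_seed)
    stop_invalid("train_seed and test_seed must differ (noise leakage)")
  decoders <- match.arg(decoders, DECODERS, several.ok = TRUE)
  train <- decoding_responses(params, task, train_kind, noise_sigma,
                              n_samples, orientation, static_steps,
                              seed = train_seed)
  test <- decoding_responses(params, task, test_kind, noise_sigma,
                             n_samples, orientation, static_steps,
                             seed = test_seed)
  out <- list()
  for (hier in names(train$x)) {
    for (dec in decoders) {
      res <- decode_responses(list(x = train$x[[hier]], y = train$y),
                              list(x = test$x[[hier]], y = test$y),
                              decoder = dec, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        task = task, decoder = dec, hierarchy = hier,
        noise_sigma = noise_sigma, accuracy = res$accuracy,
        chance = res$chance, n_train = res$n_train, n_test = res$n_test,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Moving-vs-moving decoding control
#'
#' As [run_decoding()], but both the training and the test set are built
#' from (independently noise-augmented) moving-bar responses. Used to
#' show that excessive smoothness (the temporal-only regime) makes
#' responses to different positions indistinguishable.
#'
#' @inheritParams run_decoding
#' @export
moving_vs_moving_decode <- function(params, task = "position",
                                    decoders = decoder_names(),
                                    noise_sigma = 0.1, n_samples = 300L,
                                    orientation = 0, seed = 1L) {
  run_decoding(params, task, decoders, noise_sigma,
               train_kind = "moving", test_kind = "moving",
               n_samples = n_samples, orientation = orientation, seed = seed)
}
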