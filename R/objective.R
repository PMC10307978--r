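#' Compensation density over the response interval
#'
#' The response-entropy term measures each unit's empirical response
#' density against a reference ("compensation") density on \[0, 1\].
#' A uniform reference drives responses toward maximum entropy (the
#' classical efficient-coding target, used at the lower hierarchy); a
#' reference concentrated near zero drives responses sparse (upper
#' hierarchy).
#'
#' @param type `"uniform"` or `"sparse"`.
#' @param n_bins histogram resolution.
#' @param rate decay rate of the sparse density: bin mass proportional to
#'   `exp(-rate * bin_center)`.
#' @return Probability vector of length `n_bins` (sums to 1).
#' @export
compensation_density <- function(type = c("uniform", "sparse"),
                                 n_bins = 16L, rate = 4) {
  type <- match.arg(type)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  q <- switch(type,
              uniform = rep(1, n_bins),
              sparse  = exp(-rate * centers))
  q / sum(q)
}

#' Objective configuration
#'
#' The training objective is `L = L_temporal + lambda * L_spatial`.
#' The balancing parameter has three study presets: `stec` (lambda = 5,
#' the balanced spatio-temporal regime), `sec` (lambda = 1000, spatial
#' efficiency only) and `tec` (lambda = 0.01, temporal smoothness only).
#'
#' @param preset one of `"stec"`, `"sec"`, `"tec"`; ignored if `lambda`
#'   is given directly.
#' @param lambda nonnegative balancing parameter overriding the preset.
#' @param n_bins histogram resolution of the entropy estimator.
#' @param bandwidth Gaussian kernel bandwidth of the soft (differentiable)
#'   histogram, in response units; 0 selects exact hard binning.
#' @param compensation list of per-hidden-level densities (`"uniform"`,
#'   `"sparse"`, or explicit probability vectors). Default: uniform at
#'   every level except the topmost, which is sparse.
#' @param n_levels number of hidden levels the default compensation list
#'   is built for.
#' @return A list of class `stec_objective`.
#' @export
objective_config <- function(preset = c("stec", "sec", "tec"), lambda = NULL,
                             n_bins = 16L, bandwidth = 1 / n_bins,
                             compensation = NULL, n_levels = 2L) {
  preset <- match.arg(preset)
  if (is.null(lambda))
    lambda <- c(stec = 5, sec = 1000, tec = 0.01)[[preset]]
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  if (is.null(compensation))
    compensation <- c(as.list(rep("uniform", n_levels - 1L)), list("sparse"))
  compensation <- lapply(compensation, function(q) {
    if (is.character(q)) compensation_density(q, n_bins) else {
      stopifnot(length(q) == n_bins, all(q >= 0))
      q / sum(q)
    }
  })
  structure(list(preset = preset, lambda = lambda, n_bins = as.integer(n_bins),
                 bandwidth = bandwidth, compensation = compensation),
            class = "stec_objective")
}

#' Training configuration
#'
#' Optimization constants of the study: Adam with `alpha = 0.001`,
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`; 10^4 iterations per
#' repetition, 5 repetitions (a repetition restart re-initializes the
#' optimizer state, not the weights); minibatch of 100 gaze sequences of
#' 9 steps each.
#'
#' @param iterations iterations per repetition.
#' @param repetitions number of optimizer restarts.
#' @param minibatch gaze sequences per iteration.
#' @param steps time steps per gaze sequence.
#' @param hidden hidden-level sizes.
#' @param n_scenes size of the surrogate-scene pool sampled from.
#' @param alpha,beta1,beta2,eps Adam constants.
#' @param max_speed gaze speed cap (L-infinity, pixels/step).
#' @param bptt if `TRUE`, backpropagate through the full unrolled
#'   sequence; the default truncates gradients at one time step (each
#'   update sees only the step that produced it, with earlier states
#'   treated as constants).
#' @param restart_weights if `TRUE`, a repetition restart also
#'   re-initializes the weights (best-of-run weights are not kept; this
#'   is the alternative reading of the restart protocol).
#' @param seed master seed; all substreams derive from it.
#' @return A list of class `stec_training`.
#' @export
training_config <- function(iterations = 10000L, repetitions = 5L,
                            minibatch = 100L, steps = 9L,
                            hidden = c(64L, 64L), n_scenes = 100L,
                            alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8, max_speed = 4L,
                            bptt = FALSE, restart_weights = FALSE,
                            seed = 1L) {
  stopifnot(iterations >= 0, repetitions >= 1, minibatch >= 1,
            steps >= 2, n_scenes >= 1)
  structure(as.list(environment()), class = "stec_training")
}

#' Temporal smoothness loss
#'
#' Summed squared step-to-step change, accumulated over the input level
#' and every hidden level: for a hidden level the squared L2 norm of the
#' difference between consecutive population responses (averaged over
#' steps); for the input level the squared L2 norm of the difference
#' between the generated input and the presented stimulus at each step.
#' Terms are summed over units rather than unit-averaged so that the
#' temporal and spatial objectives sit on a common per-population scale
#' (see the methods vignette for the calibration argument). Minimizing
#' it smooths response trajectories and trains the generative projection
#' to track the stimulus.
#'
#' @param trajectory an `stec_trajectory` from [run_network()].
#' @param stimuli the presented `stec_sequence` (or list of frames);
#'   defaults to the trajectory's recorded input.
#' @return Nonnegative scalar.
#' @export
temporal_loss <- function(trajectory, stimuli = NULL) {
  Tn <- nrow(trajectory$gen)
  if (is.null(Tn) || Tn < 2) stop_invalid("trajectory must span >= 2 steps")
  S <- if (is.null(stimuli)) trajectory$input else
    do.call(rbind, lapply(if (inherits(stimuli, "stec_sequence"))
      stimuli$frames else stimuli, as.vector))
  terms <- vapply(trajectory$hidden, function(X)
    sum((X[-1, , drop = FALSE] - X[-Tn, , drop = FALSE])^2) / (Tn - 1),
    numeric(1))
  input_term <- sum((trajectory$gen[-1, , drop = FALSE] -
                       S[-1, , drop = FALSE])^2) / (Tn - 1)
  sum(c(input_term, terms))
}

# Soft-histogram machinery ---------------------------------------------------

# Per-element bin assignment. bandwidth > 0: normalized Gaussian kernel
# weights (differentiable). bandwidth == 0: one-hot hard binning.
bin_weights <- function(r, n_bins, bandwidth) {
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  if (bandwidth > 0) {
    D <- outer(r, centers, "-")
    W <- exp(-D^2 / (2 * bandwidth^2))
    list(phi = W / rowSums(W), D = D, centers = centers)
  } else {
    idx <- pmin(pmax(ceiling(r * n_bins), 1L), n_bins)
    phi <- matrix(0, length(r), n_bins)
    phi[cbind(seq_along(r), idx)] <- 1
    list(phi = phi, D = NULL, centers = centers)
  }
}

#' Spatial (response-entropy) loss
#'
#' Estimates each unit's response density over \[0, 1\] by a histogram —
#' soft Gaussian-kernel binning by default, so the estimate is
#' differentiable — and returns the mean over units of the KL divergence
#' from the empirical density to the unit's compensation density.
#' Minimizing it drives the response distribution toward the reference:
#' uniform reference = maximum entropy, near-zero reference = sparseness.
#'
#' @param responses numeric matrix, pooled response samples (rows) by
#'   units (columns); values must lie strictly in (0, 1).
#' @param compensation probability vector of length `n_bins`, e.g. from
#'   [compensation_density()].
#' @param n_bins histogram resolution.
#' @param bandwidth kernel bandwidth; 0 for exact hard binning.
#' @return Nonnegative scalar (KL divergence, nats).
#' @export
spatial_loss <- function(responses, compensation, n_bins = length(compensation),
                         bandwidth = 1 / n_bins) {
  R <- as.matrix(responses)
  if (any(R <= 0) || any(R >= 1))
    stop_invalid("responses must lie strictly in (0, 1)")
  stopifnot(length(compensation) == n_bins)
  q <- compensation / sum(compensation)
  N <- nrow(R); J <- ncol(R)
  bw <- bin_weights(as.vector(R), n_bins, bandwidth)
  unit <- rep(seq_len(J), each = N)
  p <- rowsum(bw$phi, unit) / N                      # J x n_bins
  kl <- rowSums(ifelse(p > 0, p * log(p / rep(q, each = J)), 0))
  mean(kl)
}

# Gradient of spatial_loss with respect to each response element
# (soft kernel only; the hard histogram is piecewise constant).
spatial_loss_grad <- function(R, q, n_bins, bandwidth) {
  N <- nrow(R); J <- ncol(R)
  bw <- bin_weights(as.vector(R), n_bins, bandwidth)
  unit <- rep(seq_len(J), each = N)
  p <- rowsum(bw$phi, unit) / N
  A <- log(p / rep(q, each = J)) + 1                 # dKL/dp + normalization
  A_elem <- A[unit, , drop = FALSE]
  U <- -bw$D / bandwidth^2                           # d log w / d r
  ubar <- rowSums(bw$phi * U)
  g <- rowSums(A_elem * bw$phi * (U - ubar)) / (N * J)
  matrix(g, N, J)
}

#' Combined training loss
#'
#' `L = L_temporal + lambda * L_spatial`, where the spatial term is the
#' sum over hidden levels of their entropy losses, each measured against
#' that level's compensation density. Responses are pooled over all
#' post-initialization time steps (and, during training, the minibatch).
#'
#' @param trajectory an `stec_trajectory`.
#' @param stimuli presented frames (see [temporal_loss()]).
#' @param config an `stec_objective` from [objective_config()].
#' @return A list (`stec_loss_report`) with `total`, `temporal`, `spatial`
#'   (named per level) and `lambda`.
#' @export
total_loss <- function(trajectory, stimuli = NULL, config = objective_config()) {
  temporal <- temporal_loss(trajectory, stimuli)
  Tn <- nrow(trajectory$gen)
  spatial <- vapply(seq_along(trajectory$hidden), function(h)
    ncol(trajectory$hidden[[h]]) *
      spatial_loss(trajectory$hidden[[h]][-1, , drop = FALSE],
                   config$compensation[[h]], config$n_bins, config$bandwidth),
    numeric(1))
  names(spatial) <- names(trajectory$hidden)
  structure(list(total = temporal + config$lambda * sum(spatial),
                 temporal = temporal, spatial = spatial,
                 lambda = config$lambda),
            class = "stec_loss_report")
}

#' @export
print.stec_loss_report <- function(x, ...) {
  cat(sprintf("loss: total=%.6g  temporal=%.6g  spatial=[%s]  lambda=%g\n",
              x$total, x$temporal,
              paste(sprintf("%s=%.4g", names(x$spatial), x$spatial),
                    collapse = ", "), x$lambda))
  invisible(x)
}

# Loss and gradients on one minibatch ---------------------------------------
# states: output of run_network_batch; frames: list over t of B x input.
minibatch_loss_grads <- function(params, states, frames, obj, bptt = FALSE,
                                 want_grads = TRUE) {
  H <- length(states$hidden); T_len <- length(frames)
  B <- nrow(frames[[1]]); n_in <- ncol(frames[[1]])
  n_h <- params$sizes[-1]
  denomT <- T_len - 1

  # --- loss values (per-level summed squared differences; see vignette
  # for why the terms are summed, not unit-averaged)
  temporal <- 0
  for (t in 2:T_len) {
    temporal <- temporal + sum((states$gen[[t]] - frames[[t]])^2)
    for (h in seq_len(H))
      temporal <- temporal +
        sum((states$hidden[[h]][[t]] - states$hidden[[h]][[t - 1]])^2)
  }
  temporal <- temporal / (B * denomT)
  pooled <- lapply(seq_len(H), function(h)
    do.call(rbind, states$hidden[[h]][2:T_len]))
  spatial <- vapply(seq_len(H), function(h)
    n_h[h] * spatial_loss(pooled[[h]], obj$compensation[[h]], obj$n_bins,
                          obj$bandwidth),
    numeric(1))
  total <- temporal + obj$lambda * sum(spatial)
  if (!want_grads)
    return(list(total = total, temporal = temporal, spatial = spatial))

  # --- direct dL/dX at every hidden state (temporal + spatial paths)
  dX <- lapply(seq_len(H), function(h) vector("list", T_len))
  for (h in seq_len(H)) {
    scale <- 2 / (denomT * B)
    sg <- if (obj$lambda > 0 && obj$bandwidth > 0)
      obj$lambda * n_h[h] * spatial_loss_grad(pooled[[h]], obj$compensation[[h]],
                                              obj$n_bins, obj$bandwidth)
    else NULL
    for (t in 2:T_len) {
      d <- scale * (states$hidden[[h]][[t]] - states$hidden[[h]][[t - 1]])
      if (t < T_len)
        d <- d - scale * (states$hidden[[h]][[t + 1]] - states$hidden[[h]][[t]])
      if (!is.null(sg))
        d <- d + sg[(t - 2) * B + seq_len(B), , drop = FALSE]
      dX[[h]][[t]] <- d
    }
  }
  dG <- lapply(2:T_len, function(t)
    (2 / (denomT * B)) * (states$gen[[t]] - frames[[t]]))

  # --- backward accumulation into weight gradients
  g <- zero_like(params)
  dAg <- vector("list", T_len)
  for (t in 2:T_len)
    dAg[[t]] <- dG[[t - 1]] * states$gen[[t]] * (1 - states$gen[[t]])
  dA <- lapply(seq_len(H), function(h) vector("list", T_len))
  for (t in T_len:2) {
    for (h in seq_len(H)) {
      D <- dX[[h]][[t]]
      if (bptt && t < T_len) {
        D <- D + dA[[h]][[t + 1]] %*% t(params$W_rec[[h]])
        if (h < H) D <- D + dA[[h + 1]][[t + 1]] %*% t(params$W_bu[[h + 1]])
        if (h > 1) D <- D + dA[[h - 1]][[t + 1]] %*% t(params$W_td[[h - 1]])
        if (h == 1) D <- D + dAg[[t + 1]] %*% t(params$W_gen)
      }
      X <- states$hidden[[h]][[t]]
      dA[[h]][[t]] <- D * X * (1 - X)
    }
  }
  for (t in 2:T_len) {
    below_prev <- states$input[[t - 1]]
    for (h in seq_len(H)) {
      a <- dA[[h]][[t]]
      g$W_bu[[h]] <- g$W_bu[[h]] + crossprod(below_prev, a)
      g$W_rec[[h]] <- g$W_rec[[h]] +
        crossprod(states$hidden[[h]][[t - 1]], a)
      if (h < H)
        g$W_td[[h]] <- g$W_td[[h]] +
          crossprod(states$hidden[[h + 1]][[t - 1]], a)
      g$b[[h]] <- g$b[[h]] + colSums(a)
      below_prev <- states$hidden[[h]][[t - 1]]
    }
    g$W_gen <- g$W_gen + crossprod(states$hidden[[1]][[t - 1]], dAg[[t]])
    g$b_gen <- g$b_gen + colSums(dAg[[t]])
  }
  list(total = total, temporal = temporal, spatial = spatial, grads = g)
}

zero_like <- function(params) {
  z <- function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m))
  list(W_bu = lapply(params$W_bu, z), W_rec = lapply(params$W_rec, z),
       W_td = lapply(params$W_td, z), W_gen = z(params$W_gen),
       b = lapply(params$b, z), b_gen = z(params$b_gen))
}

PARAM_LEAVES <- c("W_bu", "W_rec", "W_td", "W_gen", "b", "b_gen")

#' Train a network under the combined objective
#'
#' Stochastic gradient descent with Adam. Each iteration samples a
#' minibatch of gaze sequences from the surrogate-scene pool, unrolls the
#' network, evaluates `L = L_temporal + lambda * L_spatial`, and updates
#' every weight matrix and bias from the single combined loss. By default
#' gradients are truncated at one time step (states one step back are
#' treated as constants), which keeps credit assignment local in time;
#' full backpropagation through the unrolled sequence is available via
#' `training$bptt`. Every `iterations` updates the Adam moment estimates
#' are reset (a "repetition restart"), `repetitions` times in total.
#'
#' @param objective an `stec_objective`.
#' @param training an `stec_training`.
#' @param params optional warm-start `stec_params`; default fresh
#'   initialization from the training seed.
#' @param scenes optional list of scene matrices; default a pool of
#'   `training$n_scenes` surrogate scenes.
#' @param trace_every record the loss trace every this many iterations.
#' @param engine `"cpp"` (compiled core, default) or `"r"` (the pure-R
#'   reference implementation; identical math, used for cross-checks).
#' @return An object of class `stec_fit`: `params`, a `trace` data frame
#'   (iteration, temporal, per-level spatial, total), and the configs.
#' @export
train_network <- function(objective = objective_config(),
                          training = training_config(),
                          params = NULL, scenes = NULL, trace_every = 10L,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (training$restart_weights) engine <- "r"   # only the reference engine
  seed <- training$seed
  if (is.null(params))
    params <- init_params(hidden = training$hidden, seed = seed)
  H <- length(params$sizes) - 1L
  if (length(objective$compensation) != H)
    objective$compensation <-
      objective_config(objective$preset, objective$lambda, objective$n_bins,
                       objective$bandwidth, n_levels = H)$compensation
  if (is.null(scenes))
    scenes <- lapply(seq_len(training$n_scenes), function(i)
      surrogate_scene(substream_seed(seed, "scenes") + i))
  patch <- as.integer(sqrt(params$sizes[1]))
  draws <- draw_training_batches(training, length(scenes),
                                 dim(scenes[[1]]), patch)
  if (engine == "cpp") {
    res <- cpp_train_loop(params$W_bu, params$W_rec, params$W_td,
                          params$W_gen, params$b, params$b_gen,
                          scenes, draws,
                          training$iterations, training$repetitions,
                          training$minibatch, training$steps,
                          objective$lambda, objective$compensation,
                          objective$n_bins, objective$bandwidth,
                          training$alpha, training$beta1, training$beta2,
                          training$eps, training$bptt, trace_every, patch)
    if (res$diverged)
      stop(sprintf(
        "training diverged at iteration %d (total loss not finite)",
        res$iterations_run), call. = FALSE)
    for (nm in c("W_bu", "W_rec", "W_td", "W_gen", "b", "b_gen"))
      params[[nm]] <- res[[nm]]
    sp <- res$trace_spatial
    colnames(sp) <- paste0("spatial_", hierarchy_names(H))
    trace <- data.frame(iteration = res$trace_iteration,
                        temporal = res$trace_temporal, sp,
                        total = res$trace_total)
  } else {
    trace <- list()
    total_iter <- 0L
    for (rep_i in seq_len(training$repetitions)) {
      adam <- adam_init(params)                   # restart: fresh moments
      if (training$restart_weights && rep_i > 1)
        params <- init_params(hidden = training$hidden, seed = seed + rep_i)
      for (it in seq_len(training$iterations)) {
        total_iter <- total_iter + 1L
        rows <- (total_iter - 1L) * training$minibatch +
          seq_len(training$minibatch)
        frames <- frames_from_draws(draws[rows, , drop = FALSE], scenes,
                                    training$steps, patch)
        states <- run_network_batch_r(params, frames)
        lg <- minibatch_loss_grads(params, states, frames, objective,
                                   bptt = training$bptt)
        if (!is.finite(lg$total))
          stop(sprintf(
            "training diverged at iteration %d (total loss not finite)",
            total_iter), call. = FALSE)
        upd <- adam_update(adam, params, lg$grads, training)
        adam <- upd$adam; params <- upd$params
        if (total_iter %% trace_every == 0L || total_iter == 1L)
          trace[[length(trace) + 1L]] <-
            c(iteration = total_iter, temporal = lg$temporal,
              stats::setNames(lg$spatial,
                              paste0("spatial_", hierarchy_names(H))),
              total = lg$total)
      }
    }
    trace <- as.data.frame(do.call(rbind, trace))
  }
  structure(list(params = params, trace = trace,
                 objective = objective, training = training),
            class = "stec_fit")
}

# Pre-draw every minibatch's gaze trajectories (scene index, start
# corner, realized velocity) from one substream. The same in-bounds
# magnitude-adjustment rule as sample_gaze_sequence applies; with a
# constant velocity it suffices to check the end points.
draw_training_batches <- function(training, n_scenes, scene_dim, patch) {
  total <- training$iterations * training$repetitions * training$minibatch
  if (total == 0L) return(matrix(integer(0), 0, 5))
  rmax <- scene_dim[1] - patch
  cmax <- scene_dim[2] - patch
  d <- with_seed(substream_seed(training$seed, "gaze-stream"), {
    cbind(scene = sample.int(n_scenes, total, replace = TRUE),
          r0 = sample.int(rmax + 1L, total, replace = TRUE) - 1L,
          c0 = sample.int(cmax + 1L, total, replace = TRUE) - 1L,
          mag = sample.int(training$max_speed + 1L, total,
                           replace = TRUE) - 1L,
          ang = stats::runif(total, 0, 2 * pi))
  })
  span <- training$steps - 1L
  vr <- integer(total); vc <- integer(total)
  remaining <- seq_len(total)
  for (m in seq(training$max_speed, 0)) {
    if (!length(remaining)) break
    idx <- remaining[d[remaining, "mag"] >= m]
    if (!length(idx)) next
    v1 <- pmax(pmin(round(m * cos(d[idx, "ang"])), m), -m)
    v2 <- pmax(pmin(round(m * sin(d[idx, "ang"])), m), -m)
    er <- d[idx, "r0"] + span * v1
    ec <- d[idx, "c0"] + span * v2
    ok <- er >= 0 & er <= rmax & ec >= 0 & ec <= cmax
    vr[idx[ok]] <- v1[ok]
    vc[idx[ok]] <- v2[ok]
    remaining <- setdiff(remaining, idx[ok])
  }
  cbind(scene = as.integer(d[, "scene"]), r0 = as.integer(d[, "r0"]),
        c0 = as.integer(d[, "c0"]), vr = vr, vc = vc)
}

frames_from_draws <- function(draws, scenes, steps, patch) {
  lapply(seq_len(steps) - 1L, function(t)
    do.call(rbind, lapply(seq_len(nrow(draws)), function(b) {
      sc <- scenes[[draws[b, "scene"]]]
      r0 <- draws[b, "r0"] + t * draws[b, "vr"]
      c0 <- draws[b, "c0"] + t * draws[b, "vc"]
      as.vector(sc[r0 + seq_len(patch), c0 + seq_len(patch)])
    })))
}

#' @export
print.stec_fit <- function(x, ...) {
  last <- if (nrow(x$trace)) x$trace[nrow(x$trace), ] else NULL
  cat(sprintf("<stec_fit> preset=%s lambda=%g, %d trace points%s\n",
              x$objective$preset, x$objective$lambda, nrow(x$trace),
              if (!is.null(last)) sprintf(", final total=%.5g", last$total)
              else ""))
  invisible(x)
}

# Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(adam, params, grads, cfg) {
  adam$t <- adam$t + 1L
  bc1 <- 1 - cfg$beta1^adam$t
  bc2 <- 1 - cfg$beta2^adam$t
  step1 <- function(p, g, m, v) {
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    p <- p - cfg$alpha * (m / bc1) / (sqrt(v / bc2) + cfg$eps)
    list(p = p, m = m, v = v)
  }
  for (nm in PARAM_LEAVES) {
    if (is.list(params[[nm]])) {
      for (i in seq_along(params[[nm]])) {
        r <- step1(params[[nm]][[i]], grads[[nm]][[i]],
                   adam$m[[nm]][[i]], adam$v[[nm]][[i]])
        params[[nm]][[i]] <- r$p
        adam$m[[nm]][[i]] <- r$m
        adam$v[[nm]][[i]] <- r$v
      }
    } else {
      r <- step1(params[[nm]], grads[[nm]], adam$m[[nm]], adam$v[[nm]])
      params[[nm]] <- r$p
      adam$m[[nm]] <- r$m
      adam$v[[nm]] <- r$v
    }
  }
  list(adam = adam, params = params)
}
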