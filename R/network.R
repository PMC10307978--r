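#' Initialize network parameters
#'
#' The model is a bidirectionally connected hierarchy: a clamped visual
#' input level (64 x 64 = 4096 units) and `H` hidden levels (64 units
#' each in the full-scale study; the lowest hidden level is "lower", the
#' topmost "upper"). Each hidden level `h` receives bottom-up input from
#' the level below, recurrent input from itself, and top-down input from
#' the level above (absent at the top). A separate top-down generative
#' projection from the lowest hidden level produces the "generated input"
#' that the temporal objective compares against the stimulus.
#'
#' Weights are i.i.d. zero-mean Gaussian scaled by `1/sqrt(fan-in)`;
#' biases start at zero.
#'
#' @param input_size number of input units (flattened frame).
#' @param hidden integer vector of hidden-level sizes, lowest first.
#' @param seed integer substream seed.
#' @return An object of class `stec_params` with elements `W_bu`, `W_rec`,
#'   `W_td` (lists over hidden levels; matrices are source x target),
#'   `W_gen`, biases `b` and `b_gen`, and `sizes`.
#' @export
init_params <- function(input_size = 4096L, hidden = c(64L, 64L), seed = 1L) {
  H <- length(hidden)
  stopifnot(H >= 1, all(hidden >= 1))
  sizes <- c(input_size, hidden)
  gmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  params <- with_seed(substream_seed(seed, "init"), {
    list(
      W_bu  = lapply(seq_len(H), function(h) gmat(sizes[h], sizes[h + 1])),
      W_rec = lapply(seq_len(H), function(h) gmat(sizes[h + 1], sizes[h + 1])),
      W_td  = if (H > 1)
        lapply(seq_len(H - 1), function(h) gmat(sizes[h + 2], sizes[h + 1]))
      else list(),
      W_gen = gmat(hidden[1], input_size),
      b     = lapply(seq_len(H), function(h) numeric(hidden[h])),
      b_gen = numeric(input_size)
    )
  })
  params$sizes <- sizes
  class(params) <- "stec_params"
  params
}

#' @export
print.stec_params <- function(x, ...) {
  cat(sprintf("<stec_params> input=%d, hidden=%s (%d weight groups)\n",
              x$sizes[1], paste(x$sizes[-1], collapse = "/"),
              2 * (length(x$sizes) - 1) + length(x$W_td) + 1))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "stec_params")) stop_invalid("not an stec_params object")
  ok <- all(vapply(c(params$W_bu, params$W_rec, params$W_td,
                     list(params$W_gen), params$b, list(params$b_gen)),
                   function(m) all(is.finite(m)), logical(1)))
  if (!ok) stop("non-finite network weights", call. = FALSE)
  invisible(params)
}

as_frame_matrix <- function(frame, input_size) {
  x <- if (is.matrix(frame) && nrow(frame) * ncol(frame) == input_size)
    matrix(as.vector(frame), 1L, input_size)
  else if (is.matrix(frame) && ncol(frame) == input_size) frame
  else if (length(frame) == input_size) matrix(frame, 1L, input_size)
  else stop_invalid("frame has %d values, expected %d", length(frame), input_size)
  x
}

#' Initialize the network state for a stimulus frame
#'
#' The input level is clamped to the flattened frame; every hidden level
#' and the generated input start at 0.5, the sigmoid of zero drive (the
#' unbiased fixed point of the activation).
#'
#' @param params an `stec_params` object.
#' @param frame a 64 x 64 frame (or batch matrix, rows = batch).
#' @return A list with `input` (batch x 4096), `hidden` (list of batch x
#'   n matrices) and `gen`.
#' @export
init_state <- function(params, frame) {
  check_params(params)
  x0 <- as_frame_matrix(frame, params$sizes[1])
  B <- nrow(x0)
  hidden <- lapply(params$sizes[-1], function(n) matrix(0.5, B, n))
  list(input = x0, hidden = hidden, gen = matrix(0.5, B, params$sizes[1]))
}

#' One synchronous network update
#'
#' Applies the hierarchy update rule once: every hidden level's new
#' response is the sigmoid of (top-down + recurrent + bottom-up drive plus
#' bias), all evaluated on the *previous* state, so levels update
#' simultaneously. The generated input is the sigmoid of the top-down
#' projection of the previous lowest-hidden response. The input level is
#' then clamped to `next_frame`.
#'
#' @param params an `stec_params` object.
#' @param state a state list from [init_state()] or a previous step.
#' @param next_frame the stimulus frame for the new time step.
#' @return The new state list.
#' @export
network_step <- function(params, state, next_frame) {
  check_params(params)
  step_core(params, state, next_frame)
}

step_core <- function(params, state, next_frame) {
  H <- length(state$hidden)
  new_hidden <- vector("list", H)
  for (h in seq_len(H)) {
    below <- if (h == 1) state$input else state$hidden[[h - 1]]
    a <- below %*% params$W_bu[[h]] +
         state$hidden[[h]] %*% params$W_rec[[h]]
    if (h < H) a <- a + state$hidden[[h + 1]] %*% params$W_td[[h]]
    new_hidden[[h]] <- sigmoid(sweep(a, 2, params$b[[h]], "+"))
  }
  gen <- sigmoid(sweep(state$hidden[[1]] %*% params$W_gen, 2, params$b_gen, "+"))
  list(input = as_frame_matrix(next_frame, params$sizes[1]),
       hidden = new_hidden, gen = gen)
}

#' Run the network over a stimulus sequence
#'
#' Initializes on the first frame, then applies [network_step()] once per
#' subsequent frame, recording every level's response at every step.
#'
#' @param params an `stec_params` object.
#' @param sequence an `stec_sequence`, or a plain list of frames.
#' @return An object of class `stec_trajectory`: per hidden level a
#'   `T x n` response matrix (`$hidden`), plus `T x 4096` matrices of
#'   generated (`$gen`) and presented (`$input`) input. Row `t` is the
#'   state after frame `t`.
#' @export
run_network <- function(params, sequence) {
  frames <- if (inherits(sequence, "stec_sequence")) sequence$frames else sequence
  if (length(frames) < 1) stop_invalid("sequence must contain at least one frame")
  states <- run_network_batch(params, lapply(frames, as_frame_matrix,
                                             input_size = params$sizes[1]))
  traj <- list(
    hidden = lapply(seq_along(states$hidden), function(h)
      do.call(rbind, lapply(states$hidden[[h]], function(m) m[1, ]))),
    gen = do.call(rbind, lapply(states$gen, function(m) m[1, ])),
    input = do.call(rbind, lapply(states$input, function(m) m[1, ]))
  )
  names(traj$hidden) <- hierarchy_names(length(traj$hidden))
  structure(traj, class = "stec_trajectory")
}

hierarchy_names <- function(H) {
  if (H == 2) c("lower", "upper")
  else paste0("h", seq_len(H))
}

#' @export
print.stec_trajectory <- function(x, ...) {
  cat(sprintf("<stec_trajectory> %d steps; hidden levels: %s\n",
              nrow(x$gen), paste(names(x$hidden), collapse = ", ")))
  invisible(x)
}

# Batched forward pass. `frames` is a list over time of B x input matrices.
# Returns per-step state lists: hidden[[h]][[t]], gen[[t]], input[[t]].
# Dispatches to the compiled core; run_network_batch_r is the pure-R
# reference the tests cross-check against.
run_network_batch <- function(params, frames) {
  check_params(params)
  out <- cpp_forward_batch(params$W_bu, params$W_rec, params$W_td,
                           params$W_gen, params$b, params$b_gen, frames)
  list(hidden = out$hidden, gen = out$gen, input = frames)
}

run_network_batch_r <- function(params, frames) {
  T_len <- length(frames)
  H <- length(params$sizes) - 1L
  check_params(params)
  state <- init_state(params, frames[[1]])
  hidden <- lapply(seq_len(H), function(h) {
    out <- vector("list", T_len); out[[1]] <- state$hidden[[h]]; out
  })
  gen <- vector("list", T_len); gen[[1]] <- state$gen
  for (t in seq_len(T_len)[-1]) {
    state <- step_core(params, state, frames[[t]])
    for (h in seq_len(H)) hidden[[h]][[t]] <- state$hidden[[h]]
    gen[[t]] <- state$gen
  }
  list(hidden = hidden, gen = gen, input = frames)
}
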