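SCENE_ROWS <- 128L
SCENE_COLS <- 192L
PATCH_SIZE <- 64L
N_POSITIONS <- 41L
BAR_WIDTH <- 4

#' Bar stimulus orientations
#'
#' The eight orientations used throughout: `k * pi/8` for `k = 0..7`,
#' with 0 the horizontal bar.
#'
#' @return Numeric vector of eight angles in radians.
#' @export
bar_orientations <- function() (0:7) * pi / 8

new_sequence <- function(frames, kind, metadata = list()) {
  structure(list(frames = frames, kind = kind, metadata = metadata),
            class = "stec_sequence")
}

#' @export
print.stec_sequence <- function(x, ...) {
  cat(sprintf("<stec_sequence> kind=%s, %d frames of %dx%d\n",
              x$kind, length(x$frames),
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' @export
length.stec_sequence <- function(x) length(x$frames)

#' Generate a surrogate natural scene
#'
#' Produces a 128 x 192 grayscale image with 1/f-amplitude spatial
#' statistics: white Gaussian noise is shaped in the Fourier domain by an
#' amplitude envelope proportional to the inverse spatial frequency, then
#' linearly rescaled to span exactly \[0, 1\]. This reproduces the smooth,
#' scale-free spatial correlation structure of natural scenes, which is
#' the only property of the training images the coding model relies on.
#'
#' @param seed integer; the image is a deterministic function of it.
#' @param rows,cols image size in pixels.
#' @return Numeric matrix `rows x cols` with `min = 0`, `max = 1`.
#' @export
#' @examples
#' sc <- surrogate_scene(1)
#' dim(sc)    # 128 192
#' range(sc)  # 0 1
surrogate_scene <- function(seed, rows = SCENE_ROWS, cols = SCENE_COLS) {
  white <- with_seed(substream_seed(seed, "scene"),
                     matrix(stats::rnorm(rows * cols), rows, cols))
  # radial spatial frequency per FFT cell (cycles/pixel, wrapped)
  fr <- c(0:(rows %/% 2), -((rows - rows %/% 2 - 1):1)) / rows
  fc <- c(0:(cols %/% 2), -((cols - cols %/% 2 - 1):1)) / cols
  f <- sqrt(outer(fr^2, fc^2, "+"))
  f[1, 1] <- Inf  # zero out the DC term; the rescale fixes the mean anyway
  shaped <- Re(stats::fft(stats::fft(white) / f, inverse = TRUE))
  rescale01(shaped)
}

#' Sample a gaze-driven patch sequence from a scene
#'
#' Emulates a gaze moving at constant velocity across a scene: the start
#' position is uniform over valid 64 x 64 window corners, the speed
#' magnitude is uniform over integers `0..max_speed` (L-infinity norm),
#' and the direction is uniform on the circle, rounded to the pixel grid.
#' If the drawn velocity would push any window out of the scene, its
#' magnitude is reduced to the largest one that keeps every window
#' in-bounds (direction preserved).
#'
#' @param scene matrix from [surrogate_scene()] (or any image at least
#'   64 x 64).
#' @param n_steps number of patches (time steps); 9 during training.
#' @param max_speed maximum L-infinity speed in pixels/step.
#' @param seed integer substream seed.
#' @param start,velocity optional fixed start corner (0-based row/col)
#'   and requested velocity (overriding the random draws; the velocity
#'   is still magnitude-adjusted to stay in-bounds). Intended for
#'   controlled experiments.
#' @return A `stec_sequence` of kind `"gaze"`; metadata records the start
#'   corner (0-based) and the realized integer velocity.
#' @export
sample_gaze_sequence <- function(scene, n_steps = 9L, max_speed = 4L, seed = 1L,
                                 start = NULL, velocity = NULL) {
  if (!is.matrix(scene) || nrow(scene) < PATCH_SIZE || ncol(scene) < PATCH_SIZE)
    stop_invalid("scene must be a matrix of at least %d x %d", PATCH_SIZE, PATCH_SIZE)
  stopifnot(n_steps >= 1, max_speed >= 0)
  nr <- nrow(scene); nc <- ncol(scene)
  draw <- with_seed(substream_seed(seed, "gaze"), {
    s <- start %||% c(sample.int(nr - PATCH_SIZE + 1L, 1L) - 1L,
                      sample.int(nc - PATCH_SIZE + 1L, 1L) - 1L)
    if (is.null(velocity)) {
      mag <- sample.int(max_speed + 1L, 1L) - 1L
      ang <- stats::runif(1, 0, 2 * pi)
    } else {
      mag <- max(abs(velocity))
      ang <- atan2(velocity[2], velocity[1])
    }
    list(start = s, mag = mag, ang = ang)
  })
  dir <- c(cos(draw$ang), sin(draw$ang))
  in_bounds <- function(v) {
    ends <- vapply(0:(n_steps - 1L), function(t) draw$start + t * v, numeric(2))
    all(ends[1, ] >= 0, ends[1, ] <= nr - PATCH_SIZE,
        ends[2, ] >= 0, ends[2, ] <= nc - PATCH_SIZE)
  }
  velocity <- c(0L, 0L)
  for (m in seq(draw$mag, 0)) {   # largest magnitude that stays inside
    v <- round(m * dir)
    v <- pmax(pmin(v, m), -m)     # re-clip so the L-inf norm is exactly <= m
    if (in_bounds(v)) { velocity <- as.integer(v); break }
  }
  frames <- lapply(0:(n_steps - 1L), function(t) {
    tl <- draw$start + t * velocity
    scene[tl[1] + seq_len(PATCH_SIZE), tl[2] + seq_len(PATCH_SIZE)]
  })
  new_sequence(frames, "gaze",
               list(start = draw$start, velocity = velocity, seed = seed))
}

#' Rasterize one bar stimulus frame
#'
#' A bar is a 64 x 64 binary image: 1 on the bar, 0 elsewhere. The bar is
#' an edge-to-edge band of constant 4-pixel perpendicular width at one of
#' the eight orientations `k*pi/8`. The 41 positions per orientation are
#' anchors evenly spaced along the bar normal, chosen so the first and
#' last bars touch opposite image borders and the 41-bar family covers
#' every pixel. Membership uses the signed perpendicular distance `s` of
#' the pixel center to the bar axis, with the half-open band
#' `-2 <= s < 2`, which yields a crisp, constant-width, non-anti-aliased
#' bar (exactly four full rows for the horizontal orientation).
#'
#' @param orientation one of [bar_orientations()] (radians).
#' @param position integer position index in `0..40`.
#' @param size frame edge length in pixels.
#' @return Binary `size x size` matrix with attributes `orientation` and
#'   `position`.
#' @export
#' @examples
#' sum(rasterize_bar(0, 20))  # 4 rows * 64 = 256
rasterize_bar <- function(orientation, position, size = PATCH_SIZE) {
  k <- orientation / (pi / 8)
  if (length(orientation) != 1 || abs(k - round(k)) > 1e-9 ||
      round(k) < 0 || round(k) > 7)
    stop_invalid("orientation must be one of k*pi/8, k = 0..7")
  if (length(position) != 1 || position != round(position) ||
      position < 0 || position > N_POSITIONS - 1)
    stop_invalid("position must be an integer in 0..%d", N_POSITIONS - 1)
  n <- c(-sin(orientation), cos(orientation))       # unit normal (x=col, y=row)
  half_span <- (size / 2 - 0.5) * (abs(n[1]) + abs(n[2]))
  offsets <- seq(-(half_span - 1.5), half_span - 1.5, length.out = N_POSITIONS)
  ctr <- size / 2
  xc <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)  # col centers
  yc <- matrix(rep(seq_len(size) - 0.5, times = size), size, size) # row centers
  s <- (xc - ctr) * n[1] + (yc - ctr) * n[2] - offsets[position + 1]
  half <- BAR_WIDTH / 2
  frame <- (s >= -half & s < half) * 1
  structure(frame, orientation = orientation, position = as.integer(position))
}

#' All 16 smoothly moving bar sequences
#'
#' For each of the eight orientations, one forward sequence sweeping
#' positions 0 to 40 and one backward sequence sweeping 40 to 0, each of
#' 41 frames (one position per time step).
#'
#' @param orientations angles to include; defaults to all eight.
#' @return List of `stec_sequence` objects of kinds `smooth_bar_forward`
#'   and `smooth_bar_backward`.
#' @export
make_smooth_bar_sequences <- function(orientations = bar_orientations()) {
  out <- list()
  for (th in orientations) {
    fwd <- lapply(0:(N_POSITIONS - 1L), function(p) rasterize_bar(th, p))
    out[[length(out) + 1L]] <-
      new_sequence(fwd, "smooth_bar_forward",
                   list(orientation = th, positions = 0:(N_POSITIONS - 1L)))
    out[[length(out) + 1L]] <-
      new_sequence(rev(fwd), "smooth_bar_backward",
                   list(orientation = th, positions = (N_POSITIONS - 1L):0))
  }
  out
}

#' A randomly moving bar sequence
#'
#' The bar visits every one of the 41 positions exactly once, in a
#' uniformly random order (41 frames).
#'
#' @param orientation bar angle (radians).
#' @param seed integer substream seed.
#' @return A `stec_sequence` of kind `"random_bar"`; metadata records the
#'   position permutation (0-based).
#' @export
make_random_bar_sequence <- function(orientation, seed = 1L) {
  perm <- with_seed(substream_seed(seed, "permutation"),
                    sample.int(N_POSITIONS)) - 1L
  frames <- lapply(perm, function(p) rasterize_bar(orientation, p))
  new_sequence(frames, "random_bar",
               list(orientation = orientation, positions = perm, seed = seed))
}

#' A static bar sequence
#'
#' Continuous presentation of a single frame with no change in time.
#'
#' @param frame a single 64 x 64 frame, e.g. from [rasterize_bar()].
#' @param n_steps number of presentation steps (>= 1).
#' @return A `stec_sequence` of kind `"static_bar"`.
#' @export
make_static_sequence <- function(frame, n_steps = N_POSITIONS) {
  if (n_steps < 1) stop_invalid("n_steps must be >= 1")
  new_sequence(rep(list(frame), n_steps), "static_bar",
               list(orientation = attr(frame, "orientation"),
                    position = attr(frame, "position")))
}

#' Add i.i.d. Gaussian pixel noise to a frame
#'
#' The decoder-training augmentation: `S_eps = S + eps` with
#' `eps ~ N(0, sigma^2)` per pixel. Values are deliberately not re-clipped
#' to \[0, 1\]; clipping would shrink the realized noise scale below
#' `sigma`.
#'
#' @param frame numeric matrix (any size).
#' @param sigma noise standard deviation (>= 0); the study grid is
#'   0.025, 0.05, 0.1, 0.2, 0.4.
#' @param seed integer substream seed.
#' @return Matrix of the same shape.
#' @export
add_noise <- function(frame, sigma, seed = 1L) {
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  if (sigma == 0) return(frame)
  frame + with_seed(substream_seed(seed, "noise"),
                    matrix(stats::rnorm(length(frame), 0, sigma),
                           nrow(frame), ncol(frame)))
}

#' Noise-augmented copies of a stimulus frame
#'
#' Builds the per-stimulus augmentation set used for decoding: `n`
#' independently noised copies of `frame` from one named substream, so
#' train and test sets built from different `set` labels never share
#' noise draws.
#'
#' @param frame numeric matrix.
#' @param sigma noise standard deviation.
#' @param n number of samples (300 in the study design).
#' @param set substream label, conventionally `"train"` or `"test"`.
#' @param seed integer master seed.
#' @return List of `n` matrices.
#' @export
augment_frame <- function(frame, sigma, n = 300L, set = "train", seed = 1L) {
  base <- substream_seed(seed, paste0("noise-", set))
  lapply(seq_len(n), function(i) add_noise(frame, sigma, seed = base + i))
}
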