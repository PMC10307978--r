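#' Collect position-indexed responses to bar stimuli
#'
#' Builds the 41 x units response matrix per hidden level that the
#' robustness analyses operate on. For moving sequences the hidden
#' response to each position is read out at its *encoding step* — the
#' first state driven by the frame showing that position, one step after
#' it appears (states one step earlier are still driven by the previous
#' frame; the run is extended by one step so the final frame gets its
#' encoding state too). For static bars each position is presented as
#' its own static sequence and the final-step response is taken,
#' matching the moving presentation length.
#'
#' @param params trained `stec_params`.
#' @param orientation bar angle (radians).
#' @param movement one of `"smooth_fwd"`, `"smooth_bwd"`, `"random"`,
#'   `"static"`.
#' @param static_steps presentation length for static bars.
#' @param seed substream seed (used by the random movement only).
#' @return An object of class `stec_position_responses`: `$responses` is
#'   a named list of 41 x units matrices, one per hidden level.
#' @export
collect_position_responses <- function(params, orientation,
                                       movement = c("smooth_fwd", "smooth_bwd",
                                                    "random", "static"),
                                       static_steps = 41L, seed = 1L) {
  movement <- match.arg(movement)
  check_params(params)
  H <- length(params$sizes) - 1L
  n_pos <- N_POSITIONS
  if (movement == "static") {
    frames1 <- do.call(rbind, lapply(0:(n_pos - 1L), function(p)
      as.vector(rasterize_bar(orientation, p))))
    states <- run_network_batch(params, rep(list(frames1), static_steps))
    resp <- lapply(seq_len(H), function(h) states$hidden[[h]][[static_steps]])
  } else {
    seqc <- switch(movement,
      smooth_fwd = new_sequence(
        lapply(0:(n_pos - 1L), function(p) rasterize_bar(orientation, p)),
        "smooth_bar_forward", list(positions = 0:(n_pos - 1L))),
      smooth_bwd = new_sequence(
        lapply((n_pos - 1L):0, function(p) rasterize_bar(orientation, p)),
        "smooth_bar_backward", list(positions = (n_pos - 1L):0)),
      random = make_random_bar_sequence(orientation, seed))
    # encoding-step readout: the response to a frame is the first state it
    # drives, one step after it appears; extending the run by one step
    # gives the final frame its encoding state too
    frames_ext <- c(seqc$frames, seqc$frames[length(seqc$frames)])
    traj <- run_network(params, frames_ext)
    step_of <- order(seqc$metadata$positions)   # frame index showing p
    resp <- lapply(seq_len(H), function(h)
      traj$hidden[[h]][step_of + 1L, , drop = FALSE])
  }
  names(resp) <- hierarchy_names(H)
  resp <- lapply(resp, function(m) {
    rownames(m) <- paste0("pos", 0:(n_pos - 1L)); m
  })
  structure(list(orientation = orientation, movement = movement,
                 responses = resp),
            class = "stec_position_responses")
}

#' @export
print.stec_position_responses <- function(x, ...) {
  cat(sprintf("<stec_position_responses> movement=%s orientation=%.3f, %s\n",
              x$movement, x$orientation,
              paste(sprintf("%s:%dx%d", names(x$responses),
                            sapply(x$responses, nrow),
                            sapply(x$responses, ncol)), collapse = " ")))
  invisible(x)
}

resp_matrix <- function(x, hierarchy = NULL) {
  if (inherits(x, "stec_position_responses")) {
    if (is.null(hierarchy)) stop_invalid("hierarchy must be named")
    x$responses[[hierarchy]]
  } else as.matrix(x)
}

#' Pairwise correlation of responses across positions
#'
#' Entry (i, j) is the Pearson correlation, computed across units,
#' between the population response vectors at positions i and j. High
#' correlation between adjacent positions quantifies the smoothness of
#' the representation as the bar moves.
#'
#' @param x a positions-by-units matrix, or an
#'   `stec_position_responses` with `hierarchy` naming the level.
#' @param hierarchy level name when `x` is a response set.
#' @return Symmetric 41 x 41 correlation matrix; rows with zero variance
#'   across units give `NA` entries.
#' @export
adjacent_position_correlation <- function(x, hierarchy = NULL) {
  M <- resp_matrix(x, hierarchy)
  sds <- apply(M, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(M)))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  diag(C)[sds > 0] <- 1
  C
}

#' Mean correlation between adjacent positions
#'
#' Convenience summary of [adjacent_position_correlation()]: the mean of
#' the first off-diagonal (position pairs at offset 1).
#'
#' @inheritParams adjacent_position_correlation
#' @param is_correlation set `TRUE` if `x` already is a correlation
#'   matrix from [adjacent_position_correlation()].
#' @return Scalar in \[-1, 1\].
#' @export
mean_adjacent_correlation <- function(x, hierarchy = NULL,
                                      is_correlation = FALSE) {
  C <- if (is_correlation) x else adjacent_position_correlation(x, hierarchy)
  n <- nrow(C)
  mean(C[cbind(1:(n - 1), 2:n)], na.rm = TRUE)
}

#' Correlations between unit response trajectories
#'
#' For every unordered pair of units, the Pearson correlation between
#' their response time courses to a moving bar, with the two-sided
#' p-value from the t transform `t = r * sqrt((n-2)/(1-r^2))`. Correlated
#' unit activity is the signature of redundancy, hence of robustness to
#' single-unit noise.
#'
#' @param x a `stec_trajectory`, or a steps-by-units response matrix.
#' @param hierarchy level name when `x` is a trajectory.
#' @param alpha significance threshold (two-sided, uncorrected).
#' @return A list: `frac_sig_pos` (fraction of pairs positively
#'   correlated at `p < alpha`), `abs_r` (absolute correlations of all
#'   retained pairs), `r`, `p` (pairwise matrices), `n_pairs`,
#'   `n_excluded` (pairs dropped because a unit's trajectory was
#'   constant).
#' @export
unit_trajectory_correlations <- function(x, hierarchy = NULL, alpha = 0.05) {
  M <- if (inherits(x, "stec_trajectory")) x$hidden[[hierarchy]] else as.matrix(x)
  Tn <- nrow(M)
  if (Tn < 3) stop_invalid("need at least 3 time steps")
  sds <- apply(M, 2, stats::sd)
  r <- suppressWarnings(stats::cor(M))
  tt <- r * sqrt((Tn - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = Tn - 2)
  ut <- upper.tri(r)
  bad <- outer(sds == 0, sds == 0, "|")
  keep <- ut & !bad
  list(frac_sig_pos = mean(r[keep] > 0 & p[keep] < alpha),
       abs_r = abs(r[keep]),
       r = r, p = p,
       n_pairs = sum(keep), n_excluded = sum(ut & bad))
}

#' Wilcoxon rank-sum comparison between two conditions
#'
#' Two-sided rank-sum (Mann-Whitney) test on per-orientation or per-pair
#' statistics of two coding conditions.
#'
#' @param stat_a,stat_b numeric samples.
#' @param exact passed to [stats::wilcox.test()].
#' @return A list with the Mann-Whitney `statistic` and two-sided
#'   `p.value`.
#' @export
compare_conditions_ranksum <- function(stat_a, stat_b, exact = NULL) {
  if (length(stat_a) == 0 || length(stat_b) == 0)
    stop_invalid("both samples must be non-empty")
  res <- suppressWarnings(
    stats::wilcox.test(stat_a, stat_b, alternative = "two.sided", exact = exact))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Euclidean distances between static and moving responses
#'
#' Entry (i, j) is the Euclidean distance between the population response
#' to the static bar at position i and the response to the moving bar at
#' position j. Small diagonal entries mean the moving-bar representation
#' matches the static one at the same position — robustness to the stale
#' inter-level signals that motion induces; distances growing smoothly
#' with |i - j| mean the representation preserves local stimulus
#' structure.
#'
#' @param static,moving positions-by-units matrices (or
#'   `stec_position_responses` with `hierarchy`).
#' @param hierarchy level name when response sets are passed.
#' @return 41 x 41 nonnegative distance matrix (static rows, moving
#'   columns).
#' @export
static_vs_moving_distance <- function(static, moving, hierarchy = NULL) {
  A <- resp_matrix(static, hierarchy)
  B <- resp_matrix(moving, hierarchy)
  if (ncol(A) != ncol(B)) stop_invalid("unit dimensions differ")
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D <- sqrt(pmax(sq, 0))
  dimnames(D) <- list(rownames(A), rownames(B))
  D
}

#' Local distance-vs-offset trend
#'
#' Spearman correlation between position offset |i - j| (within
#' `offsets`) and the mean static-vs-moving distance at that offset. A
#' positive trend indicates that response distance grows with stimulus
#' separation, i.e. the map preserves local external structure.
#'
#' @param D distance matrix from [static_vs_moving_distance()].
#' @param offsets integer offsets to include (0 = diagonal).
#' @return List with `rho` and the per-offset mean distances.
#' @export
distance_offset_trend <- function(D, offsets = 0:5) {
  n <- nrow(D)
  off <- abs(outer(seq_len(n), seq_len(n), "-"))
  means <- vapply(offsets, function(k) mean(D[off == k]), numeric(1))
  rho <- suppressWarnings(
    stats::cor(offsets, means, method = "spearman"))
  list(rho = rho, offsets = offsets, mean_distance = means)
}
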