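test_that("position response sets have one row per position", {
  p <- init_params(seed = 4, hidden = c(6L, 6L))
  for (mv in c("smooth_fwd", "smooth_bwd", "random", "static")) {
    rs <- collect_position_responses(p, 0, mv, static_steps = 5, seed = 2)
    expect_equal(dim(rs$responses$lower), c(41L, 6L))
    expect_equal(dim(rs$responses$upper), c(41L, 6L))
  }
})

test_that("moving responses use the encoding step of each position", {
  p <- init_params(seed = 4, hidden = c(6L, 6L))
  sq <- make_smooth_bar_sequences(0)[[1]]
  traj <- run_network(p, c(sq$frames, sq$frames[41]))
  fwd <- collect_position_responses(p, 0, "smooth_fwd")
  # forward: frame p (0-based) first drives the state at row p + 2
  expect_equal(fwd$responses$lower[21, ], traj$hidden$lower[22, ])
  expect_equal(fwd$responses$lower[1, ], traj$hidden$lower[2, ])
  expect_equal(fwd$responses$lower[41, ], traj$hidden$lower[42, ])
  sqb <- make_smooth_bar_sequences(0)[[2]]
  trajb <- run_network(p, c(sqb$frames, sqb$frames[41]))
  bwd <- collect_position_responses(p, 0, "smooth_bwd")
  # backward: position p is frame 41 - p, encoding state at row 42 - p
  expect_equal(bwd$responses$upper[21, ], trajb$hidden$upper[22, ])
  expect_equal(bwd$responses$upper[41, ], trajb$hidden$upper[2, ])
})

test_that("a zero-weight network responds with sigmoid(bias) everywhere", {
  p <- init_params(seed = 1, hidden = c(4L, 4L))
  for (nm in c("W_bu", "W_rec", "W_td")) p[[nm]] <- lapply(p[[nm]], `*`, 0)
  p$b[[1]][] <- 0.25; p$b[[2]][] <- -0.5
  st <- collect_position_responses(p, 0, "static", static_steps = 4)
  expect_true(all(abs(st$responses$lower - 1 / (1 + exp(-0.25))) < 1e-12))
  expect_true(all(abs(st$responses$upper - 1 / (1 + exp(0.5))) < 1e-12))
})

test_that("position correlation matrices match the textbook formula", {
  M <- rbind(c(0.2, 0.4, 0.9), c(0.1, 0.5, 0.7), c(0.9, 0.2, 0.3))
  C <- adjacent_position_correlation(M)
  expect_equal(diag(C), rep(1, 3))
  expect_equal(C, t(C))
  pearson <- function(a, b)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_equal(C[i, j], pearson(M[i, ], M[j, ]), tolerance = 1e-12)
  expect_equal(mean_adjacent_correlation(C, is_correlation = TRUE),
               mean(c(C[1, 2], C[2, 3])))
})

test_that("zero-variance position rows are flagged, not fabricated", {
  M <- rbind(c(0.5, 0.5, 0.5), c(0.1, 0.5, 0.7), c(0.9, 0.2, 0.3))
  C <- adjacent_position_correlation(M)
  expect_true(all(is.na(C[1, ])))
  expect_false(anyNA(C[2:3, 2:3]))
})

test_that("unit-pair trajectory statistics match cor.test", {
  set.seed(11)
  M <- matrix(runif(5 * 4), 5, 4)
  out <- unit_trajectory_correlations(M)
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(M[, i], M[, j])
    expect_equal(out$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(out$p[i, j], ct$p.value, tolerance = 1e-10)
  }
  expect_equal(out$n_pairs, 6L)
})

test_that("identical, anti-correlated and constant units are handled", {
  base <- c(0.1, 0.3, 0.2, 0.8, 0.6)
  M <- cbind(base, base, 1 - base, rep(0.4, 5))
  out <- unit_trajectory_correlations(M)
  expect_equal(out$r[1, 2], 1)
  expect_equal(out$r[1, 3], -1)
  # pairs involving the constant unit are excluded and counted
  expect_equal(out$n_excluded, 3L)
  expect_equal(out$n_pairs, 3L)
  # of the three retained pairs, one is perfectly positive, two negative
  expect_equal(out$frac_sig_pos, 1 / 3)
  expect_error(unit_trajectory_correlations(M[1:2, ]), "3 time steps")
})

test_that("rank-sum comparison matches exact enumeration on separated samples", {
  a <- 1:8; b <- 101:108
  res <- compare_conditions_ranksum(a, b, exact = TRUE)
  # complete separation: minimal Mann-Whitney statistic, exact two-sided
  # p = 2 / choose(16, 8)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 2 / choose(16, 8), tolerance = 1e-12)
  swapped <- compare_conditions_ranksum(b, a, exact = TRUE)
  expect_equal(swapped$statistic, 64)          # 8*8 - 0
  expect_equal(swapped$p.value, res$p.value)
  same <- compare_conditions_ranksum(1:20, 1:20)
  expect_gt(same$p.value, 0.9)
  expect_error(compare_conditions_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("static-vs-moving distances match a brute-force double loop", {
  expect_equal(static_vs_moving_distance(matrix(c(0, 0), 1),
                                         matrix(c(3, 4), 1))[1, 1], 5)
  set.seed(21)
  A <- matrix(runif(41 * 8), 41, 8)
  B <- matrix(runif(41 * 8), 41, 8)
  D <- static_vs_moving_distance(A, B)
  for (i in sample(41, 6)) for (j in sample(41, 6))
    expect_equal(D[i, j], sqrt(sum((A[i, ] - B[j, ])^2)), tolerance = 1e-10)
  expect_true(all(D >= 0))
  self <- static_vs_moving_distance(A, A)
  expect_equal(diag(self), rep(0, 41), tolerance = 1e-7)
  expect_error(static_vs_moving_distance(A, B[, 1:3]), "dimensions")
})

test_that("distance-offset trend recovers a monotone gradient", {
  pos <- matrix(seq(0, 1, length.out = 41), 41, 1)
  D <- static_vs_moving_distance(pos, pos)
  tr <- distance_offset_trend(D, 0:5)
  expect_equal(tr$rho, 1)
  expect_equal(tr$mean_distance[1], 0)
})
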