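test_that("state initialization clamps the input and centers hidden units", {
  p <- toy_params(input = 9L, hidden = c(3L, 2L))
  f <- matrix(runif(9), 3, 3)
  st <- init_state(p, f)
  expect_equal(st$input, matrix(as.vector(f), 1, 9))
  expect_true(all(st$hidden[[1]] == 0.5))
  expect_true(all(st$hidden[[2]] == 0.5))
  expect_true(all(st$gen == 0.5))
  st0 <- init_state(p, matrix(0, 3, 3))
  expect_true(all(st0$input == 0))
  expect_error(init_state(p, matrix(0, 2, 2)), "expected")
})

test_that("a zero-weight network maps everything to 0.5", {
  p <- toy_params(input = 4L)
  for (nm in c("W_bu", "W_rec", "W_td", "b")) {
    p[[nm]] <- lapply(p[[nm]], function(m) m * 0)
  }
  p$W_gen <- p$W_gen * 0; p$b_gen <- p$b_gen * 0
  st <- network_step(p, init_state(p, matrix(1, 2, 2)), matrix(0, 2, 2))
  expect_equal(as.vector(st$hidden[[1]]), c(0.5, 0.5))
  expect_equal(as.vector(st$hidden[[2]]), c(0.5, 0.5))
})

test_that("a scalar top-down drive reproduces sigmoid(1) by hand", {
  p <- init_params(input_size = 1L, hidden = c(1L, 1L), seed = 1)
  p$W_bu <- lapply(p$W_bu, function(m) m * 0)
  p$W_rec <- lapply(p$W_rec, function(m) m * 0)
  p$W_td[[1]][] <- 1
  p$b <- lapply(p$b, function(x) x * 0)
  st <- init_state(p, matrix(0.3, 1, 1))
  st$hidden[[2]][] <- 1
  out <- network_step(p, st, matrix(0.3, 1, 1))
  expect_equal(out$hidden[[1]][1, 1], 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("hidden responses stay strictly inside (0, 1)", {
  p <- toy_params(input = 4L)
  p$W_td[[1]][] <- 50   # extreme drive
  st <- network_step(p, init_state(p, matrix(1, 2, 2)), matrix(1, 2, 2))
  for (h in 1:2) {
    expect_true(all(st$hidden[[h]] > 0 & st$hidden[[h]] < 1))
  }
})

test_that("run_network matches a fully hand-unrolled computation", {
  set.seed(1)
  p <- toy_params(input = 4L, hidden = c(2L, 2L), seed = 7)
  frames <- lapply(1:3, function(i) matrix(runif(4), 2, 2))
  traj <- run_network(p, frames)
  expect_equal(nrow(traj$hidden$lower), 3L)
  sig <- function(x) 1 / (1 + exp(-x))
  xl <- c(0.5, 0.5); xu <- c(0.5, 0.5)
  for (t in 2:3) {
    x_prev <- as.vector(frames[[t - 1]])
    nl <- sig(t(p$W_bu[[1]]) %*% x_prev + t(p$W_rec[[1]]) %*% xl +
                t(p$W_td[[1]]) %*% xu + p$b[[1]])
    nu <- sig(t(p$W_bu[[2]]) %*% xl + t(p$W_rec[[2]]) %*% xu + p$b[[2]])
    g <- sig(t(p$W_gen) %*% xl + p$b_gen)
    expect_equal(traj$hidden$lower[t, ], as.vector(nl), tolerance = 1e-12)
    expect_equal(traj$hidden$upper[t, ], as.vector(nu), tolerance = 1e-12)
    expect_equal(traj$gen[t, ], as.vector(g), tolerance = 1e-12)
    xl <- as.vector(nl); xu <- as.vector(nu)
  }
})

test_that("trajectories have one row per frame and are deterministic", {
  p <- init_params(seed = 3, hidden = c(8L, 8L))
  sq <- make_smooth_bar_sequences(0)[[1]]
  t1 <- run_network(p, sq)
  t2 <- run_network(p, sq)
  expect_equal(nrow(t1$hidden$lower), 41L)
  expect_equal(nrow(t1$gen), 41L)
  expect_identical(t1, t2)
  expect_error(run_network(p, list()), "at least one")
})

test_that("a static input with zero weights gives a constant trajectory", {
  p <- toy_params(input = 4L)
  for (nm in c("W_bu", "W_rec", "W_td")) p[[nm]] <- lapply(p[[nm]], `*`, 0)
  p$b[[1]][] <- 0.3; p$b[[2]][] <- -0.2
  sq <- make_static_sequence(matrix(0.7, 2, 2), 6)
  traj <- run_network(p, sq)
  for (t in 2:6) {
    expect_equal(traj$hidden$lower[t, ], traj$hidden$lower[2, ])
    expect_equal(traj$hidden$upper[t, ], rep(1 / (1 + exp(0.2)), 2))
  }
})

test_that("the update rule is equivariant under unit permutation", {
  set.seed(42)
  p <- toy_params(input = 4L, hidden = c(5L, 3L), seed = 9)
  perm <- sample(5)
  q <- p
  q$W_bu[[1]] <- p$W_bu[[1]][, perm]
  q$W_rec[[1]] <- p$W_rec[[1]][perm, perm]
  q$W_td[[1]] <- p$W_td[[1]][, perm]
  q$W_bu[[2]] <- p$W_bu[[2]][perm, ]
  q$W_gen <- p$W_gen[perm, ]
  q$b[[1]] <- p$b[[1]][perm]
  frames <- lapply(1:4, function(i) matrix(runif(4), 2, 2))
  t_p <- run_network(p, frames)
  t_q <- run_network(q, frames)
  expect_equal(t_q$hidden$lower, t_p$hidden$lower[, perm], tolerance = 1e-12)
  expect_equal(t_q$hidden$upper, t_p$hidden$upper, tolerance = 1e-12)
  expect_equal(t_q$gen, t_p$gen, tolerance = 1e-12)
})

test_that("static-input trajectories settle for small random weights", {
  for (s in 1:5) {
    p <- init_params(input_size = 16L, hidden = c(6L, 6L), seed = s)
    sq <- make_static_sequence(matrix(runif(16), 4, 4), 20)
    traj <- run_network(p, sq)
    step_inf <- vapply(3:20, function(t)
      max(abs(traj$hidden$lower[t, ] - traj$hidden$lower[t - 1, ]),
          abs(traj$hidden$upper[t, ] - traj$hidden$upper[t - 1, ])),
      numeric(1))
    # after the initial transient the per-step change must shrink overall
    expect_lt(step_inf[length(step_inf)], step_inf[1] + 1e-12)
    expect_lt(step_inf[length(step_inf)], 1e-3)
  }
})

test_that("non-finite weights are rejected", {
  p <- toy_params(input = 4L)
  p$W_rec[[1]][1, 1] <- NaN
  expect_error(network_step(p, init_state(toy_params(input = 4L),
                                          matrix(0, 2, 2)), matrix(0, 2, 2)),
               "non-finite")
})
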