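make_traj <- function(lower, upper, gen, input) {
  structure(list(hidden = list(lower = lower, upper = upper),
                 gen = gen, input = input),
            class = "stec_trajectory")
}

test_that("temporal loss is zero for constant, perfectly generated input", {
  Tn <- 5
  traj <- make_traj(matrix(0.4, Tn, 2), matrix(0.6, Tn, 2),
                    matrix(0.3, Tn, 4), matrix(0.3, Tn, 4))
  expect_equal(temporal_loss(traj), 0)
})

test_that("temporal loss matches explicit arithmetic on a 2-step toy", {
  lower <- rbind(c(0.5, 0.5), c(0.7, 0.5))
  traj <- make_traj(lower, matrix(0.6, 2, 2),
                    matrix(0.3, 2, 4), matrix(0.3, 2, 4))
  # only the lower level changes: ||(0.7,0.5)-(0.5,0.5)||^2 / (T-1)
  expect_equal(temporal_loss(traj), 0.2^2)
  expect_gte(temporal_loss(traj), 0)
  one <- make_traj(matrix(0.5, 1, 2), matrix(0.5, 1, 2),
                   matrix(0.5, 1, 4), matrix(0.5, 1, 4))
  expect_error(temporal_loss(one), "2 steps")
})

test_that("spatial loss vanishes iff the empirical density matches", {
  # equal mass at the four bin centers, uniform reference: exact zero
  R <- matrix(rep(c(0.125, 0.375, 0.625, 0.875), each = 10), ncol = 1)
  expect_equal(spatial_loss(R, rep(0.25, 4), 4, bandwidth = 0), 0)
  expect_gte(spatial_loss(R, compensation_density("sparse", 4), 4,
                          bandwidth = 0), 0)
  expect_error(spatial_loss(matrix(c(0.5, 1), 2, 1), rep(0.25, 4), 4),
               "strictly")
})

test_that("hard-binned spatial loss equals the closed-form discrete KL", {
  # all mass in one of four bins against a uniform reference: log 4
  R <- matrix(rep(0.4, 50), ncol = 1)
  expect_equal(spatial_loss(R, rep(0.25, 4), 4, bandwidth = 0), log(4))
  # a constructed two-unit histogram vs an independently computed KL
  R2 <- cbind(c(rep(0.1, 30), rep(0.9, 10)),
              c(rep(0.3, 20), rep(0.55, 20)))
  q <- compensation_density("sparse", 4)
  p1 <- c(30, 0, 0, 10) / 40
  p2 <- c(0, 20, 20, 0) / 40
  kl <- function(p) sum(ifelse(p > 0, p * log(p / q), 0))
  expect_equal(spatial_loss(R2, q, 4, bandwidth = 0),
               mean(c(kl(p1), kl(p2))), tolerance = 1e-12)
})

test_that("soft spatial loss gradient matches central finite differences", {
  set.seed(5)
  R <- matrix(runif(30, 0.05, 0.95), 15, 2)
  q <- compensation_density("sparse", 8)
  g <- stec:::spatial_loss_grad(R, q, 8, 1 / 8)
  h <- 1e-6
  for (j in sample(length(R), 10)) {
    R1 <- R; R2 <- R; R1[j] <- R[j] + h; R2[j] <- R[j] - h
    fd <- (spatial_loss(R1, q, 8) - spatial_loss(R2, q, 8)) / (2 * h)
    expect_lt(abs(fd - g[j]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("loss report is additive: total = temporal + lambda * spatial", {
  p <- init_params(input_size = 16L, hidden = c(4L, 3L), seed = 2)
  frames <- lapply(1:5, function(i) matrix(runif(16), 4, 4))
  traj <- run_network(p, frames)
  for (preset in c("stec", "sec", "tec")) {
    cfg <- objective_config(preset)
    rep <- total_loss(traj, frames, cfg)
    expect_equal(rep$total, rep$temporal + cfg$lambda * sum(rep$spatial),
                 tolerance = 1e-10)
  }
  cfg0 <- objective_config(lambda = 0)
  expect_equal(total_loss(traj, frames, cfg0)$total,
               temporal_loss(traj, frames))
})

test_that("full-sequence gradients match finite differences on a toy net", {
  set.seed(2)
  p <- init_params(input_size = 4L, hidden = c(3L, 2L), seed = 3)
  frames <- lapply(1:4, function(t) matrix(runif(2 * 4), 2, 4))
  obj <- objective_config("stec", n_bins = 4, n_levels = 2)
  loss_of <- function(params) {
    st <- stec:::run_network_batch(params, frames)
    stec:::minibatch_loss_grads(params, st, frames, obj, bptt = TRUE,
                                want_grads = FALSE)$total
  }
  st <- stec:::run_network_batch(p, frames)
  g <- stec:::minibatch_loss_grads(p, st, frames, obj, bptt = TRUE)$grads
  h <- 1e-6
  for (nm in stec:::PARAM_LEAVES) {
    leaves <- if (is.list(p[[nm]])) seq_along(p[[nm]]) else NA
    for (i in leaves) {
      W <- if (is.na(i)[1]) p[[nm]] else p[[nm]][[i]]
      G <- if (is.na(i)[1]) g[[nm]] else g[[nm]][[i]]
      for (j in sample(length(W), min(4, length(W)))) {
        p1 <- p; p2 <- p
        if (is.na(i)[1]) { p1[[nm]][j] <- W[j] + h; p2[[nm]][j] <- W[j] - h }
        else { p1[[nm]][[i]][j] <- W[j] + h; p2[[nm]][[i]][j] <- W[j] - h }
        fd <- (loss_of(p1) - loss_of(p2)) / (2 * h)
        expect_lt(abs(fd - G[j]) / max(abs(fd), abs(G[j]), 1e-6), 1e-4)
      }
    }
  }
})

test_that("one-step truncation equals full backpropagation when T = 2", {
  set.seed(3)
  p <- init_params(input_size = 4L, hidden = c(3L, 2L), seed = 5)
  frames <- lapply(1:2, function(t) matrix(runif(2 * 4), 2, 4))
  obj <- objective_config("stec", n_bins = 4, n_levels = 2)
  st <- stec:::run_network_batch(p, frames)
  g1 <- stec:::minibatch_loss_grads(p, st, frames, obj, bptt = FALSE)$grads
  g2 <- stec:::minibatch_loss_grads(p, st, frames, obj, bptt = TRUE)$grads
  for (nm in stec:::PARAM_LEAVES) {
    a <- g1[[nm]]; b <- g2[[nm]]
    if (is.list(a)) for (i in seq_along(a))
      expect_equal(a[[i]], b[[i]], tolerance = 1e-12)
    else expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("zero training iterations return the initialization unchanged", {
  trn <- training_config(iterations = 0L, repetitions = 1L, minibatch = 2L,
                         hidden = c(4L, 4L), n_scenes = 2L, seed = 8)
  fit <- train_network(objective_config("stec"), trn)
  expect_identical(fit$params$W_bu,
                   init_params(hidden = c(4L, 4L), seed = 8)$W_bu)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("a short training run reduces the total loss", {
  for (s in 1:3) {
    trn <- training_config(iterations = 120L, repetitions = 1L,
                           minibatch = 5L, hidden = c(8L, 8L),
                           n_scenes = 5L, seed = s)
    fit <- train_network(objective_config("stec"), trn, trace_every = 5L)
    expect_lt(fit$trace$total[nrow(fit$trace)], fit$trace$total[1])
  }
})

test_that("compensation densities are proper and shaped as intended", {
  u <- compensation_density("uniform", 16)
  s <- compensation_density("sparse", 16)
  expect_equal(sum(u), 1); expect_equal(sum(s), 1)
  expect_true(all(diff(s) < 0))       # decaying toward high responses
  expect_equal(u, rep(1 / 16, 16))
  expect_equal(s[1] / s[16], exp(4 * (15.5 - 0.5) / 16), tolerance = 1e-12)
})

test_that("objective presets carry the study lambda values", {
  expect_equal(objective_config("stec")$lambda, 5)
  expect_equal(objective_config("sec")$lambda, 1000)
  expect_equal(objective_config("tec")$lambda, 0.01)
  expect_error(objective_config(lambda = -1), "lambda")
})
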