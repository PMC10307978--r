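DECODERS <- c("naive_bayes", "lda", "linear_svm", "decision_tree",
              "ensemble", "nn5")

#' Available decoder families
#' @return Character vector of decoder names accepted by
#'   [decode_responses()].
#' @export
decoder_names <- function() DECODERS

# Small feed-forward classifier: input -> 4 hidden ReLU layers (64 units)
# -> softmax, trained full-batch with Adam, early-stopped when the
# training loss plateaus.
mlp_fit <- function(x, y, hidden = rep(64L, 4L), alpha = 0.001,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                    max_epochs = 500L, patience = 30L, tol = 1e-4,
                    seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2, stats::sd), 1e-8)
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  K <- nlevels(y); n <- nrow(x)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  sizes <- c(ncol(x), hidden, K)
  L <- length(sizes) - 1L
  W <- with_seed(substream_seed(seed, "mlp"), lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  m_w <- lapply(W, function(w) w * 0); v_w <- m_w
  m_b <- lapply(b, function(x) x * 0); v_b <- m_b
  best <- Inf; stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    acts <- vector("list", L + 1L); acts[[1]] <- x
    for (l in seq_len(L)) {
      z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
      acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    logits <- acts[[L + 1]]
    mx <- apply(logits, 1, max)
    P <- exp(logits - mx); P <- P / rowSums(P)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-12)))
    if (loss < best * (1 - tol)) { best <- loss; stall <- 0L }
    else { stall <- stall + 1L; if (stall >= patience) break }
    delta <- (P - Y) / n
    for (l in L:1) {
      gW <- crossprod(acts[[l]], delta); gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
      bc1 <- 1 - beta1^epoch; bc2 <- 1 - beta2^epoch
      m_w[[l]] <- beta1 * m_w[[l]] + (1 - beta1) * gW
      v_w[[l]] <- beta2 * v_w[[l]] + (1 - beta2) * gW^2
      W[[l]] <- W[[l]] - alpha * (m_w[[l]] / bc1) / (sqrt(v_w[[l]] / bc2) + eps)
      m_b[[l]] <- beta1 * m_b[[l]] + (1 - beta1) * gb
      v_b[[l]] <- beta2 * v_b[[l]] + (1 - beta2) * gb^2
      b[[l]] <- b[[l]] - alpha * (m_b[[l]] / bc1) / (sqrt(v_b[[l]] / bc2) + eps)
    }
  }
  list(W = W, b = b, levels = levels(y), center = ctr, scale = scl)
}

mlp_predict <- function(model, x) {
  a <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  L <- length(model$W)
  for (l in seq_len(L)) {
    a <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    if (l < L) a <- pmax(a, 0)
  }
  factor(model$levels[max.col(a, ties.method = "first")],
         levels = model$levels)
}

#' Fit one decoder on training responses and score it on test responses
#'
#' Train/test sets are lists with `x` (samples x units response matrix)
#' and `y` (class labels). The six families are Gaussian naive Bayes,
#' LDA, linear-kernel SVM, a decision tree, an ensemble of 100 bagged
#' trees, and a 5-layer feed-forward neural network.
#'
#' @param train,test lists with elements `x` and `y`.
#' @param decoder one of [decoder_names()].
#' @param seed seed for the stochastic decoders (ensemble, nn5).
#' @return A list (`stec_decoding_result`): `accuracy`, `decoder`,
#'   `n_train`, `n_test`, `n_classes`, `chance`.
#' @export
decode_responses <- function(train, test, decoder = DECODERS, seed = 1L) {
  decoder <- match.arg(decoder)
  ytr <- factor(train$y); yte <- factor(test$y, levels = levels(ytr))
  xtr <- as.matrix(train$x); xte <- as.matrix(test$x)
  pred <- if (nlevels(ytr) < 2) {
    rep(levels(ytr)[1], nrow(xte))      # degenerate single-class task
  } else switch(decoder,
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte)
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
      predict(fit, xte)$class
    },
    linear_svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear", scale = FALSE)
      predict(fit, xte)
    },
    decision_tree = {
      df <- data.frame(y = ytr, xtr)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      predict(fit, data.frame(xte), type = "class")
    },
    ensemble = with_seed(substream_seed(seed, "ensemble"), {
      # bagged trees: a forest with every predictor available at each split
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100,
                                        mtry = ncol(xtr))
      predict(fit, xte)
    }),
    nn5 = {
      fit <- mlp_fit(xtr, ytr, seed = seed)
      mlp_predict(fit, xte)
    })
  acc <- mean(as.character(pred) == as.character(yte))
  structure(list(accuracy = acc, decoder = decoder,
                 n_train = nrow(xtr), n_test = nrow(xte),
                 n_classes = nlevels(ytr), chance = 1 / nlevels(ytr)),
            class = "stec_decoding_result")
}

#' @export
print.stec_decoding_result <- function(x, ...) {
  cat(sprintf("%s: accuracy %.3f (chance %.3f, n_train=%d, n_test=%d)\n",
              x$decoder, x$accuracy, x$chance, x$n_train, x$n_test))
  invisible(x)
}
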