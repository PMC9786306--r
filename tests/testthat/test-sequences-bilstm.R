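# Sequence construction and the BiLSTM model.

test_that("window counts match the enumeration oracle", {
  set.seed(51)
  for (rep in 1:30) {
    T <- sample(1:60, 1); L <- sample(1:20, 1); st <- sample(1:7, 1)
    x <- matrix(rnorm(T * 3), T, 3)
    b <- make_sequences(x, L = L, stride = st, pad = "none")
    oracle <- length(seq_len(T)[seq_len(T) >= L][
      (seq_len(T)[seq_len(T) >= L] - L) %% st == 0])
    expect_identical(dim(b$x)[1], as.integer(max(0, (T - L) %/% st + 1)))
    expect_identical(dim(b$x)[1], as.integer(oracle))
    bp <- make_sequences(x, L = L, stride = 1, pad = "repeat")
    expect_identical(dim(bp$x)[1], T)  # one prediction per second
  }
})

test_that("padding repeats the first row and targets sit at window ends", {
  x <- matrix(1:20, 10, 2)
  b <- make_sequences(x, L = 4, stride = 1, pad = "repeat")
  expect_identical(b$index, 1:10)
  # window ending at t=1 is all first-row
  expect_equal(b$x[1, , ], matrix(rep(x[1, ], each = 4), 4, 2))
  # a full window is the raw slice
  expect_equal(b$x[7, , ], x[4:7, ])
  bn <- make_sequences(x, L = 10, stride = 1, pad = "none")
  expect_identical(dim(bn$x)[1], 1L)
  expect_equal(bn$x[1, , ], x)
})

test_that("analytic BiLSTM gradients match finite differences", {
  set.seed(52)
  F <- 3; L <- 4; N <- 6
  X <- array(rnorm(N * F * L), dim = c(N, F, L))
  for (task in c("classification", "regression")) {
    O <- if (task == "classification") 3 else 1
    Y <- if (task == "classification") {
      m <- matrix(0, N, O); m[cbind(1:N, sample(1:O, N, TRUE))] <- 1; m
    } else matrix(rnorm(N), N, 1)
    par <- aftmon:::.bilstm_init_cpp(F, 3, 2, 4, O, 7)
    lg <- aftmon:::.bilstm_loss_grad_cpp(par, X, Y, task)
    eps <- 1e-6
    for (nm in names(par)) {
      g <- lg$grads[[nm]]
      for (idx in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
        p2 <- par
        p2[[nm]][idx] <- p2[[nm]][idx] + eps
        l2 <- aftmon:::.bilstm_loss_grad_cpp(p2, X, Y, task)$loss
        p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
        l1 <- aftmon:::.bilstm_loss_grad_cpp(p2, X, Y, task)$loss
        num <- (l2 - l1) / (2 * eps)
        expect_lt(abs(num - g[idx]) /
                    max(1e-6, abs(num) + abs(g[idx])), 1e-4)
      }
    }
  }
})

test_that("classification predictions live in the training label set", {
  set.seed(53)
  N <- 120; L <- 6; F <- 3
  cl <- sample(1:3, N, TRUE)
  X <- array(rnorm(N * L * F) + rep(2.5 * cl, L * F), dim = c(N, L, F))
  y <- factor(activity_codes()[cl], levels = activity_codes()[1:3])
  fit <- bilstm(X, y, hidden = c(5, 3), dense = 6, epochs = 10,
                batch_size = 32, learning_rate = 1e-2,
                validation_split = 0, seed = 2)
  p <- predict(fit, X)
  expect_length(p, N)
  expect_true(all(p %in% activity_codes()[1:3]))
  expect_gt(mean(p == y), 0.9)  # well-separated classes are learnable
  pr <- predict(fit, X, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, N), tolerance = 1e-9)
})

test_that("training on shuffled labels stays near chance level", {
  set.seed(54)
  N <- 400; L <- 5; F <- 3; K <- 4
  X <- array(rnorm(N * L * F), dim = c(N, L, F))
  y <- factor(sample(letters[1:K], N, TRUE))
  fit <- bilstm(X[1:200, , ], y[1:200], hidden = c(5, 3), dense = 6,
                epochs = 6, batch_size = 32, learning_rate = 1e-2,
                validation_split = 0, seed = 3)
  acc <- mean(predict(fit, X[201:400, , ]) == y[201:400])
  # chance 1/K plus 4 binomial standard errors
  expect_lt(acc, 1 / K + 4 * sqrt((1 / K) * (1 - 1 / K) / 200))
})

test_that("constant-target regression recovers the constant", {
  set.seed(55)
  N <- 150; L <- 5; F <- 2
  X <- array(rnorm(N * L * F), dim = c(N, L, F))
  y <- rep(7.5, N)
  fit <- bilstm(X, y, task = "regression", hidden = c(5, 3), dense = 6,
                epochs = 60, batch_size = 16, learning_rate = 5e-2,
                validation_split = 0, seed = 4)
  p <- predict(fit, X)
  expect_true(all(abs(p - 7.5) / 7.5 < 0.05))
  expect_true(all(p >= 0))  # clipped at zero
})

test_that("doubling the target scale doubles the mean-baseline RMSE", {
  set.seed(56)
  y <- rnorm(500, 10, 2)
  rmse <- function(a, p) sqrt(mean((a - p)^2))
  expect_equal(rmse(2 * y, mean(2 * y)), 2 * rmse(y, mean(y)),
               tolerance = 1e-12)
})

test_that("fits are reproducible for a fixed seed", {
  set.seed(57)
  N <- 80; L <- 5; F <- 3
  X <- array(rnorm(N * L * F), dim = c(N, L, F))
  y <- rnorm(N, 5)
  f1 <- bilstm(X, y, hidden = c(4, 3), dense = 4, epochs = 3,
               batch_size = 16, validation_split = 0.1, seed = 11)
  f2 <- bilstm(X, y, hidden = c(4, 3), dense = 4, epochs = 3,
               batch_size = 16, validation_split = 0.1, seed = 11)
  expect_equal(f1$params, f2$params)
  expect_identical(predict(f1, X), predict(f2, X))
})
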