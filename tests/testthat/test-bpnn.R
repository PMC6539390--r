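test_that("initialization respects the weight scale and seeding", {
  ctrl <- bpnn_control()
  n1 <- odsensor:::bpnn_init(5, ctrl, seed = 1)
  n2 <- odsensor:::bpnn_init(5, ctrl, seed = 1)
  n3 <- odsensor:::bpnn_init(5, ctrl, seed = 2)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_true(all(abs(n1$W1) <= 0.3) && all(abs(n1$W2) <= 0.3))
  expect_equal(n1$theta, numeric(10))
  expect_equal(n1$b, 0)
})

test_that("the forward pass evaluates the hidden/output equations exactly", {
  # zero weights: hidden all sigmoid(0) = 0.5, zero output weights -> 0
  net0 <- list(W1 = matrix(0, 2, 3), theta = numeric(3), W2 = numeric(3), b = 0)
  expect_equal(odsensor:::bpnn_forward(net0, matrix(0, 1, 2)), 0)

  # 1-1-1 net, unit weights: output = sigmoid(1)
  net1 <- list(W1 = matrix(1, 1, 1), theta = 0, W2 = 1, b = 0)
  expect_equal(odsensor:::bpnn_forward(net1, matrix(1, 1, 1)),
               1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(1 / (1 + exp(-1)), 0.731059, tolerance = 1e-6)

  # the output threshold shifts every prediction by -c
  net2 <- net1; net2$b <- net1$b + 0.25
  X <- matrix(rnorm(5), 5, 1)
  expect_equal(odsensor:::bpnn_forward(net2, X),
               odsensor:::bpnn_forward(net1, X) - 0.25)
})

test_that("analytic gradients match central finite differences", {
  numeric_grad <- function(net, X, y, eps = 1e-6) {
    g <- list()
    for (nm in c("W1", "theta", "W2", "b")) {
      par <- net[[nm]]
      gp <- par
      for (i in seq_along(par)) {
        up <- net; up[[nm]][i] <- par[i] + eps
        dn <- net; dn[[nm]][i] <- par[i] - eps
        gp[i] <- (odsensor:::bpnn_error(up, X, y) -
                    odsensor:::bpnn_error(dn, X, y)) / (2 * eps)
      }
      g[[nm]] <- gp
    }
    g
  }
  set.seed(5)
  for (rep in 1:20) {
    net <- list(W1 = matrix(rnorm(15, sd = 0.5), 3, 5),
                theta = rnorm(5, sd = 0.3),
                W2 = rnorm(5, sd = 0.5), b = rnorm(1, sd = 0.3))
    X <- matrix(runif(12), 4, 3)
    y <- runif(4)
    ga <- odsensor:::bpnn_gradient(net, X, y)
    gn <- numeric_grad(net, X, y)
    for (nm in c("W1", "theta", "W2", "b")) {
      denom <- pmax(abs(gn[[nm]]), 1e-4)
      expect_lt(max(abs(ga[[nm]] - gn[[nm]]) / denom), 1e-4)
    }
  }
})

test_that("training fits a representable function and stops as configured", {
  set.seed(2)
  X <- matrix(runif(200), 100, 2)
  y <- 0.3 * X[, 1] - 0.2 * X[, 2]
  fit <- bpnn(X, y, control = bpnn_control(error_goal = 1e-9), seed = 1)
  expect_gte(r2(y, fitted(fit)), 0.99)

  # saturating monotone 2-feature target (the network's intended regime)
  ys <- X[, 1] / (X[, 1] + 0.3) + 0.5 * X[, 2]
  fit2 <- bpnn(X, ys, control = bpnn_control(error_goal = 1e-9), seed = 1)
  expect_gte(r2(ys, fitted(fit2)), 0.99)

  # zero learning rate leaves the initial weights untouched
  init <- odsensor:::bpnn_init(2, bpnn_control(), seed = 3)
  frozen <- bpnn(X, y, control = bpnn_control(learning_rate = 0,
                                              max_epochs = 5), seed = 3)
  expect_equal(frozen$net$W1, init$W1)
  expect_equal(frozen$net$W2, init$W2)

  # trace contract: converged iff final E <= error_goal
  fit3 <- bpnn(X, y, control = bpnn_control(error_goal = 0.01), seed = 4)
  expect_identical(fit3$converged, tail(fit3$trace, 1) <= 0.01)
  expect_length(fit3$trace, fit3$epochs_run)
})

test_that("training is deterministic and batch mode agrees with the R gradient", {
  set.seed(8)
  X <- matrix(runif(60), 20, 3)
  y <- rowSums(X)
  f1 <- bpnn(X, y, seed = 11, control = quick_train())
  f2 <- bpnn(X, y, seed = 11, control = quick_train())
  expect_identical(f1$net, f2$net)

  # one batch epoch = one explicit gradient/momentum step of the R reference
  ctrl <- bpnn_control(update = "batch", max_epochs = 1, error_goal = 0)
  fitb <- bpnn(X, y, seed = 11, control = ctrl)
  init <- odsensor:::bpnn_init(3, ctrl, seed = 11)
  Xs <- odsensor:::scale_minmax(X, apply(X, 2, min),
                                apply(X, 2, max) - apply(X, 2, min))
  yss <- (y - min(y)) / (max(y) - min(y))
  g <- odsensor:::bpnn_gradient(init, Xs, yss)
  expect_equal(fitb$net$W1, init$W1 - 0.1 * g$W1, tolerance = 1e-12)
  expect_equal(fitb$net$W2, init$W2 - 0.1 * g$W2, tolerance = 1e-12)
  expect_equal(fitb$net$theta, init$theta - 0.1 * g$theta, tolerance = 1e-12)
  expect_equal(fitb$net$b, init$b - 0.1 * g$b, tolerance = 1e-12)
})

test_that("prediction applies the trained network row-wise on the OD scale", {
  d <- generate_dataset(n_batches = 2, seed = 21)
  X <- feature_matrix(d)[, c(9, 24)]
  fit <- bpnn(X, d$od_measured, seed = 2, control = quick_train())
  p <- predict(fit, X)
  expect_equal(p, fitted(fit))
  expect_equal(predict(fit, X[5, , drop = FALSE]), p[5])
  perm <- sample(nrow(X))
  expect_equal(predict(fit, X[perm, ]), p[perm])
  # recomputing E from predictions reproduces the final trace entry
  ys <- (d$od_measured - fit$scaling$y_lo) / fit$scaling$y_rng
  ps <- (p - fit$scaling$y_lo) / fit$scaling$y_rng
  expect_equal(mean(0.5 * (ps - ys)^2), tail(fit$trace, 1), tolerance = 1e-9)
  expect_error(predict(fit, X[, 1, drop = FALSE]), "expects")
})

test_that("formula interface and JSON serialization round-trip", {
  d <- generate_dataset(n_batches = 2, seed = 31)
  df <- data.frame(od = d$od_measured, f1 = feature_matrix(d)[, 9],
                   f2 = feature_matrix(d)[, 24])
  fit <- bpnn(od ~ f1 + f2, df, seed = 5, control = quick_train())
  expect_equal(predict(fit, df), fitted(fit), tolerance = 1e-12)

  path <- tempfile(fileext = ".json")
  write_bpnn(fit, path)
  back <- read_bpnn(path)
  expect_equal(predict(back, cbind(df$f1, df$f2)), fitted(fit),
               tolerance = 1e-8)
  unlink(path)
})
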