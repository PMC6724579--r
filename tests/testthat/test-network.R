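test_that("forward pass composes the documented activations", {
  spec <- network_spec(2, 1)
  model <- nn_init(spec, seed = 1)
  model$w1[] <- 0; model$w2[] <- 0
  expect_equal(nn_forward(model, c(3, -4)), 0.5)   # logistic(0)

  # hand-set weights evaluated by hand arithmetic
  model$w1[, 1] <- c(0.1, 0.4, -0.3)   # bias, in1, in2
  model$w2[, 1] <- c(-0.2, 0.7)        # bias, h1
  x <- c(1.5, -2)
  h <- tanh(0.1 + 0.4 * 1.5 - 0.3 * (-2))
  expect_equal(nn_forward(model, x), 1 / (1 + exp(-(-0.2 + 0.7 * h))),
               tolerance = 1e-12)

  # monotone in an input connected by positive weights
  s1 <- nn_forward(model, c(1, 0))
  s2 <- nn_forward(model, c(2, 0))
  expect_gt(s2, s1)
  expect_error(nn_forward(model, c(1, 2, 3)), "expected 2")
})

test_that("backpropagation matches central finite differences", {
  set.seed(8)
  spec <- network_spec(4, 3)
  model <- nn_init(spec, seed = 8)
  model$center <- rnorm(4); model$scale <- runif(4, 0.5, 2)
  x <- matrix(rnorm(20), 5, 4)
  y <- c(1, 0, 1, 1, 0)
  g <- nn_gradient(model, x, y)
  w0 <- c(as.vector(model$w1), as.vector(model$w2))
  gv <- c(as.vector(g$w1), as.vector(g$w2))
  eps <- 1e-6
  loss_at <- function(w) {
    m <- model
    n1 <- length(m$w1)
    m$w1 <- matrix(w[seq_len(n1)], nrow(m$w1), ncol(m$w1))
    m$w2 <- matrix(w[-seq_len(n1)], nrow(m$w2), 1)
    xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
    s <- nn_forward(m, x)
    -mean(y * log(s) + (1 - y) * log(1 - s))
  }
  fd <- vapply(seq_along(w0), function(i) {
    wp <- w0; wm <- w0
    wp[i] <- wp[i] + eps; wm[i] <- wm[i] - eps
    (loss_at(wp) - loss_at(wm)) / (2 * eps)
  }, numeric(1))
  expect_equal(gv, fd, tolerance = 1e-5 * max(1, max(abs(fd))))
})

test_that("batch gradient is the mean of per-example gradients", {
  model <- nn_init(network_spec(3, 2), seed = 2)
  x <- matrix(rnorm(9), 3, 3)
  y <- c(1, 0, 1)
  g_all <- nn_gradient(model, x, y)
  parts <- lapply(1:3, function(i) nn_gradient(model, x[i, , drop = FALSE], y[i]))
  expect_equal(g_all$w1, (parts[[1]]$w1 + parts[[2]]$w1 + parts[[3]]$w1) / 3,
               tolerance = 1e-12)
  expect_equal(g_all$w2, (parts[[1]]$w2 + parts[[2]]$w2 + parts[[3]]$w2) / 3,
               tolerance = 1e-12)
  expect_error(nn_gradient(model, x[0, , drop = FALSE], integer(0)), "empty")
  x[1, 1] <- NaN
  expect_error(nn_gradient(model, x, y), "finite")
})

test_that("SCG training separates a separable toy and is deterministic", {
  set.seed(1)
  x <- matrix(rnorm(400), 200, 2)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  tr <- 1:150; va <- 151:200
  net <- scg_train(x[tr, ], y[tr], x[va, ], y[va], n_hidden = 3, seed = 5)
  expect_equal(roc_auc(nn_forward(net, x[tr, ]), y[tr]), 1)
  # accepted-step training loss is non-increasing
  expect_true(all(diff(net$history$train_loss) <= 1e-9))
  net2 <- scg_train(x[tr, ], y[tr], x[va, ], y[va], n_hidden = 3, seed = 5)
  expect_identical(net$w1, net2$w1)
  expect_identical(net$w2, net2$w2)
  expect_error(scg_train(x[0, ], integer(0), x[va, ], y[va]), "empty")
})

test_that("standardization comes from the training split only", {
  set.seed(3)
  x <- matrix(rnorm(300, mean = 5, sd = 3), 100, 3)
  y <- rbinom(100, 1, 0.5)
  tr <- 1:70; va <- 71:100
  net <- scg_train(x[tr, ], y[tr], x[va, ], y[va], n_hidden = 2, seed = 1,
                   max_epochs = 5)
  expect_equal(net$center, colMeans(x[tr, ]))
  expect_equal(net$scale, apply(x[tr, ], 2, sd))
  xs <- sweep(sweep(x[tr, ], 2, net$center), 2, net$scale, "/")
  expect_equal(colMeans(xs), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(xs, 2, sd), rep(1, 3), tolerance = 1e-12)
})

test_that("the returned snapshot is the best-validation model", {
  set.seed(9)
  x <- matrix(rnorm(200), 100, 2)
  y <- as.integer(x[, 1] > 0.2 * rnorm(100))
  net <- scg_train(x[1:60, ], y[1:60], x[61:100, ], y[61:100], n_hidden = 4,
                   seed = 2, max_epochs = 100)
  expect_equal(net$best_val_loss, min(net$history$val_loss), tolerance = 1e-12)
})

test_that("serialization round-trips weights exactly", {
  net <- nn_init(network_spec(7, 4), seed = 3)
  net$center <- rnorm(7); net$scale <- runif(7)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  back <- read_network(f)
  expect_identical(back$w1, net$w1)
  expect_identical(back$w2, net$w2)
  expect_identical(back$center, net$center)
  expect_identical(back$scale, net$scale)
  expect_equal(back$spec$n_inputs, 7)
  expect_equal(back$spec$n_hidden, 4)
})

test_that("tidy and glance summarize fitted networks", {
  net <- nn_init(network_spec(3, 2), seed = 1)
  td <- tidy(net)
  expect_equal(nrow(td), (3 + 1) * 2 + (2 + 1))
  gl <- glance(net)
  expect_equal(gl$n_inputs, 3L)
  expect_equal(gl$n_hidden, 2L)
})
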