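test_that("initialization is reproducible and respects the fan-in bound", {
  m1 <- init_mlp(c(259, rep(8, 6), 2), "arctan", seed = 3)
  m2 <- init_mlp(c(259, rep(8, 6), 2), "arctan", seed = 3)
  expect_identical(m1$W, m2$W)
  expect_length(m1$W, 7L)
  for (i in seq_along(m1$W)) {
    expect_lte(max(abs(m1$W[[i]])), 1 / sqrt(ncol(m1$W[[i]])))
    expect_equal(m1$b[[i]], numeric(nrow(m1$W[[i]])))
  }
  expect_error(init_mlp(c(10, 2), "arctan"), "hidden")
  expect_error(init_mlp(c(10, 5, 3), "arctan"), "softmax")
})

test_that("forward pass produces a softmax distribution", {
  m <- init_mlp(c(5, 4, 2), "sigmoid", seed = 1)
  p <- mlp_forward(m, stats::rnorm(5))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  P <- mlp_forward(m, matrix(stats::rnorm(15), 3, 5))
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
  expect_error(mlp_forward(m, c(1, 2, NA, 4, 5)), "finite")
})

test_that("a forced single layer reproduces a hand-computed softmax", {
  # 2 features -> 2 outputs, weights set by hand: z = W x + b
  m <- init_mlp(c(2, 2, 2), "arctan", seed = 1)
  m$W[[1]] <- diag(2) * 0          # hidden contributes atan(0) = 0
  m$b[[1]] <- c(1, -1)             # fixed hidden activations atan(+-1)
  m$W[[2]] <- matrix(c(2, -1, 0.5, 1), 2, 2)
  m$b[[2]] <- c(0.1, -0.2)
  a <- atan(c(1, -1))
  z <- m$W[[2]] %*% a + m$b[[2]]
  expected <- exp(z) / sum(exp(z))
  expect_equal(mlp_forward(m, c(3.7, -1.2)), as.vector(expected),
               tolerance = 1e-12)
  # arctan closed form at pre-activation 1
  expect_equal(a[1], pi / 4)
})

test_that("binary cross-entropy closed forms", {
  expect_lt(bce_loss(1, 1), 1e-10)
  expect_lt(bce_loss(0, 0), 1e-10)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  set.seed(9)
  y <- stats::rbinom(5, 1, 0.5); p <- stats::runif(5)
  singles <- vapply(1:5, function(i) bce_loss(y[i], p[i]), numeric(1))
  expect_equal(bce_loss(y, p), mean(singles), tolerance = 1e-12)
})

test_that("output-layer error is p - y and gradients pass finite differences", {
  set.seed(10)
  for (act in c("arctan", "tanh", "sigmoid")) {
    m <- init_mlp(c(10, 6, 4, 2), act, seed = 17)
    x <- stats::rnorm(10); y <- 1L
    gr <- mlp_backward(m, x, y)
    p <- mlp_forward(m, x)
    expect_equal(gr$db[[3]], p - c(0, 1), tolerance = 1e-12)
    # central-difference check on every parameter of every layer
    eps <- 1e-6
    loss_at <- function(model) bce_loss(y, mlp_forward(model, x)[2])
    for (li in 1:3) {
      for (idx in seq_along(m$W[[li]])) {
        mp <- m; mp$W[[li]][idx] <- mp$W[[li]][idx] + eps
        mm <- m; mm$W[[li]][idx] <- mm$W[[li]][idx] - eps
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(gr$dW[[li]][idx], fd, tolerance = 1e-6,
                     label = paste(act, "layer", li, "w", idx))
      }
      for (idx in seq_along(m$b[[li]])) {
        mp <- m; mp$b[[li]][idx] <- mp$b[[li]][idx] + eps
        mm <- m; mm$b[[li]][idx] <- mm$b[[li]][idx] - eps
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(gr$db[[li]][idx], fd, tolerance = 1e-6,
                     label = paste(act, "layer", li, "b", idx))
      }
    }
  }
})

test_that("a saturated-correct prediction yields vanishing gradients", {
  m <- init_mlp(c(4, 3, 2), "tanh", seed = 2)
  m$b[[2]] <- c(-25, 25)  # p ~ (1e-22, 1): matches y = 1
  gr <- mlp_backward(m, stats::rnorm(4), 1L)
  expect_lt(max(abs(unlist(gr$dW))), 1e-10)
  expect_lt(max(abs(unlist(gr$db))), 1e-10)
})

test_that("zero learning rate leaves weights unchanged", {
  d <- toy_blobs()
  m <- init_mlp(c(2, 4, 2), "arctan", seed = 5)
  tr <- mlp_train(m, d$X, d$y, d$X, d$y,
                  train_config(lr = 0, epochs = 3, batch = 1, seed = 1))
  expect_identical(tr$model$W, m$W)
  expect_identical(tr$model$b, m$b)
})

test_that("one SGD step equals the hand-computed update", {
  m <- init_mlp(c(2, 3, 2), "sigmoid", seed = 8)
  x <- c(0.4, -1.1); y <- 1L
  lr <- 0.05
  gr <- mlp_backward(m, x, y)
  tr <- mlp_train(m, matrix(x, 1, 2), y, matrix(x, 1, 2), y,
                  train_config(lr = lr, epochs = 1, batch = 1, seed = 1,
                               selection_rule = "final"))
  for (i in seq_along(m$W)) {
    expect_equal(tr$model$W[[i]], m$W[[i]] - lr * gr$dW[[i]],
                 tolerance = 1e-12)
    expect_equal(tr$model$b[[i]], m$b[[i]] - lr * gr$db[[i]],
                 tolerance = 1e-12)
  }
})

test_that("SGD separates a linearly separable two-feature problem", {
  d <- toy_blobs(40)
  m <- init_mlp(c(2, 8, 2), "arctan", seed = 1)
  tr <- mlp_train(m, d$X, d$y, d$X, d$y,
                  train_config(lr = 1e-2, epochs = 60, batch = 1, seed = 1))
  expect_equal(mlp_evaluate(tr$model, d$X, d$y)$accuracy, 1.0)
})

test_that("full-batch mode trains too and histories have one row per epoch", {
  d <- toy_blobs(15)
  m <- init_mlp(c(2, 4, 2), "tanh", seed = 3)
  tr <- mlp_train(m, d$X, d$y, d$X, d$y,
                  train_config(lr = 0.5, epochs = 25, batch = Inf, seed = 1))
  expect_equal(nrow(tr$history), 25L)
  expect_gte(tr$history$train_acc[25], 0.9)
  expect_equal(tr$selected_epoch, which.min(tr$history$test_cost))
})

test_that("evaluation metrics match hand calculations", {
  # confusion [[3,1],[2,4]]: truth 0 x4 (3 right), truth 1 x6 (4 right)
  y    <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1)
  pred <- c(0, 0, 0, 1, 0, 0, 1, 1, 1, 1)
  met <- kcdetect:::metrics_from_predictions(y, pred)
  expect_equal(met$accuracy, 0.7)
  expect_equal(unname(met$confusion), matrix(c(3, 2, 1, 4), 2, 2))
  expect_equal(met$per_class$precision, c(3 / 5, 4 / 5))
  expect_equal(met$per_class$recall, c(3 / 4, 4 / 6))
  expect_equal(met$per_class$f1[2],
               2 * (4 / 5) * (4 / 6) / ((4 / 5) + (4 / 6)))
  expect_equal(met$micro_f1, 0.7)
  # accuracy equals the brute-force correct count on any prediction vector
  set.seed(12)
  y2 <- stats::rbinom(40, 1, 0.4); p2 <- stats::rbinom(40, 1, 0.5)
  met2 <- kcdetect:::metrics_from_predictions(y2, p2)
  expect_equal(met2$accuracy, sum(y2 == p2) / 40)
})

test_that("absent truth class reports NaN recall with a warning", {
  expect_warning(
    met <- kcdetect:::metrics_from_predictions(c(0, 0, 0), c(0, 1, 0)),
    "recall undefined")
  expect_true(is.nan(met$per_class$recall[2]))
})

test_that("perfect predictions give accuracy and F1 of 1", {
  d <- toy_blobs(20)
  m <- init_mlp(c(2, 8, 2), "arctan", seed = 1)
  tr <- mlp_train(m, d$X, d$y, d$X, d$y,
                  train_config(lr = 1e-2, epochs = 60, batch = 1, seed = 1))
  met <- mlp_evaluate(tr$model, d$X, d$y)
  expect_equal(met$accuracy, 1.0)
  expect_equal(met$per_class$f1, c(1, 1))
})

test_that("JSON serialization round-trips the model exactly", {
  m <- init_mlp(c(7, 5, 2), "arctan", seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(m, path)
  m2 <- read_mlp(path)
  x <- matrix(stats::rnorm(21), 3, 7)
  expect_equal(mlp_forward(m2, x), mlp_forward(m, x), tolerance = 1e-15)
  expect_equal(m2$activation, "arctan")
})
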