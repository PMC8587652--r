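#' Initialize a multilayer perceptron
#'
#' Fully connected network with a 2-unit softmax head. Hidden activations:
#' `arctan` (the best-performing choice for this task, and rarely available
#' in off-the-shelf frameworks), `tanh`, or `sigmoid`. Weights are drawn
#' uniformly on `(-1/sqrt(fan_in), +1/sqrt(fan_in))`, biases start at zero.
#'
#' @param layer_sizes integer vector `(input, hidden..., output)`; at least
#'   one hidden layer; output size 2.
#' @param activation `"arctan"`, `"tanh"` or `"sigmoid"`.
#' @param seed integer seed for reproducible initialization.
#' @return list of class `mlp_model` with `W`, `b`, `layer_sizes`,
#'   `activation`, `seed`.
#' @examples
#' m <- init_mlp(c(259, rep(8, 6), 2), "arctan", seed = 1)
#' @export
init_mlp <- function(layer_sizes, activation = c("arctan", "tanh", "sigmoid"),
                     seed = 1L) {
  activation <- match.arg(activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L) {
    stop("need at least input, one hidden and output layer sizes")
  }
  if (layer_sizes[length(layer_sizes)] != 2L) {
    stop("the output layer must have 2 (softmax) units")
  }
  set.seed(seed)
  nl <- length(layer_sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (i in seq_len(nl)) {
    fan_in <- layer_sizes[i]
    lim <- 1 / sqrt(fan_in)
    W[[i]] <- matrix(stats::runif(layer_sizes[i + 1L] * fan_in, -lim, lim),
                     layer_sizes[i + 1L], fan_in)
    b[[i]] <- numeric(layer_sizes[i + 1L])
  }
  structure(list(W = W, b = b, layer_sizes = layer_sizes,
                 activation = activation, seed = seed),
            class = "mlp_model")
}

act_fun <- function(name) {
  switch(name,
    arctan  = list(f = atan, d = function(z, a) 1 / (1 + z^2)),
    tanh    = list(f = tanh, d = function(z, a) 1 - a^2),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   d = function(z, a) a * (1 - a)))
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

# forward pass keeping intermediates; X is d x n (columns = examples)
mlp_forward_full <- function(model, X) {
  af <- act_fun(model$activation)
  nl <- length(model$W)
  Zs <- vector("list", nl); As <- vector("list", nl + 1L)
  As[[1L]] <- X
  A <- X
  for (i in seq_len(nl)) {
    Z <- model$W[[i]] %*% A + model$b[[i]]
    if (i < nl) A <- af$f(Z) else A <- softmax_cols(Z)
    Zs[[i]] <- Z; As[[i + 1L]] <- A
  }
  list(Zs = Zs, As = As, probs = A)
}

#' Forward pass: class probabilities
#'
#' @param model an [init_mlp()] model.
#' @param x feature vector (length = input size) or matrix with one example
#'   per row.
#' @return probability vector `(P(class 0), P(class 1))`, or an `n x 2`
#'   matrix for matrix input. Softmax rows sum to 1.
#' @export
mlp_forward <- function(model, x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == model$layer_sizes[1])
    if (!all(is.finite(x))) stop("non-finite input")
    t(mlp_forward_full(model, t(x))$probs)
  } else {
    stopifnot(length(x) == model$layer_sizes[1])
    if (!all(is.finite(x))) stop("non-finite input")
    as.vector(mlp_forward_full(model, matrix(x, ncol = 1L))$probs)
  }
}

#' Binary cross-entropy loss
#'
#' `L = -(1/N) sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]` where `p_i`
#' is the predicted positive-class probability, clipped to
#' `[1e-12, 1 - 1e-12]`. For a 2-unit softmax head this equals the
#' categorical cross-entropy of the one-hot pair.
#'
#' @param y 0/1 labels (or a one-hot matrix whose second column is taken).
#' @param p positive-class probabilities (or an `n x 2` probability matrix).
#' @return scalar mean loss over the batch.
#' @export
bce_loss <- function(y, p) {
  if (is.matrix(y)) y <- y[, 2L]
  if (is.matrix(p)) p <- p[, 2L]
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Backpropagation gradients
#'
#' Exact gradients of the softmax + cross-entropy composite for one example;
#' the output-layer error simplifies to `p - y_onehot`.
#'
#' @param model an [init_mlp()] model.
#' @param x feature vector.
#' @param y label in `{0, 1}`.
#' @return list with gradient lists `dW` and `db` (shapes matching the
#'   model) and the forward `probs`.
#' @export
mlp_backward <- function(model, x, y) {
  af <- act_fun(model$activation)
  fw <- mlp_forward_full(model, matrix(x, ncol = 1L))
  nl <- length(model$W)
  y_onehot <- c(1 - y, y)
  delta <- fw$probs - y_onehot            # output-layer error
  dW <- vector("list", nl); db <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    dW[[i]] <- delta %*% t(fw$As[[i]])
    db[[i]] <- as.vector(delta)
    if (i > 1L) {
      delta <- (t(model$W[[i]]) %*% delta) *
        af$d(fw$Zs[[i - 1L]], fw$As[[i]])
    }
  }
  list(dW = dW, db = db, probs = as.vector(fw$probs))
}

#' Training configuration
#'
#' Defaults reproduce the reference protocol: single-example stochastic
#' gradient descent (batch size 1), constant learning rate `1e-5`,
#' 100 epochs, and model selection by the lowest cost on the evaluation set.
#' Selecting on the test lot mirrors the reference protocol; for leakage-free
#' estimates pass a separate validation set as `eval` and keep a held-out
#' test set (the 80/10/10 route).
#'
#' @param lr learning rate (>= 0; 0 leaves the weights untouched).
#' @param epochs number of epochs (>= 1).
#' @param batch minibatch size; 1 = SGD, `Inf` = full-batch gradient descent.
#' @param seed RNG seed for the per-epoch shuffles.
#' @param selection_rule `"lowest-test-cost"` or `"final"`.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-5, epochs = 100L, batch = 1L, seed = 1L,
                         selection_rule = c("lowest-test-cost", "final")) {
  stopifnot(lr >= 0, epochs >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs), batch = batch,
                 seed = as.integer(seed),
                 selection_rule = match.arg(selection_rule)),
            class = "train_config")
}

#' Train an MLP by (stochastic) gradient descent
#'
#' Per epoch the training examples are shuffled and consumed in minibatches
#' of `cfg$batch` (default 1: the single-example update
#' `w <- w - lr * grad`). Train and evaluation cost/accuracy are recorded
#' every epoch; the returned model is the epoch snapshot selected by
#' `cfg$selection_rule`.
#'
#' @param model an [init_mlp()] model.
#' @param X_train,y_train training features (rows = examples) and 0/1 labels.
#' @param X_eval,y_eval evaluation set used for selection.
#' @param cfg a [train_config()].
#' @return list with `model` (selected), `history` (per-epoch data frame),
#'   `selected_epoch`.
#' @export
mlp_train <- function(model, X_train, y_train, X_eval, y_eval,
                      cfg = train_config()) {
  stopifnot(nrow(X_train) == length(y_train),
            nrow(X_eval) == length(y_eval), nrow(X_train) >= 1L)
  set.seed(cfg$seed)
  n <- nrow(X_train)
  bsz <- if (is.infinite(cfg$batch)) n else as.integer(cfg$batch)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_cost = NA_real_,
                     train_acc = NA_real_, test_cost = NA_real_,
                     test_acc = NA_real_)
  best_cost <- Inf; best_model <- model; best_epoch <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq.int(1L, n, by = bsz)) {
      idx <- ord[start:min(start + bsz - 1L, n)]
      gW <- NULL; gb <- NULL
      for (i in idx) {
        gr <- mlp_backward(model, X_train[i, ], y_train[i])
        if (is.null(gW)) {
          gW <- gr$dW; gb <- gr$db
        } else {
          for (j in seq_along(gW)) {
            gW[[j]] <- gW[[j]] + gr$dW[[j]]
            gb[[j]] <- gb[[j]] + gr$db[[j]]
          }
        }
      }
      sc <- cfg$lr / length(idx)
      for (j in seq_along(model$W)) {
        model$W[[j]] <- model$W[[j]] - sc * gW[[j]]
        model$b[[j]] <- model$b[[j]] - sc * gb[[j]]
      }
    }
    p_tr <- mlp_forward(model, X_train)[, 2L]
    p_ev <- mlp_forward(model, X_eval)[, 2L]
    hist$train_cost[ep] <- bce_loss(y_train, p_tr)
    hist$train_acc[ep] <- mean((p_tr > 0.5) == (y_train == 1))
    hist$test_cost[ep] <- bce_loss(y_eval, p_ev)
    hist$test_acc[ep] <- mean((p_ev > 0.5) == (y_eval == 1))
    if (!is.finite(hist$train_cost[ep])) {
      stop(sprintf("training diverged at epoch %d (non-finite cost)", ep))
    }
    if (cfg$selection_rule == "lowest-test-cost") {
      if (hist$test_cost[ep] < best_cost) {
        best_cost <- hist$test_cost[ep]; best_model <- model; best_epoch <- ep
      }
    } else {
      best_model <- model; best_epoch <- ep
    }
  }
  list(model = best_model, history = hist, selected_epoch = best_epoch)
}

#' Classification metrics
#'
#' @param model an [init_mlp()] model.
#' @param X,y features and 0/1 labels.
#' @param threshold decision threshold on the positive-class probability.
#' @return list with `accuracy`, `confusion` (2 x 2, rows = truth),
#'   `per_class` data frame (precision/recall/F1 for classes 0 and 1) and
#'   `micro_f1` (= accuracy for single-label classification). A class absent
#'   from the truth yields `NaN` recall with a warning.
#' @export
mlp_evaluate <- function(model, X, y, threshold = 0.5) {
  stopifnot(nrow(X) == length(y), length(y) >= 1L)
  p <- mlp_forward(model, X)[, 2L]
  pred <- as.integer(p > threshold)
  metrics_from_predictions(y, pred)
}

# shared by mlp_evaluate and the toy-confusion tests
metrics_from_predictions <- function(y, pred) {
  conf <- matrix(0, 2L, 2L, dimnames = list(truth = c("0", "1"),
                                            pred = c("0", "1")))
  for (i in seq_along(y)) {
    conf[y[i] + 1L, pred[i] + 1L] <- conf[y[i] + 1L, pred[i] + 1L] + 1
  }
  acc <- sum(diag(conf)) / sum(conf)
  per <- lapply(1:2, function(k) {
    tp <- conf[k, k]
    prec <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else NaN
    if (sum(conf[k, ]) == 0) {
      warning(sprintf("class %d absent from truth; recall undefined", k - 1L))
      rec <- NaN
    } else {
      rec <- tp / sum(conf[k, ])
    }
    f1 <- if (is.finite(prec) && is.finite(rec) && (prec + rec) > 0) {
      2 * prec * rec / (prec + rec)
    } else {
      NaN
    }
    c(precision = prec, recall = rec, f1 = f1)
  })
  per_class <- data.frame(class = c(0L, 1L), do.call(rbind, per))
  list(accuracy = acc, confusion = conf, per_class = per_class,
       micro_f1 = acc)
}

#' Serialize / restore an MLP as JSON
#'
#' @param model an [init_mlp()] model.
#' @param path file path.
#' @return `write_mlp` invisibly returns `path`; `read_mlp` the model.
#' @export
write_mlp <- function(model, path) {
  obj <- list(layer_sizes = model$layer_sizes, activation = model$activation,
              seed = model$seed,
              W = lapply(model$W, as.vector),
              b = model$b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- as.integer(obj$layer_sizes)
  nl <- length(ls) - 1L
  W <- lapply(seq_len(nl), function(i) {
    matrix(obj$W[[i]], ls[i + 1L], ls[i])
  })
  b <- lapply(seq_len(nl), function(i) as.numeric(obj$b[[i]]))
  structure(list(W = W, b = b, layer_sizes = ls,
                 activation = obj$activation, seed = obj$seed),
            class = "mlp_model")
}
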