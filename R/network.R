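# Feed-forward network (one hidden layer, single logistic output) with
# exact backpropagation and the scaled-conjugate-gradient trainer of
# Moller (1993), using validation-based early stopping.

#' Network architecture specification
#'
#' One hidden layer, a single output neuron and two constant bias nodes
#' (one per layer).  Hidden activation is hyperbolic tangent, output is
#' logistic, so scores live in (0, 1).
#'
#' @param n_inputs input dimension (9-180 across the package's encoders)
#' @param n_hidden hidden neurons (1-10)
#' @return a `network_spec`
#' @export
network_spec <- function(n_inputs, n_hidden = 5) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, n_hidden <= 10)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 hidden_activation = "tanh", output_activation = "logistic"),
            class = "network_spec")
}

#' Initialize a network with fan-in-scaled symmetric uniform weights
#'
#' @param spec a [network_spec()]
#' @param seed RNG seed
#' @return an `scg_net` model (untrained; identity standardization)
#' @export
nn_init <- function(spec, seed = 1) {
  set.seed(seed)
  r1 <- 1 / sqrt(spec$n_inputs + 1)
  r2 <- 1 / sqrt(spec$n_hidden + 1)
  model <- list(
    spec = spec,
    w1 = matrix(runif((spec$n_inputs + 1) * spec$n_hidden, -r1, r1),
                spec$n_inputs + 1, spec$n_hidden),
    w2 = matrix(runif(spec$n_hidden + 1, -r2, r2), spec$n_hidden + 1, 1),
    center = rep(0, spec$n_inputs), scale = rep(1, spec$n_inputs),
    history = NULL)
  class(model) <- "scg_net"
  model
}

logistic <- function(z) 1 / (1 + exp(-z))

standardize <- function(x, model) {
  sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
}

#' Forward pass: immunogenicity scores in (0, 1)
#'
#' @param model a trained or initialized `scg_net`
#' @param x numeric matrix/data frame (rows = examples) or a single vector
#' @return numeric vector of scores
#' @export
nn_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$spec$n_inputs) {
    stop("forward: expected ", model$spec$n_inputs, " inputs, got ", ncol(x))
  }
  xs <- standardize(x, model)
  h <- tanh(cbind(1, xs) %*% model$w1)
  as.vector(logistic(cbind(1, h) %*% model$w2))
}

#' @export
predict.scg_net <- function(object, newdata, ...) nn_forward(object, newdata)

# mean binary cross-entropy on standardized inputs
nn_loss <- function(model, xs, y) {
  h <- tanh(cbind(1, xs) %*% model$w1)
  s <- logistic(cbind(1, h) %*% model$w2)
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Backpropagation gradient of the cross-entropy loss
#'
#' @param model an `scg_net`
#' @param x input matrix (raw scale; the model's standardization applies)
#' @param y 0/1 targets
#' @return list with gradients `w1`, `w2` of the mean loss
#' @export
nn_gradient <- function(model, x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("gradient: empty batch")
  if (any(!is.finite(x))) stop("gradient: non-finite inputs")
  xs <- standardize(x, model)
  grad_std(model, xs, y)
}

grad_std <- function(model, xs, y) {
  n <- nrow(xs)
  a1 <- cbind(1, xs)
  h <- tanh(a1 %*% model$w1)
  a2 <- cbind(1, h)
  s <- as.vector(logistic(a2 %*% model$w2))
  d2 <- matrix((s - y) / n, n, 1)              # dL/dz2 for logistic + CE
  g2 <- crossprod(a2, d2)
  dh <- (d2 %*% t(model$w2[-1, , drop = FALSE])) * (1 - h^2)
  g1 <- crossprod(a1, dh)
  list(w1 = g1, w2 = g2)
}

flatten <- function(g) c(as.vector(g$w1), as.vector(g$w2))
unflatten <- function(model, v) {
  n1 <- length(model$w1)
  model$w1 <- matrix(v[seq_len(n1)], nrow(model$w1), ncol(model$w1))
  model$w2 <- matrix(v[-seq_len(n1)], nrow(model$w2), 1)
  model
}

#' Train a network by scaled conjugate gradients with early stopping
#'
#' Implements the scaled-conjugate-gradient update rules (conjugate
#' directions with Hessian-free curvature estimates and
#' Levenberg-Marquardt-style adjustment of the scaling parameter).
#' Standardization statistics (mean/sd) are computed from the training set
#' only and stored on the model; training stops at `max_epochs` or when
#' validation loss has failed to improve for `patience` consecutive
#' epochs, and the best-validation snapshot is returned.
#'
#' @param x_train,y_train training inputs (raw scale) and 0/1 targets
#' @param x_val,y_val validation split used solely for stopping
#' @param n_hidden hidden-layer size
#' @param patience consecutive validation failures tolerated
#' @param max_epochs epoch cap
#' @param seed initialization seed
#' @param sigma0,lambda0 SCG internal constants
#' @return a trained `scg_net` with a `history` tibble
#' @export
scg_train <- function(x_train, y_train, x_val, y_val, n_hidden = 5,
                      patience = 6, max_epochs = 1000, seed = 1,
                      sigma0 = 5e-5, lambda0 = 5e-7) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (nrow(x_train) == 0 || nrow(x_val) == 0) {
    stop("scg_train: empty train or validation split")
  }
  model <- nn_init(network_spec(ncol(x_train), n_hidden), seed = seed)
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  model$center <- ctr; model$scale <- scl
  xs <- standardize(x_train, model)
  xv <- standardize(x_val, model)

  loss_w <- function(w) nn_loss(unflatten(model, w), xs, y_train)
  grad_w <- function(w) flatten(grad_std(unflatten(model, w), xs, y_train))

  w <- flatten(model)
  nw <- length(w)
  r <- -grad_w(w)
  p <- r
  lambda <- lambda0; lambda_bar <- 0
  success <- TRUE
  delta <- 0; mu <- 0
  best_val <- Inf; best_w <- w; fails <- 0L
  hist <- vector("list", max_epochs)
  e_w <- loss_w(w)

  for (epoch in seq_len(max_epochs)) {
    p2 <- sum(p * p)
    if (p2 < 1e-30) break
    pnorm_ <- sqrt(p2)
    if (success) {
      sigma <- sigma0 / pnorm_
      s <- (grad_w(w + sigma * p) + r) / sigma   # r = -grad, so grad = -r
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    e_new <- loss_w(w + alpha * p)
    cmp <- 2 * delta * (e_w - e_new) / (mu^2)
    if (cmp >= 0) {
      w <- w + alpha * p
      e_w <- e_new
      r_new <- -grad_w(w)
      lambda_bar <- 0
      success <- TRUE
      if (epoch %% nw == 0) {
        p <- r_new                      # periodic restart
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (cmp >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (cmp < 0.25) lambda <- lambda + delta * (1 - cmp) / p2
    if (lambda > 1e20) lambda <- 1e20

    val <- nn_loss(unflatten(model, w), xv, y_val)
    hist[[epoch]] <- c(epoch = epoch, train_loss = e_w, val_loss = val)
    if (val < best_val - 1e-12) {
      best_val <- val; best_w <- w; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= patience) break
    }
  }
  model <- unflatten(model, best_w)
  model$history <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null,
                                                                 logical(1))]))
  model$best_val_loss <- best_val
  model
}

#' @export
print.scg_net <- function(x, ...) {
  cat("<scg_net>", x$spec$n_inputs, "inputs ->", x$spec$n_hidden,
      "tanh hidden -> 1 logistic output",
      if (!is.null(x$history)) paste0("| trained ", nrow(x$history),
                                      " epochs, best val loss ",
                                      format(x$best_val_loss, digits = 5)),
      "\n")
  invisible(x)
}

#' Tidiers for fitted objects
#'
#' `tidy()` returns per-element rows (weights, terms, folds as
#' appropriate); `glance()` returns a one-row model summary.
#'
#' @param x a fitted/structured structimm object
#' @param ... unused
#' @return a tibble
#' @name tidy_structimm
NULL

#' @rdname tidy_structimm
#' @exportS3Method generics::tidy
tidy.scg_net <- function(x, ...) {
  w1 <- x$w1; w2 <- x$w2
  from1 <- c("bias", paste0("in", seq_len(nrow(w1) - 1)))
  dplyr::bind_rows(
    tidyr::expand_grid(layer = "input_hidden", from = from1,
                       to = paste0("h", seq_len(ncol(w1)))) |>
      dplyr::mutate(weight = as.vector(w1)),
    tibble::tibble(layer = "hidden_output",
                   from = c("bias", paste0("h", seq_len(nrow(w2) - 1))),
                   to = "out", weight = as.vector(w2)))
}

#' @rdname tidy_structimm
#' @exportS3Method generics::glance
glance.scg_net <- function(x, ...) {
  tibble::tibble(n_inputs = x$spec$n_inputs, n_hidden = x$spec$n_hidden,
                 epochs = if (is.null(x$history)) 0L else nrow(x$history),
                 best_val_loss = if (is.null(x$best_val_loss)) NA_real_
                                 else x$best_val_loss)
}

#' Serialize a network to a plain-text JSON file (exact round-trip)
#'
#' Doubles are written with 17 significant digits, which reconstructs the
#' binary values exactly on read.
#'
#' @param model an `scg_net`
#' @param path output file
#' @return `path` invisibly
#' @export
write_network <- function(model, path) {
  num <- function(v) sprintf("%.17g", v)
  obj <- list(spec = model$spec[c("n_inputs", "n_hidden")],
              hidden_activation = model$spec$hidden_activation,
              output_activation = model$spec$output_activation,
              w1 = list(dim = dim(model$w1), data = num(as.vector(model$w1))),
              w2 = list(dim = dim(model$w2), data = num(as.vector(model$w2))),
              center = num(model$center), scale = num(model$scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(obj$spec$n_inputs, obj$spec$n_hidden)
  model <- list(
    spec = spec,
    w1 = matrix(as.numeric(obj$w1$data), obj$w1$dim[1], obj$w1$dim[2]),
    w2 = matrix(as.numeric(obj$w2$data), obj$w2$dim[1], obj$w2$dim[2]),
    center = as.numeric(obj$center), scale = as.numeric(obj$scale),
    history = NULL)
  class(model) <- "scg_net"
  model
}
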