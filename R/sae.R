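# Stacked autoencoder: greedily trained rectifier autoencoder stages that
# bring heterogeneous raw attribute vectors to a common 64-d representation.
# Encoder h = relu(W x + p), decoder y = relu(W' h + q), mean squared
# reconstruction loss, full-batch gradient descent with momentum.

.relu <- function(z) pmax(z, 0)

# One autoencoder stage. X: n x d_in (rows = samples). Returns weights plus
# the per-epoch loss trace.
.train_stage <- function(X, d_hidden, epochs, learning_rate) {
  d_in <- ncol(X)
  n <- nrow(X)
  sd0 <- sqrt(2 / d_in)
  W  <- matrix(stats::rnorm(d_hidden * d_in, sd = sd0), d_hidden, d_in)
  p  <- rep(0.01, d_hidden)
  Wd <- matrix(stats::rnorm(d_in * d_hidden, sd = sqrt(2 / d_hidden)),
               d_in, d_hidden)
  # decoder bias starts at the feature means so no output unit is born dead
  q  <- colMeans(X)
  vW <- W * 0; vp <- p * 0; vWd <- Wd * 0; vq <- q * 0
  mom <- 0.9
  lr <- learning_rate
  Xt <- t(X)                       # d_in x n
  loss_of <- function(Y) mean((Y - Xt)^2)
  trace <- numeric(epochs + 1L)
  Z1 <- W %*% Xt + p; H <- .relu(Z1)
  Z2 <- Wd %*% H + q; Y <- .relu(Z2)
  trace[1L] <- loss_of(Y)
  for (e in seq_len(epochs)) {
    # backprop of mean((Y - X)^2)
    dY <- 2 * (Y - Xt) / length(Y)
    dZ2 <- dY * (Z2 > 0)
    gWd <- dZ2 %*% t(H); gq <- rowSums(dZ2)
    dH <- t(Wd) %*% dZ2
    dZ1 <- dH * (Z1 > 0)
    gW <- dZ1 %*% X; gp <- rowSums(dZ1)
    W_old <- W; p_old <- p; Wd_old <- Wd; q_old <- q
    vW  <- mom * vW  - lr * gW;  W  <- W  + vW
    vp  <- mom * vp  - lr * gp;  p  <- p  + vp
    vWd <- mom * vWd - lr * gWd; Wd <- Wd + vWd
    vq  <- mom * vq  - lr * gq;  q  <- q  + vq
    Z1 <- W %*% Xt + p; H <- .relu(Z1)
    Z2 <- Wd %*% H + q; Y <- .relu(Z2)
    loss <- loss_of(Y)
    if (!is.finite(loss) || loss > trace[e] * 1.01 + 1e-12) {
      # overshoot: halve the step, drop momentum, retry from the last state
      lr <- lr / 2
      vW <- vW * 0; vp <- vp * 0; vWd <- vWd * 0; vq <- vq * 0
      W <- W_old; p <- p_old; Wd <- Wd_old; q <- q_old
      Z1 <- W %*% Xt + p; H <- .relu(Z1)
      Z2 <- Wd %*% H + q; Y <- .relu(Z2)
      loss <- loss_of(Y)
    }
    trace[e + 1L] <- loss
  }
  list(W = W, p = p, Wd = Wd, q = q, loss_trace = trace)
}

# Default stage sizing: inputs wider than 256 get an intermediate 256 stage.
sae_layer_dims <- function(d_in, d_out = 64L) {
  if (d_in > 256L) c(256L, d_out) else d_out
}

#' Train a stacked autoencoder
#'
#' Stages are trained greedily: the first autoencoder reconstructs `X`, each
#' later stage reconstructs the previous stage's hidden representation.
#' Both encoder and decoder use the rectifier activation.
#'
#' @param X numeric matrix, one raw attribute vector per row.
#' @param layer_dims integer vector of successive hidden dimensions ending in
#'   the target attribute dimension; default [sae_layer_dims()] of `ncol(X)`.
#' @param epochs gradient-descent epochs per stage.
#' @param learning_rate step size.
#' @param seed integer seed; training is reproducible under it.
#' @return an `sae_model`: list of stages plus `dims` and per-stage
#'   `loss_trace`s.
#' @export
sae_train <- function(X, layer_dims = NULL, epochs = 200L,
                      learning_rate = 0.05, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in autoencoder input")
  if (is.null(layer_dims)) layer_dims <- sae_layer_dims(ncol(X))
  stages <- local_seed(seed, {
    cur <- X
    lapply(layer_dims, function(dh) {
      st <- .train_stage(cur, dh, epochs, learning_rate)
      cur <<- t(.relu(st$W %*% t(cur) + st$p))
      st
    })
  })
  structure(list(stages = stages,
                 dims = c(ncol(X), as.integer(layer_dims))),
            class = "sae_model")
}

#' Encode vectors with a trained stacked autoencoder
#'
#' @param model an `sae_model`.
#' @param x a numeric vector of the model's input dimension, or a matrix with
#'   one such vector per row.
#' @return encoded vector (or matrix of encoded rows) of the final stage
#'   dimension; entries are non-negative (rectifier).
#' @export
sae_encode <- function(model, x) {
  stopifnot(inherits(model, "sae_model"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$dims[1L]) {
    stop("input dimension ", ncol(X), " does not match model input dimension ",
         model$dims[1L])
  }
  H <- t(X)
  for (st in model$stages) H <- .relu(st$W %*% H + st$p)
  out <- t(H)
  rownames(out) <- rownames(X)
  if (vec) drop(out) else out
}

#' Reconstruction error of a stacked autoencoder
#'
#' Mean squared error between `X` and its decode(encode(X)) reconstruction
#' through all stages.
#'
#' @param model an `sae_model`.
#' @param X matrix of raw vectors (rows).
#' @return a single number.
#' @export
sae_reconstruction_error <- function(model, X) {
  X <- as.matrix(X)
  H <- t(X)
  hs <- list(H)
  for (st in model$stages) {
    H <- .relu(st$W %*% H + st$p)
    hs[[length(hs) + 1L]] <- H
  }
  for (i in rev(seq_along(model$stages))) {
    st <- model$stages[[i]]
    H <- .relu(st$Wd %*% H + st$q)
  }
  mean((H - t(X))^2)
}
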