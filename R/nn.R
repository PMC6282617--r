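## Minimal feed-forward network engine used by the counting model.
##
## Image batches are (H, W, C, N) arrays, feature batches (N, D) matrices.
## Layers are mutable environments exposing forward()/backward() closures;
## parameters live in the layer environment together with their gradients
## ("d" prefix) and Adam moments ("m"/"v" prefix).  The convolution hot
## path (im2col/col2im) is compiled; matrix products go through BLAS.

new_layer <- function(type, param_names = character(0)) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$param_names <- param_names
  l$sublayers <- list()
  l
}

#' @useDynLib leafcounter, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

nn_conv <- function(k, cin, cout, stride = 1L, pad = k %/% 2L) {
  l <- new_layer("conv", c("W", "b"))
  l$k <- as.integer(k); l$cin <- as.integer(cin); l$cout <- as.integer(cout)
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  sd <- sqrt(2 / (k * k * cin))  # He initialization for ReLU nets
  l$W <- array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout))
  l$b <- numeric(cout)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    l$in_dim <- d
    cols <- im2col_hwcn(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    hout <- (d[1] + 2 * l$pad - l$k) %/% l$stride + 1L
    wout <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1L
    y <- cols %*% matrix(l$W, ncol = l$cout)
    y <- sweep(y, 2, l$b, "+")
    if (training) l$cols <- cols else l$cols <- NULL
    aperm(array(y, c(hout, wout, d[4], l$cout)), c(1, 2, 4, 3))
  }
  l$backward <- function(dy) {
    d <- dim(dy)  # (hout, wout, cout, N)
    dm <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = l$cout)
    l$dW <- array(crossprod(l$cols, dm), dim(l$W))
    l$db <- colSums(dm)
    dcols <- dm %*% t(matrix(l$W, ncol = l$cout))
    id <- l$in_dim
    l$cols <- NULL
    col2im_hwcn(dcols, id[1], id[2], id[3], id[4], l$k, l$stride, l$pad)
  }
  l
}

nn_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, training = FALSE) {
    if (training) l$mask <- x > 0
    x * (x > 0)
  }
  l$backward <- function(dy) {
    dx <- dy * l$mask
    l$mask <- NULL
    dx
  }
  l
}

## Per-channel affine y = gamma * x + beta on (H, W, C, N) arrays.  Plays
## the role of batch norm with frozen running statistics (the fine-tuning
## regime): the normalization is absorbed, scale and shift stay trainable.
nn_channel_affine <- function(c) {
  l <- new_layer("channel_affine", c("gamma", "beta"))
  l$c <- as.integer(c)
  l$gamma <- rep(1, c)
  l$beta <- rep(0, c)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    g <- rep(l$gamma, each = d[1] * d[2])
    b <- rep(l$beta, each = d[1] * d[2])
    if (training) l$x <- x
    x * g + b
  }
  l$backward <- function(dy) {
    d <- dim(dy)
    hw <- d[1] * d[2]
    ## gradients summed over H, W and N per channel
    l$dgamma <- colSums(matrix(rowSums(matrix(dy * l$x, ncol = d[4])), nrow = hw))
    l$dbeta <- colSums(matrix(rowSums(matrix(dy, ncol = d[4])), nrow = hw))
    dx <- dy * rep(l$gamma, each = hw)
    l$x <- NULL
    dx
  }
  l
}

nn_maxpool <- function(k, stride, pad = 0L) {
  l <- new_layer("maxpool")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    r <- maxpool_hwcn(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    if (training) {
      l$argmax <- r$argmax
      l$in_dim <- d
    }
    r$y
  }
  l$backward <- function(dy) {
    dx <- numeric(prod(l$in_dim))
    idx <- as.vector(l$argmax)
    g <- as.vector(dy)
    agg <- rowsum(g, idx)
    dx[as.integer(rownames(agg))] <- agg
    dim(dx) <- l$in_dim
    l$argmax <- NULL
    dx
  }
  l
}

## Global average pooling: (H, W, C, N) -> (N, C).
nn_gap <- function() {
  l <- new_layer("gap")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    l$in_dim <- d
    m <- colMeans(matrix(x, nrow = d[1] * d[2]))  # length C*N
    t(matrix(m, nrow = d[3]))
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    per <- t(dy) / (d[1] * d[2])  # (C, N)
    array(rep(as.vector(per), each = d[1] * d[2]), d)
  }
  l
}

nn_dense <- function(nin, nout) {
  l <- new_layer("dense", c("W", "b"))
  sd <- sqrt(2 / nin)
  l$W <- matrix(stats::rnorm(nin * nout, 0, sd), nin, nout)
  l$b <- numeric(nout)
  l$forward <- function(x, training = FALSE) {
    if (training) l$x <- x
    sweep(x %*% l$W, 2, l$b, "+")
  }
  l$backward <- function(dy) {
    l$dW <- crossprod(l$x, dy)
    l$db <- colSums(dy)
    dx <- dy %*% t(l$W)
    l$x <- NULL
    dx
  }
  l
}

## Residual block: y = relu(main(x) + skip(x)); skip = list() is identity.
nn_residual <- function(main, skip = list()) {
  l <- new_layer("residual")
  l$sublayers <- c(main, skip)
  l$main <- main
  l$skip <- skip
  l$forward <- function(x, training = FALSE) {
    a <- seq_forward(l$main, x, training)
    s <- if (length(l$skip)) seq_forward(l$skip, x, training) else x
    y <- a + s
    if (training) l$mask <- y > 0
    y <- y * (y > 0)
    l$last_output <- y
    y
  }
  l$backward <- function(dy) {
    dy <- dy * l$mask
    l$mask <- NULL
    da <- seq_backward(l$main, dy)
    ds <- if (length(l$skip)) seq_backward(l$skip, dy) else dy
    da + ds
  }
  l
}

seq_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- l$forward(x, training)
  x
}

seq_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$backward(dy)
  dy
}

## Depth-first flattening of composite layers into parameter-carrying leaves.
flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (length(l$sublayers)) out <- c(out, flatten_layers(l$sublayers))
    if (length(l$param_names)) out <- c(out, list(l))
  }
  out
}

layer_weights <- function(layers) {
  lapply(flatten_layers(layers), function(l) {
    mget(l$param_names, envir = l)
  })
}

set_layer_weights <- function(layers, weights) {
  flat <- flatten_layers(layers)
  stopifnot(length(flat) == length(weights))
  for (i in seq_along(flat)) {
    for (p in flat[[i]]$param_names) {
      stopifnot(identical(dim(flat[[i]][[p]]), dim(weights[[i]][[p]])),
                length(flat[[i]][[p]]) == length(weights[[i]][[p]]))
      assign(p, weights[[i]][[p]], envir = flat[[i]])
    }
  }
  invisible(layers)
}

## One Adam update over all parameters that have gradients.
adam_step <- function(layers, lr, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in flatten_layers(layers)) {
    for (p in l$param_names) {
      g <- l[[paste0("d", p)]]
      if (is.null(g)) next
      mkey <- paste0("m_", p); vkey <- paste0("v_", p)
      if (is.null(l[[mkey]])) {
        l[[mkey]] <- g * 0
        l[[vkey]] <- g * 0
      }
      l[[mkey]] <- beta1 * l[[mkey]] + (1 - beta1) * g
      l[[vkey]] <- beta2 * l[[vkey]] + (1 - beta2) * g * g
      mhat <- l[[mkey]] / (1 - beta1^step)
      vhat <- l[[vkey]] / (1 - beta2^step)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(layers)
}

clear_grads <- function(layers) {
  for (l in flatten_layers(layers)) {
    for (p in l$param_names) l[[paste0("d", p)]] <- NULL
  }
  invisible(layers)
}

reset_optimizer_state <- function(layers) {
  for (l in flatten_layers(layers)) {
    for (p in l$param_names) {
      l[[paste0("m_", p)]] <- NULL
      l[[paste0("v_", p)]] <- NULL
    }
  }
  invisible(layers)
}
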