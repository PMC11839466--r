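# Minimal neural-network toolkit on base-R BLAS matrix ops.
#
# All models in this package (bias CNN, dispersion MLP, TF/nucleosome
# classifiers, the sequence-to-footprint trunk) are small enough that
# im2col + %*% on an optimized BLAS is fast at the problem sizes used here.
# Gradients are hand-derived and verified against finite differences in the
# test suite. Layout convention for sequence data: a batch of B sequences of
# length L with C channels is a (B*L) x C matrix, rows grouped by sequence.

## ---- activations -----------------------------------------------------------

nn_relu <- function(x) (x > 0) * x
nn_relu_grad <- function(x) (x > 0) * 1

# exact GELU: x * Phi(x)
nn_gelu <- function(x) x * stats::pnorm(x)
nn_gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_act <- function(x, act) {
  switch(act,
    linear = x,
    relu = nn_relu(x),
    gelu = nn_gelu(x),
    sigmoid = nn_sigmoid(x),
    stop("unknown activation: ", act)
  )
}

nn_act_grad <- function(x, act) {
  switch(act,
    linear = array(1, dim(x) %||% length(x)),
    relu = nn_relu_grad(x),
    gelu = nn_gelu_grad(x),
    sigmoid = {
      s <- nn_sigmoid(x)
      s * (1 - s)
    },
    stop("unknown activation: ", act)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- parameter initialisation ---------------------------------------------

# He-style fan-in scaling; callers control the RNG stream via set.seed.
nn_init_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

## ---- Adam ------------------------------------------------------------------

# params/grads are arbitrary nested lists of numeric arrays with identical
# structure. State mirrors that structure.

nn_walk2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nn_walk2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

nn_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, nn_zeros_like) else p * 0
}

nn_adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_walk2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- nn_walk2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- nn_walk2(params, mh, function(p, u) p - lr * u)
  list(params = params, state = state)
}

## ---- dense layers / MLP -----------------------------------------------------

nn_mlp_init <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = nn_init_mat(dims[i], dims[i + 1L]),
                        b = rep(0, dims[i + 1L]))
  }
  # small head init: the output starts near zero, which is exactly optimal
  # for standardized targets and removes a long constant-offset transient
  layers[[length(layers)]]$W <- layers[[length(layers)]]$W * 0.05
  layers
}

# forward pass; returns pre-activations for backward. Dropout is inverted
# dropout applied to hidden activations during training only.
nn_mlp_forward <- function(layers, X, act = "relu", out_act = "linear",
                           dropout = 0, training = FALSE) {
  n_layer <- length(layers)
  pre <- vector("list", n_layer)
  post <- vector("list", n_layer + 1L)
  masks <- vector("list", n_layer)
  post[[1L]] <- X
  for (i in seq_len(n_layer)) {
    z <- post[[i]] %*% layers[[i]]$W
    z <- sweep(z, 2L, layers[[i]]$b, "+")
    pre[[i]] <- z
    a_i <- if (i < n_layer) act else out_act
    h <- nn_act(z, a_i)
    if (training && dropout > 0 && i < n_layer) {
      m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h)) /
        (1 - dropout)
      h <- h * m
      masks[[i]] <- m
    }
    post[[i + 1L]] <- h
  }
  list(out = post[[n_layer + 1L]], pre = pre, post = post, masks = masks)
}

# dOut is the gradient of the loss w.r.t. the network output (post out_act).
nn_mlp_backward <- function(layers, fwd, dOut, act = "relu",
                            out_act = "linear") {
  n_layer <- length(layers)
  grads <- vector("list", n_layer)
  g <- dOut
  for (i in rev(seq_len(n_layer))) {
    a_i <- if (i < n_layer) act else out_act
    if (i < n_layer && !is.null(fwd$masks[[i]])) g <- g * fwd$masks[[i]]
    g <- g * nn_act_grad(fwd$pre[[i]], a_i)
    grads[[i]] <- list(W = crossprod(fwd$post[[i]], g), b = colSums(g))
    if (i > 1L) g <- g %*% t(layers[[i]]$W)
  }
  grads
}

# Shortcut for losses with a canonical pre-activation gradient:
# MSE + linear head or BCE + sigmoid head both give (out - y) / n.
nn_mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$norm)) {
    X <- sweep(sweep(X, 2L, model$norm$mu, "-"), 2L, model$norm$sd, "/")
  }
  nn_mlp_forward(model$layers, X, act = model$act, out_act = model$out_act)$out
}

#' Fit a small fully connected network
#'
#' Generic trainer used by the dispersion model and the TF and nucleosome
#' predictors: Adam, mini-batches, early stopping on validation loss, with
#' the best-validation weights restored at the end. Supported losses are
#' mean squared error (linear output) and binary cross-entropy (sigmoid
#' output); for both, the gradient at the output pre-activation is
#' (prediction - target) / n, which is what the backward pass uses.
#'
#' @param X,Y numeric matrices of inputs and targets (rows = examples).
#' @param hidden integer vector of hidden-layer widths.
#' @param loss "mse" or "bce".
#' @param act hidden activation ("relu" or "gelu").
#' @param dropout hidden-layer dropout rate during training.
#' @param batch,epochs,patience,lr,lr_decay optimisation controls
#'   (`lr_decay` shrinks the learning rate per epoch, damping Adam's
#'   late-stage parameter jitter).
#' @param val_idx indices of rows held out for early stopping; default a
#'   seeded 10 percent sample.
#' @param standardize standardize inputs with training statistics (stored in
#'   the model and applied by [nn_mlp_predict()]).
#' @param seed RNG seed controlling initialisation, batching and dropout.
#' @return a model list with elements `layers`, `act`, `out_act`, `norm`,
#'   `val_loss`, `epochs_run`.
#' @keywords internal
nn_fit_mlp <- function(X, Y, hidden, loss = c("mse", "bce"), act = "relu",
                       dropout = 0, batch = 64, epochs = 200, patience = 8,
                       lr = 1e-3, lr_decay = 1, val_idx = NULL,
                       standardize = FALSE, seed = 1) {
  loss <- match.arg(loss)
  out_act <- if (loss == "bce") "sigmoid" else "linear"
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  set.seed(seed)
  norm <- NULL
  if (standardize) {
    mu <- colMeans(X)
    sd <- apply(X, 2L, stats::sd)
    sd[sd < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
    norm <- list(mu = mu, sd = sd)
  }
  n <- nrow(X)
  if (is.null(val_idx)) {
    val_idx <- sample.int(n, max(1L, round(0.1 * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("no training rows left after validation split")
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  layers <- nn_mlp_init(ncol(X), hidden, ncol(Y))
  opt <- nn_adam_init(layers)
  eval_loss <- function(layers, Xe, Ye) {
    out <- nn_mlp_forward(layers, Xe, act = act, out_act = out_act)$out
    if (loss == "mse") {
      mean((out - Ye)^2)
    } else {
      eps <- 1e-7
      -mean(Ye * log(out + eps) + (1 - Ye) * log(1 - out + eps))
    }
  }
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  wait <- 0L
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    lr_ep <- lr * lr_decay^(ep - 1L)
    for (start in seq(1L, ntr, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, ntr)]
      xb <- Xtr[idx, , drop = FALSE]
      yb <- Ytr[idx, , drop = FALSE]
      fwd <- nn_mlp_forward(layers, xb, act = act, out_act = out_act,
                            dropout = dropout, training = TRUE)
      # (pred - y)/n is d(loss)/d(pre-activation) for both supported losses;
      # divide by the activation gradient so nn_mlp_backward can re-apply it.
      gpre <- (fwd$out - yb) / length(yb)
      dOut <- if (out_act == "sigmoid") {
        s <- fwd$out
        gpre / pmax(s * (1 - s), 1e-12)
      } else {
        gpre
      }
      grads <- nn_mlp_backward(layers, fwd, dOut, act = act, out_act = out_act)
      res <- nn_adam_step(layers, grads, opt, lr = lr_ep)
      layers <- res$params; opt <- res$state
    }
    vl <- eval_loss(layers, Xva, Yva)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, layers = layers, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(layers = best$layers, act = act, out_act = out_act, norm = norm,
       val_loss = best$loss, epochs_run = ep)
}

## ---- 1-D convolution via im2col --------------------------------------------

# Row-index map for a same-padded dilated conv: L x k matrix, entry (p, j) is
# the input position feeding tap j at output position p, or 0 for padding.
nn_conv_index <- function(L, k, dilation = 1L) {
  offs <- (seq_len(k) - (k + 1) / 2) * dilation
  idx <- outer(seq_len(L), offs, "+")
  idx[idx < 1 | idx > L] <- 0L
  storage.mode(idx) <- "integer"
  idx
}

# expand to a batch of B sequences laid out as (B*L) rows; 0 stays 0.
# Cached: the map depends only on (B, L, k, dilation) and is rebuilt
# thousands of times during training otherwise.
.conv_rows_cache <- new.env(parent = emptyenv())

nn_conv_rows <- function(B, L, k, dilation = 1L) {
  key <- paste(B, L, k, dilation, sep = "_")
  hit <- .conv_rows_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- nn_conv_index(L, k, dilation)
  idxrep <- idx[rep(seq_len(L), B), , drop = FALSE]
  off <- rep((seq_len(B) - 1L) * L, each = L)
  out <- idxrep + off * (idxrep > 0L)
  .conv_rows_cache[[key]] <- out
  out
}

# X: (B*L) x Cin. W: (k*Cin_g) x Cout with output channels ordered by group
# (weight rows are tap-major: tap 1 channels of the group, tap 2 channels...).
# The im2col gather, the GEMMs and the backward scatter run in compiled code
# (src/conv1d.cpp); the returned `cols` cube is kept for the backward pass.
nn_conv1d_forward <- function(X, B, L, W, b, k, dilation = 1L, groups = 1L,
                              rows = NULL) {
  stopifnot(ncol(X) %% groups == 0L, ncol(W) %% groups == 0L)
  if (is.null(rows)) rows <- nn_conv_rows(B, L, k, dilation)
  res <- conv1d_fwd_cpp(X, rows, W, as.numeric(b), as.integer(groups))
  list(out = res$out, cols = res$cols, rows = rows)
}

nn_conv1d_backward <- function(X, fwd, dOut, W, k, dilation = 1L,
                               groups = 1L) {
  res <- conv1d_bwd_cpp(X, fwd$cols, fwd$rows, W, dOut,
                        as.integer(groups))
  list(dX = res$dX, dW = res$dW, db = as.numeric(res$db))
}

## ---- max pooling (width 2, stride 2) ---------------------------------------

nn_maxpool2_forward <- function(X, B, L) {
  Lp <- L %/% 2L
  i1 <- 2L * seq_len(Lp) - 1L
  rowsA <- rep((seq_len(B) - 1L) * L, each = Lp) + i1
  rowsB <- rowsA + 1L
  A <- X[rowsA, , drop = FALSE]
  Bm <- X[rowsB, , drop = FALSE]
  mask <- A >= Bm
  list(out = pmax(A, Bm), mask = mask, rowsA = rowsA, rowsB = rowsB,
       Lp = Lp, L = L, B = B)
}

nn_maxpool2_backward <- function(X, fwd, dOut) {
  dX <- X * 0
  dX[fwd$rowsA, ] <- dOut * fwd$mask
  dX[fwd$rowsB, ] <- dOut * (!fwd$mask)
  dX
}

## ---- batch normalisation (per channel over all rows) ------------------------

nn_bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

nn_bn_forward <- function(bn, X, training = TRUE, momentum = 0.9,
                          eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu, "-")
    v <- colMeans(xc^2)
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
    xc <- sweep(X, 2L, mu, "-")
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(out = out, xhat = xhat, inv = inv, bn = bn, training = training)
}

nn_bn_backward <- function(fwd, dOut, gamma) {
  dgamma <- colSums(dOut * fwd$xhat)
  dbeta <- colSums(dOut)
  if (fwd$training) {
    n <- nrow(dOut)
    t1 <- sweep(dOut, 2L, colMeans(dOut), "-")
    t2 <- sweep(fwd$xhat, 2L, colMeans(dOut * fwd$xhat), "*")
    dX <- sweep(t1 - t2, 2L, gamma * fwd$inv, "*")
  } else {
    dX <- sweep(dOut, 2L, gamma * fwd$inv, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- utilities ---------------------------------------------------------------

# one-hot encode an A/C/G/T/N string into an L x 4 matrix (N rows are zero)
nn_one_hot <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- matrix(0, length(chars), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  hit <- match(chars, c("A", "C", "G", "T"))
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

# rank-based AUROC (Mann-Whitney); used for quick internal checks
nn_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
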