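# Tn5 sequence-bias modelling.
#
# The transposase's insertion rate depends strongly on the local sequence.
# On deproteinized (naked) DNA the observed relative insertion rate is pure
# bias, so a model trained there can later divide bias out of chromatin data.
# Target definition: raw insertion count at a position divided by the mean
# count in a +/-50-bp window, log10-transformed and affinely standardized
# (the standardization parameters are stored in the model for exact
# inversion). The model input is the +/-50-bp sequence context, one-hot
# encoded as a 101 x 4 matrix.

BIAS_WINDOW <- 50L   # +/- window for both the sequence input and local mean

# encode a batch of base-code rows (n x 101, codes 1..4, 0 = N) as one-hot
bias_one_hot <- function(codes) {
  n <- nrow(codes); L <- ncol(codes)
  X <- matrix(0, n * L, 4L)
  flat <- as.vector(t(codes))          # row-major: batch-grouped rows
  ok <- flat > 0L
  X[cbind(which(ok), flat[ok])] <- 1
  X
}

seq_to_codes <- function(seq) {
  chartr("ACGTN", "12340", toupper(seq)) |>
    strsplit("") |>
    (\(x) as.integer(x[[1]]))()
}

rc_codes <- function(codes) {
  out <- 5L - codes[, rev(seq_len(ncol(codes))), drop = FALSE]
  out[out == 5L] <- 0L
  out
}

#' Prepare Tn5-bias training examples from naked-DNA insertion counts
#'
#' Relative bias at a position is its insertion count divided by the mean
#' count within +/-50 bp; positions whose local mean is below
#' `coverage_min` (default 20 insertions per bp) are removed, as are
#' positions within 50 bp of a contig end and positions with zero count
#' (log-undefined). Targets are log10-transformed and standardized to zero
#' mean / unit variance on the training set. Contigs are split 80/10/10 so
#' no source contig spans partitions. Training examples are binned into five
#' equal-range bias bins and upsampled to the largest bin's size, then
#' reverse-complement copies are appended.
#'
#' @param counts list of per-bp insertion count vectors, named by contig.
#' @param genome named character vector of contig sequences.
#' @param coverage_min minimum local mean coverage (insertions/bp).
#' @param n_bins number of equal-range target bins for upsampling.
#' @param max_per_contig optional cap on eligible positions sampled per
#'   contig (keeps training tractable on deep simulations).
#' @param seed RNG seed (contig split, position sampling, upsampling).
#' @return list with `train`, `val`, `test` (each `codes` n x 101 integer
#'   matrix and `y` standardized log10 target), `transform` (mu, sd) and
#'   `split` (contig assignment).
#' @export
prepare_bias_training_data <- function(counts, genome, coverage_min = 20,
                                       n_bins = 5, max_per_contig = NULL,
                                       seed = 1) {
  stopifnot(all(names(counts) %in% names(genome)))
  set.seed(seed)
  W <- BIAS_WINDOW
  per_contig <- lapply(names(counts), function(ctg) {
    cnt <- counts[[ctg]]
    L <- length(cnt)
    local_mean <- stats::filter(cnt, rep(1 / (2 * W + 1), 2 * W + 1),
                                sides = 2)
    ok <- !is.na(local_mean) & local_mean >= coverage_min & cnt > 0
    pos <- which(ok)
    pos <- pos[pos > W & pos <= L - W]
    if (length(pos) == 0L) return(NULL)
    if (!is.null(max_per_contig) && length(pos) > max_per_contig) {
      pos <- sort(sample(pos, max_per_contig))
    }
    data.frame(contig = ctg, pos = pos,
               y = log10(cnt[pos] / local_mean[pos]))
  })
  per_contig <- Filter(Negate(is.null), per_contig)
  if (length(per_contig) == 0L) {
    stop("no position passes the coverage filter; simulate or sequence deeper")
  }
  ex <- do.call(rbind, per_contig)
  ctgs <- unique(ex$contig)
  ord <- sample(ctgs)
  n <- length(ord)
  n_tr <- max(1L, round(0.8 * n))
  n_va <- max(1L, min(n - n_tr - 1L, round(0.1 * n)))
  if (n < 3L) stop("need >= 3 contigs for an 80/10/10 contig-level split")
  split <- list(train = ord[seq_len(n_tr)],
                val = ord[n_tr + seq_len(n_va)],
                test = ord[(n_tr + n_va + 1L):n])
  codes_of <- function(df) {
    t(vapply(seq_len(nrow(df)), function(i) {
      s <- substr(genome[[df$contig[i]]], df$pos[i] - W, df$pos[i] + W)
      seq_to_codes(s)
    }, integer(2L * W + 1L)))
  }
  mk <- function(part) {
    df <- ex[ex$contig %in% split[[part]], ]
    list(codes = codes_of(df), y = df$y, contig = df$contig)
  }
  sets <- list(train = mk("train"), val = mk("val"), test = mk("test"))
  mu <- mean(sets$train$y)
  sd <- stats::sd(sets$train$y)
  if (!is.finite(sd) || sd < 1e-12) {
    stop("constant bias targets; cannot standardize or fit")
  }
  for (p in names(sets)) sets[[p]]$y <- (sets[[p]]$y - mu) / sd

  # equal-range binning + upsampling to the largest bin, training set only.
  # The bin range spans the 1st-99th percentile of the targets (values
  # outside fall into the end bins): single extreme-noise positions must
  # not define the range, or the tail bins degenerate to a few unique
  # examples that upsampling then duplicates massively.
  tr <- sets$train
  qr <- stats::quantile(tr$y, c(0.01, 0.99), names = FALSE)
  br <- seq(qr[1], qr[2], length.out = n_bins + 1L)
  br[1] <- -Inf
  br[n_bins + 1L] <- Inf
  bin <- cut(tr$y, breaks = br, labels = FALSE)
  tab <- table(factor(bin, levels = seq_len(n_bins)))
  target_n <- max(tab)
  idx <- unlist(lapply(seq_len(n_bins), function(b) {
    ib <- which(bin == b)
    if (length(ib) == 0L) return(integer())
    c(ib, sample(ib, target_n - length(ib), replace = TRUE))
  }))
  codes <- tr$codes[idx, , drop = FALSE]
  y <- tr$y[idx]
  codes <- rbind(codes, rc_codes(codes))   # reverse-complement augmentation
  y <- c(y, y)
  sh <- sample.int(length(y))
  sets$train <- list(codes = codes[sh, , drop = FALSE], y = y[sh])
  list(train = sets$train, val = sets$val, test = sets$test,
       transform = list(mu = mu, sd = sd), split = split)
}

## ---- CNN --------------------------------------------------------------------

bias_cnn_init <- function(n_filters = 32L, width = 5L) {
  list(
    c1 = list(W = nn_init_mat(width * 4L, n_filters), b = rep(0, n_filters)),
    c2 = list(W = nn_init_mat(width * n_filters, n_filters),
              b = rep(0, n_filters)),
    c3 = list(W = nn_init_mat(width * n_filters, n_filters),
              b = rep(0, n_filters)),
    d1 = list(W = nn_init_mat(12L * n_filters, 32L), b = rep(0, 32L)),
    d2 = list(W = nn_init_mat(32L, 1L), b = 0)
  )
}

# forward pass over a batch of code rows; returns prediction and caches.
# `X` may be passed pre-encoded ((B*101) x 4) to skip the one-hot step.
bias_cnn_forward <- function(params, codes, X = NULL) {
  B <- nrow(codes)
  L1 <- ncol(codes)                       # 101
  if (is.null(X)) X <- bias_one_hot(codes)
  f1 <- nn_conv1d_forward(X, B, L1, params$c1$W, params$c1$b, k = 5L)
  a1 <- nn_relu(f1$out)
  p1 <- nn_maxpool2_forward(a1, B, L1)    # 50
  f2 <- nn_conv1d_forward(p1$out, B, p1$Lp, params$c2$W, params$c2$b, k = 5L)
  a2 <- nn_relu(f2$out)
  p2 <- nn_maxpool2_forward(a2, B, p1$Lp) # 25
  f3 <- nn_conv1d_forward(p2$out, B, p2$Lp, params$c3$W, params$c3$b, k = 5L)
  a3 <- nn_relu(f3$out)
  p3 <- nn_maxpool2_forward(a3, B, p2$Lp) # 12
  C <- ncol(p3$out)
  Fl <- matrix(0, B, p3$Lp * C)
  for (b in seq_len(B)) {
    Fl[b, ] <- as.vector(p3$out[(b - 1L) * p3$Lp + seq_len(p3$Lp), ])
  }
  z1 <- sweep(Fl %*% params$d1$W, 2L, params$d1$b, "+")
  h1 <- nn_relu(z1)
  out <- as.vector(h1 %*% params$d2$W + params$d2$b)
  list(out = out, X = X, f1 = f1, a1 = a1, p1 = p1, f2 = f2, a2 = a2,
       p2 = p2, f3 = f3, a3 = a3, p3 = p3, Fl = Fl, z1 = z1, h1 = h1,
       B = B, L1 = L1)
}

bias_cnn_backward <- function(params, fwd, dOut) {
  B <- fwd$B
  g2 <- matrix(dOut, ncol = 1L)
  dd2 <- list(W = crossprod(fwd$h1, g2), b = sum(g2))
  gh1 <- g2 %*% t(params$d2$W)
  gz1 <- gh1 * nn_relu_grad(fwd$z1)
  dd1 <- list(W = crossprod(fwd$Fl, gz1), b = colSums(gz1))
  gFl <- gz1 %*% t(params$d1$W)
  Lp3 <- fwd$p3$Lp
  C <- ncol(fwd$p3$out)
  gP3 <- matrix(0, B * Lp3, C)
  for (b in seq_len(B)) {
    gP3[(b - 1L) * Lp3 + seq_len(Lp3), ] <- matrix(gFl[b, ], Lp3, C)
  }
  ga3 <- nn_maxpool2_backward(fwd$a3, fwd$p3, gP3)
  gf3 <- ga3 * nn_relu_grad(fwd$f3$out)
  b3 <- nn_conv1d_backward(fwd$p2$out, fwd$f3, gf3, params$c3$W, k = 5L)
  ga2 <- nn_maxpool2_backward(fwd$a2, fwd$p2, b3$dX)
  gf2 <- ga2 * nn_relu_grad(fwd$f2$out)
  b2 <- nn_conv1d_backward(fwd$p1$out, fwd$f2, gf2, params$c2$W, k = 5L)
  ga1 <- nn_maxpool2_backward(fwd$a1, fwd$p1, b2$dX)
  gf1 <- ga1 * nn_relu_grad(fwd$f1$out)
  b1 <- nn_conv1d_backward(fwd$X, fwd$f1, gf1, params$c1$W, k = 5L)
  list(c1 = list(W = b1$dW, b = b1$db),
       c2 = list(W = b2$dW, b = b2$db),
       c3 = list(W = b3$dW, b = b3$db),
       d1 = dd1, d2 = dd2)
}

#' Fit the Tn5 bias CNN
#'
#' Architecture: three convolution + max-pooling stages (32 filters of width
#' 5, 'same' padding, stride 1, ReLU; pool width 2), a fully connected layer
#' of 32 units with ReLU, and a linear scalar output. Mean-squared-error
#' loss, Adam with default hyperparameters, batch size 64, early stopping on
#' validation loss with best-weights restoration.
#'
#' @param prep output of [prepare_bias_training_data()].
#' @param epochs,patience,batch,lr,lr_decay optimisation controls
#'   (`lr_decay` shrinks the learning rate per epoch).
#' @param seed RNG seed; fixed seed gives reproducible weights in
#'   single-threaded BLAS execution.
#' @return a `BiasModel` (parameters + stored target transform).
#' @export
fit_bias_model <- function(prep, epochs = 40, patience = 6, batch = 64,
                           lr = 2e-3, lr_decay = 0.94, seed = 1) {
  if (stats::sd(prep$train$y) < 1e-12) {
    stop("constant training targets: bias model cannot be fitted ",
         "(correlation undefined)")
  }
  set.seed(seed)
  params <- bias_cnn_init()
  opt <- nn_adam_init(params)
  Xtr <- prep$train$codes; ytr <- prep$train$y
  Xva <- prep$val$codes; yva <- prep$val$y
  n <- nrow(Xtr)
  val_mse <- function(params) {
    preds <- bias_cnn_predict_std(params, Xva, batch = 256L)
    mean((preds - yva)^2)
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  onehot_all <- bias_one_hot(Xtr)         # encoded once, sliced per batch
  L1 <- ncol(Xtr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    lr_ep <- lr * lr_decay^(ep - 1L)
    for (s in seq(1L, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      rows <- rep((idx - 1L) * L1, each = L1) + seq_len(L1)
      fwd <- bias_cnn_forward(params, Xtr[idx, , drop = FALSE],
                              X = onehot_all[rows, , drop = FALSE])
      dOut <- 2 * (fwd$out - ytr[idx]) / length(idx)
      grads <- bias_cnn_backward(params, fwd, dOut)
      res <- nn_adam_step(params, grads, opt, lr = lr_ep)
      params <- res$params; opt <- res$state
    }
    vl <- val_mse(params)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = ep); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(params = best$params, transform = prep$transform,
                 arch = list(n_filters = 32L, width = 5L, input = 101L),
                 val_loss = best$loss, epochs_run = ep),
            class = "BiasModel")
}

#' @export
print.BiasModel <- function(x, ...) {
  cat("BiasModel: 3x(conv 32x5 + maxpool) + FC(32) + linear;",
      "input 101 bp; val MSE", signif(x$val_loss, 4), "\n")
  invisible(x)
}

# standardized-scale predictions for a matrix of code rows
bias_cnn_predict_std <- function(params, codes, batch = 256L) {
  n <- nrow(codes)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    out[idx] <- bias_cnn_forward(params, codes[idx, , drop = FALSE])$out
  }
  out
}

#' Predict a per-bp Tn5 bias track for a contig
#'
#' Each position is predicted from its +/-50-bp one-hot window; windows
#' overrunning the contig ends are zero-padded (N channel). The stored
#' affine/log10 transform is inverted, so values are positive relative
#' multipliers.
#'
#' @param model a `BiasModel`.
#' @param seq contig sequence (string).
#' @param positions 1-based positions to predict (default all).
#' @return numeric vector of positive bias multipliers.
#' @export
predict_bias_track <- function(model, seq, positions = NULL) {
  L <- nchar(seq)
  if (L < 1L) stop("sequence must be at least 1 bp")
  if (is.null(positions)) positions <- seq_len(L)
  W <- BIAS_WINDOW
  codes_full <- seq_to_codes(seq)
  codes <- t(vapply(positions, function(p) {
    lo <- p - W; hi <- p + W
    pad_l <- max(0L, 1L - lo); pad_r <- max(0L, hi - L)
    c(rep(0L, pad_l), codes_full[max(1L, lo):min(L, hi)], rep(0L, pad_r))
  }, integer(2L * W + 1L)))
  z <- bias_cnn_predict_std(model$params, codes)
  10^(z * model$transform$sd + model$transform$mu)
}

## ---- baselines --------------------------------------------------------------

#' k-mer and single-nucleotide-PWM Tn5 bias baselines
#'
#' k-mer mode: bias of a k-mer is its count-weighted frequency centred at
#' insertion events divided by its frequency over all positions; the track
#' is a per-position table lookup. pwm21 mode: per-base foreground /
#' background frequency log-ratios over a +/-10-bp window (21 bp total),
#' summed per position and exponentiated to a positive multiplier.
#'
#' @param counts list of per-bp insertion counts per contig (naked DNA).
#' @param genome named character vector of contig sequences.
#' @param mode "kmer" or "pwm21".
#' @param k k-mer size (3, 5 or 7) for kmer mode.
#' @param contigs contigs used for estimation (default all).
#' @return list with `model` (named bias table, or 4 x 21 log-ratio matrix)
#'   and `predict(seq)` returning a per-bp track.
#' @export
baseline_bias <- function(counts, genome, mode = c("kmer", "pwm21"), k = 3,
                          contigs = names(counts)) {
  mode <- match.arg(mode)
  if (mode == "kmer") {
    stopifnot(k %in% c(3, 5, 7))
    flank <- (k - 1L) %/% 2L
    fg_all <- numeric(0); bg_all <- numeric(0)
    for (ctg in contigs) {
      s <- genome[[ctg]]
      L <- nchar(s)
      kv <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
      w <- counts[[ctg]][(flank + 1L):(L - flank)]
      fg_t <- tapply(w, kv, sum)          # count-weighted, centred k-mers
      bg_t <- c(table(kv))                # all positions
      fg_all <- merge_sum(fg_all, fg_t)
      bg_all <- merge_sum(bg_all, bg_t)
    }
    fg_all <- fg_all / sum(fg_all)
    bg_all <- bg_all / sum(bg_all)
    km <- union(names(fg_all), names(bg_all))
    tab <- stats::setNames(rep(1, length(km)), km)
    known <- intersect(names(fg_all), names(bg_all))
    tab[known] <- fg_all[known] / bg_all[known]
    miss <- setdiff(km, known)
    if (length(miss)) {
      warning(length(miss), " k-mer(s) absent from fore- or background; ",
              "bias set to 1")
    }
    predict_fn <- function(seq) {
      L <- nchar(seq)
      kv <- substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
      b <- rep(NA_real_, L)
      v <- tab[kv]
      v[is.na(v)] <- 1
      b[(flank + 1L):(L - flank)] <- v
      b
    }
    list(model = tab, predict = predict_fn, mode = mode, k = k)
  } else {
    W <- 10L
    fg <- matrix(0, 4L, 2L * W + 1L,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
    bg <- rep(0, 4L); names(bg) <- rownames(fg)
    for (ctg in contigs) {
      codes <- seq_to_codes(genome[[ctg]])
      cnt <- counts[[ctg]]
      L <- length(codes)
      for (o in -W:W) {
        src <- seq_len(L) + o             # base position feeding offset o
        ok <- src >= 1L & src <= L
        ok[ok] <- codes[src[ok]] > 0L
        fg[, o + W + 1L] <- fg[, o + W + 1L] +
          tabulate_weighted(codes[src[ok]], cnt[ok], 4L)
      }
      tb <- tabulate(codes[codes > 0L], 4L)
      bg <- bg + tb
    }
    fg <- sweep(fg, 2L, colSums(fg), "/")
    bg <- bg / sum(bg)
    logratio <- log(sweep(fg, 1L, bg, "/"))
    predict_fn <- function(seq) {
      codes <- seq_to_codes(seq)
      L <- length(codes)
      score <- rep(NA_real_, L)
      for (p in (W + 1L):(L - W)) {
        win <- codes[(p - W):(p + W)]
        if (all(win > 0L)) {
          score[p] <- sum(logratio[cbind(win, seq_len(2L * W + 1L))])
        }
      }
      exp(score)
    }
    list(model = logratio, predict = predict_fn, mode = mode, window = 21L)
  }
}

merge_sum <- function(a, b) {
  nm <- union(names(a), names(b))
  out <- stats::setNames(rep(0, length(nm)), nm)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

tabulate_weighted <- function(codes, w, nbins) {
  out <- numeric(nbins)
  for (i in seq_len(nbins)) out[i] <- sum(w[codes == i])
  out
}
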