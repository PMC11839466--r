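# Sequence-to-multiscale-footprint model.
#
# A dilated grouped residual convolutional network maps one-hot DNA sequence
# to per-position multiscale footprint z-statistics (footprint head) and a
# log-scale total insertion count (accessibility head). The trunk is driven
# solely by the footprint objective: accessibility-head gradients are
# stopped before the convolutional blocks, so the accessibility layer only
# reweights learned sequence features. Training targets are z-statistics
# (the footprint statistic before the p-value step), computed batched.
#
# The full-scale configuration (1,024 filters, 8 blocks, groups 8) is
# constructible; reduced configurations train on CPU. The vignette explains
# how receptive field (blocks) and first-layer width set what a reduced
# model can learn.

#' Configuration for the sequence-to-footprint model
#'
#' @param n_filters filters in every convolutional layer (divisible by
#'   `groups`).
#' @param first_width width of the first (motif-detecting) convolution.
#' @param n_blocks number of residual blocks; block i uses dilation 2^i.
#' @param groups groups of the dilated convolutions.
#' @param kernel width of the dilated convolutions.
#' @param scales footprint scale diameters predicted by the footprint head.
#' @param window input window width in bp.
#' @return a `SeqFootprintConfig`; `receptive_half_width` is derived from the
#'   schedule as (first_width-1)/2 + sum_i dilation_i * (kernel-1)/2 and
#'   never hard-coded.
#' @export
seqfp_config <- function(n_filters = 64L, first_width = 21L,
                             n_blocks = 4L, groups = 4L, kernel = 3L,
                             scales = c(20, 40, 60, 100, 160, 200),
                             window = 800L) {
  n_filters <- as.integer(n_filters)
  groups <- as.integer(groups)
  if (n_filters %% groups != 0L) {
    stop("n_filters (", n_filters, ") must be divisible by groups (",
         groups, ")")
  }
  dil <- as.integer(2^seq_len(n_blocks))
  structure(list(
    n_filters = n_filters, first_width = as.integer(first_width),
    n_blocks = as.integer(n_blocks), groups = groups,
    kernel = as.integer(kernel), dilations = dil,
    scales = as.integer(scales), window = as.integer(window),
    receptive_half_width = (as.integer(first_width) - 1L) %/% 2L +
      sum(dil * (as.integer(kernel) - 1L) %/% 2L)
  ), class = "SeqFootprintConfig")
}

#' @export
print.SeqFootprintConfig <- function(x, ...) {
  cat("SeqFootprintConfig:", x$n_filters, "filters, first conv width",
      x$first_width, ",", x$n_blocks, "residual blocks (groups", x$groups,
      ", dilations", paste(x$dilations, collapse = "/"),
      "), receptive field +/-", x$receptive_half_width, "bp\n")
  invisible(x)
}

#' Build a sequence-to-footprint model
#'
#' Trunk: first convolution (GELU) then residual blocks, each
#' `x + pw(gelu(bn2(gconv(gelu(bn1(x))))))` with a grouped dilated
#' convolution `gconv` (width `kernel`, dilation 2^i) and a position-wise
#' feed-forward convolution `pw` (width 1). Heads: a width-1 convolution
#' producing per-position z-statistics for each scale, and an accessibility
#' head (global average pooling + fully connected scalar on the log(1+n)
#' scale).
#'
#' @param config a `SeqFootprintConfig`.
#' @param seed RNG seed for weight initialisation.
#' @return a `SeqFootprintModel`; `n_params` is the analytic trainable
#'   parameter count.
#' @export
build_seqfp <- function(config, seed = 1) {
  stopifnot(inherits(config, "SeqFootprintConfig"))
  set.seed(seed)
  FF <- config$n_filters
  cg <- FF %/% config$groups
  k <- config$kernel
  S <- length(config$scales)
  params <- list(
    c1 = list(W = nn_init_mat(config$first_width * 4L, FF), b = rep(0, FF)),
    blocks = lapply(seq_len(config$n_blocks), function(i) {
      list(bn1_gamma = rep(1, FF), bn1_beta = rep(0, FF),
           gW = nn_init_mat(k * cg, FF), gb = rep(0, FF),
           bn2_gamma = rep(1, FF), bn2_beta = rep(0, FF),
           pW = nn_init_mat(FF, FF), pb = rep(0, FF))
    }),
    fp = list(W = nn_init_mat(FF, S), b = rep(0, S)),
    acc = list(W = nn_init_mat(FF, 1L), b = 0)
  )
  bn_run <- lapply(seq_len(config$n_blocks), function(i) {
    list(bn1 = list(mean = rep(0, FF), var = rep(1, FF)),
         bn2 = list(mean = rep(0, FF), var = rep(1, FF)))
  })
  n_params <- sum(vapply(rapply(params, length, how = "unlist"),
                         identity, numeric(1)))
  structure(list(config = config, params = params, bn_run = bn_run,
                 ema = NULL, n_params = n_params),
            class = "SeqFootprintModel")
}

#' @export
print.SeqFootprintModel <- function(x, ...) {
  print(x$config)
  cat("  trainable parameters:", x$n_params,
      if (!is.null(x$ema)) "; EMA shadow weights present" else "", "\n")
  invisible(x)
}

# merged grouped-conv weight for block i (base + optional LoRA delta)
s2p_block_gw <- function(params, i, lora_delta = NULL) {
  W <- params$blocks[[i]]$gW
  if (!is.null(lora_delta)) W <- W + lora_delta[[i]]
  W
}

# forward pass. codes: B x L integer base codes. Returns heads, caches for
# backward, and updated BN running stats.
s2p_forward <- function(model, codes, training = FALSE, lora_delta = NULL) {
  cfg <- model$config
  p <- model$params
  B <- nrow(codes); L <- ncol(codes)
  X <- bias_one_hot(codes)
  f1 <- nn_conv1d_forward(X, B, L, p$c1$W, p$c1$b, k = cfg$first_width)
  h <- nn_gelu(f1$out)
  caches <- list(X = X, f1 = f1, blocks = vector("list", cfg$n_blocks))
  bn_run <- model$bn_run
  for (i in seq_len(cfg$n_blocks)) {
    bl <- p$blocks[[i]]
    bn1 <- list(gamma = bl$bn1_gamma, beta = bl$bn1_beta,
                run_mean = bn_run[[i]]$bn1$mean,
                run_var = bn_run[[i]]$bn1$var)
    o1 <- nn_bn_forward(bn1, h, training = training)
    a1 <- nn_gelu(o1$out)
    gW <- s2p_block_gw(p, i, lora_delta)
    g1 <- nn_conv1d_forward(a1, B, L, gW, bl$gb, k = cfg$kernel,
                            dilation = cfg$dilations[i],
                            groups = cfg$groups)
    bn2 <- list(gamma = bl$bn2_gamma, beta = bl$bn2_beta,
                run_mean = bn_run[[i]]$bn2$mean,
                run_var = bn_run[[i]]$bn2$var)
    o2 <- nn_bn_forward(bn2, g1$out, training = training)
    a2 <- nn_gelu(o2$out)
    f <- sweep(a2 %*% bl$pW, 2L, bl$pb, "+")
    caches$blocks[[i]] <- list(x_in = h, o1 = o1, a1_pre = o1$out,
                               g1 = g1, o2 = o2, a2_pre = o2$out, a2 = a2)
    if (training) {
      bn_run[[i]]$bn1 <- list(mean = o1$bn$run_mean, var = o1$bn$run_var)
      bn_run[[i]]$bn2 <- list(mean = o2$bn$run_mean, var = o2$bn$run_var)
    }
    h <- h + f
  }
  Tout <- h
  fp <- sweep(Tout %*% p$fp$W, 2L, p$fp$b, "+")          # (B*L) x S
  gap <- rowsum(Tout, rep(seq_len(B), each = L)) / L     # B x F
  acc <- as.vector(gap %*% p$acc$W + p$acc$b)
  list(fp = fp, acc = acc, trunk = Tout, gap = gap, caches = caches,
       bn_run = bn_run, B = B, L = L)
}

# backward pass. dfp: (B*L) x S gradient on the footprint head output; dacc:
# length-B gradient on the accessibility output. The accessibility gradient
# is stopped at the trunk: it reaches only acc$W and acc$b.
s2p_backward <- function(model, fw, dfp, dacc = NULL,
                         lora_delta = NULL) {
  cfg <- model$config
  p <- model$params
  B <- fw$B; L <- fw$L
  grads <- list(c1 = NULL, blocks = vector("list", cfg$n_blocks),
                fp = NULL, acc = NULL)
  grads$fp <- list(W = crossprod(fw$trunk, dfp), b = colSums(dfp))
  if (is.null(dacc)) dacc <- rep(0, B)
  grads$acc <- list(W = crossprod(fw$gap, matrix(dacc, ncol = 1L)),
                    b = sum(dacc))
  dT <- dfp %*% t(p$fp$W)                 # gradient stop: no acc term
  dh <- dT
  for (i in rev(seq_len(cfg$n_blocks))) {
    bl <- p$blocks[[i]]
    cc <- fw$caches$blocks[[i]]
    df <- dh                              # residual: same grad into f(x)
    da2 <- df %*% t(bl$pW)
    gpW <- crossprod(cc$a2, df)
    gpb <- colSums(df)
    do2 <- da2 * nn_gelu_grad(cc$a2_pre)
    b2 <- nn_bn_backward(cc$o2, do2, bl$bn2_gamma)
    gW <- s2p_block_gw(p, i, lora_delta)
    cb <- nn_conv1d_backward(cc$a1, cc$g1, b2$dX, gW, k = cfg$kernel,
                             dilation = cfg$dilations[i],
                             groups = cfg$groups)
    da1 <- cb$dX
    do1 <- da1 * nn_gelu_grad(cc$a1_pre)
    b1 <- nn_bn_backward(cc$o1, do1, bl$bn1_gamma)
    grads$blocks[[i]] <- list(bn1_gamma = b1$dgamma, bn1_beta = b1$dbeta,
                              gW = cb$dW, gb = cb$db,
                              bn2_gamma = b2$dgamma, bn2_beta = b2$dbeta,
                              pW = gpW, pb = gpb)
    dh <- dh + b1$dX                      # residual skip
  }
  dc1pre <- dh * nn_gelu_grad(fw$caches$f1$out)
  cb1 <- nn_conv1d_backward(fw$caches$X, fw$caches$f1, dc1pre, p$c1$W,
                            k = cfg$first_width)
  grads$c1 <- list(W = cb1$dW, b = cb1$db)
  grads
}

#' Predict multiscale footprint z-statistics (and accessibility) from
#' sequence
#'
#' @param model a `SeqFootprintModel` or a list of fold models (predictions
#'   averaged).
#' @param codes B x L integer base-code matrix (see internals) or character
#'   vector of sequences.
#' @param use_ema use the EMA shadow weights if present.
#' @param lora optional `LoRAAdapterSet` with `embedding` (see
#'   [lora_finetune()]).
#' @param embedding pseudo-bulk embedding row used to condition `lora`.
#' @return list with `z` (array B x scales x L) and `acc` (length B,
#'   log(1+n) scale).
#' @export
predict_seqfp <- function(model, codes, use_ema = TRUE, lora = NULL,
                              embedding = NULL) {
  if (is.character(codes)) {
    codes <- do.call(rbind, lapply(codes, seq_to_codes))
  }
  if (!inherits(model, "SeqFootprintModel") && is.list(model)) {
    preds <- lapply(model, predict_seqfp, codes = codes,
                    use_ema = use_ema, lora = lora, embedding = embedding)
    z <- Reduce(`+`, lapply(preds, `[[`, "z")) / length(preds)
    acc <- Reduce(`+`, lapply(preds, `[[`, "acc")) / length(preds)
    return(list(z = z, acc = acc))
  }
  m <- model
  if (use_ema && !is.null(model$ema)) m$params <- model$ema
  delta <- if (!is.null(lora)) {
    lora_delta(lora, embedding, m$config)
  } else NULL
  fw <- s2p_forward(m, codes, training = FALSE, lora_delta = delta)
  S <- length(m$config$scales)
  z <- aperm(array(fw$fp, c(fw$L, fw$B, S)), c(2L, 3L, 1L))
  list(z = z, acc = fw$acc)
}

#' Batched footprint z-statistic targets
#'
#' Computes, for a batch of regions at once, the same one-sided
#' centre-vs-flank z-statistics as the footprint scoring path but stops
#' before the p-value conversion: the retained value per position is the
#' larger (less significant) of the left and right z. Used as training
#' targets for the sequence model.
#'
#' @param counts,bias n x L matrices (regions x positions).
#' @param set a `DispersionModelSet` covering all scale radii.
#' @param scales footprint diameters.
#' @return array n x scales x L of z-statistics (NA where unscorable).
#' @export
compute_footprint_targets <- function(counts, bias,
                                      set,
                                      scales = c(20, 40, 60, 100, 160, 200)) {
  counts <- as.matrix(counts); bias <- as.matrix(bias)
  stopifnot(all(dim(counts) == dim(bias)))
  n <- nrow(counts); L <- ncol(counts)
  scales <- as.integer(scales)
  bias[is.na(bias)] <- 0
  CS <- cbind(0, t(apply(counts, 1L, cumsum)))
  BS <- cbind(0, t(apply(bias, 1L, cumsum)))
  out <- array(NA_real_, c(n, length(scales), L))
  for (si in seq_along(scales)) {
    r <- scales[si] %/% 2L
    lo <- 3L * r + 1L
    hi <- L - 3L * r + 1L
    if (hi < lo) next
    pp <- lo:hi
    centre <- CS[, pp + r, drop = FALSE] - CS[, pp - r, drop = FALSE]
    left <- CS[, pp - r, drop = FALSE] - CS[, pp - 3L * r, drop = FALSE]
    right <- CS[, pp + 3L * r, drop = FALSE] - CS[, pp + r, drop = FALSE]
    centre_b <- BS[, pp + r, drop = FALSE] - BS[, pp - r, drop = FALSE]
    left_b <- BS[, pp - r, drop = FALSE] - BS[, pp - 3L * r, drop = FALSE]
    right_b <- BS[, pp + 3L * r, drop = FALSE] - BS[, pp + r, drop = FALSE]
    zs <- function(flank, flank_b) {
      covr <- centre + flank
      ok <- covr > 0 & centre_b > 0 & flank_b > 0
      zz <- matrix(NA_real_, n, length(pp))
      if (any(ok)) {
        bg <- predict_background(set, r, centre_b[ok], flank_b[ok],
                                 covr[ok])
        zz[ok] <- (centre[ok] / covr[ok] - bg$mean) / bg$sd
      }
      zz
    }
    z <- pmax(zs(left, left_b), zs(right, right_b))
    out[, si, pp] <- z
  }
  out
}

#' Round-robin chromosome fold assignment
#'
#' Chromosomes are sorted by size (largest first, seeded shuffle among
#' equal sizes) and dealt round-robin into folds.
#' @param chroms chromosome names.
#' @param sizes chromosome sizes (bp).
#' @param n_folds number of folds.
#' @param seed RNG seed for tie ordering.
#' @return named integer vector: fold of each chromosome.
#' @export
seqfp_fold_assignment <- function(chroms, sizes, n_folds = 5L,
                                      seed = 1) {
  stopifnot(length(chroms) == length(sizes))
  set.seed(seed)
  ord <- order(-sizes, sample.int(length(chroms)))
  fold <- integer(length(chroms))
  fold[ord] <- rep_len(seq_len(n_folds), length(chroms))
  names(fold) <- chroms
  fold
}

# flatten a B x S x L target array to the (B*L) x S head layout
s2p_flatten_targets <- function(z) {
  B <- dim(z)[1]; S <- dim(z)[2]; L <- dim(z)[3]
  matrix(aperm(z, c(3L, 1L, 2L)), B * L, S)
}

#' Train the sequence-to-footprint model
#'
#' Loss = MSE(footprint z targets, footprint head) + MSE(log(1+n_obs),
#' accessibility head), with the accessibility gradient stopped before the
#' trunk. Adam (default learning rate 3e-4), an exponential moving average
#' of the weights, and early stopping on validation footprint loss. NA
#' targets (unscorable positions) are masked from the loss.
#'
#' @param model a `SeqFootprintModel`.
#' @param codes n x L base-code matrix of region sequences.
#' @param targets n x scales x L z-statistic array
#'   (see [compute_footprint_targets()]).
#' @param n_obs observed insertion counts per region.
#' @param chrom chromosome of each region.
#' @param val_chroms chromosomes held out for early stopping (must not also
#'   appear in the training set).
#' @param epochs,batch,lr,lr_decay,patience optimisation controls
#'   (`lr_decay` shrinks the learning rate per epoch).
#' @param ema_decay decay of the EMA shadow weights.
#' @param seed RNG seed.
#' @return the trained `SeqFootprintModel` (EMA weights in `$ema`, training
#'   history in `$history`).
#' @export
train_seqfp <- function(model, codes, targets, n_obs, chrom,
                            val_chroms, epochs = 60, batch = 8, lr = 3e-4,
                            lr_decay = 1, patience = 10, ema_decay = 0.95,
                            seed = 1) {
  stopifnot(inherits(model, "SeqFootprintModel"))
  if (!any(chrom %in% val_chroms)) stop("no validation regions")
  if (all(chrom %in% val_chroms)) stop("no training regions")
  set.seed(seed)
  iva <- which(chrom %in% val_chroms)
  itr <- which(!chrom %in% val_chroms)
  y_acc <- log1p(n_obs)
  opt <- nn_adam_init(model$params)
  ema <- model$params
  fp_loss <- function(fp, zt) {
    ok <- !is.na(zt)
    mean((fp[ok] - zt[ok])^2)
  }
  # validation is evaluated on the EMA shadow weights: those are what
  # inference uses, so early stopping must select on them
  val_loss <- function(m, ema) {
    m$params <- ema
    tot <- 0; nb <- 0
    for (s in seq(1L, length(iva), by = batch)) {
      idx <- iva[s:min(s + batch - 1L, length(iva))]
      fw <- s2p_forward(m, codes[idx, , drop = FALSE], training = FALSE)
      zt <- s2p_flatten_targets(targets[idx, , , drop = FALSE])
      tot <- tot + fp_loss(fw$fp, zt)
      nb <- nb + 1
    }
    tot / nb
  }
  best <- list(loss = Inf, params = model$params, ema = ema, epoch = 0L)
  wait <- 0L
  hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(itr)
    lr_ep <- lr * lr_decay^(ep - 1L)
    for (s in seq(1L, length(ord), by = batch)) {
      idx <- ord[s:min(s + batch - 1L, length(ord))]
      fw <- s2p_forward(model, codes[idx, , drop = FALSE], training = TRUE)
      model$bn_run <- fw$bn_run
      zt <- s2p_flatten_targets(targets[idx, , , drop = FALSE])
      ok <- !is.na(zt)
      dfp <- matrix(0, nrow(zt), ncol(zt))
      dfp[ok] <- 2 * (fw$fp[ok] - zt[ok]) / sum(ok)
      dacc <- 2 * (fw$acc - y_acc[idx]) / length(idx)
      grads <- s2p_backward(model, fw, dfp, dacc)
      res <- nn_adam_step(model$params, grads, opt, lr = lr_ep)
      model$params <- res$params
      opt <- res$state
      ema <- nn_walk2(ema, model$params, function(e, w) {
        ema_decay * e + (1 - ema_decay) * w
      })
    }
    vl <- val_loss(model, ema)
    hist <- c(hist, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = model$params, ema = ema,
                   bn_run = model$bn_run, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$params <- best$params
  model$ema <- best$ema
  if (!is.null(best$bn_run)) model$bn_run <- best$bn_run
  model$history <- hist
  model$val_loss <- best$loss
  model
}

#' Chromosome-based cross-validated training
#'
#' Trains one model per fold, holding the fold's chromosomes out; at
#' inference, fold predictions are averaged by passing the returned list to
#' [predict_seqfp()].
#'
#' @inheritParams train_seqfp
#' @param folds named fold assignment from [seqfp_fold_assignment()]; a
#'   chromosome may appear in only one fold.
#' @param ... passed to [train_seqfp()].
#' @return list of trained models, one per fold.
#' @export
train_seqfp_cv <- function(model, codes, targets, n_obs, chrom, folds,
                               ...) {
  if (anyDuplicated(names(folds))) {
    stop("chromosome present in two folds: ",
         names(folds)[duplicated(names(folds))][1])
  }
  lapply(sort(unique(folds)), function(f) {
    train_seqfp(model, codes, targets, n_obs, chrom,
                    val_chroms = names(folds)[folds == f], ...)
  })
}
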