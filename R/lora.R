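# LoRA fine-tuning: per-pseudo-bulk low-rank weight deltas for the grouped
# dilated convolution of each residual block, conditioned on the
# pseudo-bulk's cell embedding. For a layer with n_filter output channels,
# groups g and kernel width k, the base weight (k * n_filter/g) x n_filter
# is updated by
#   delta_W[(tap-1)*Cg + c, o] = left[c] * right[o, tap]
# where left = e A1 A2 (length Cg = n_filter/g) and right = e B1 B2
# (length n_filter * k), e being the embedding. Factors A = (A1: d_e x r,
# A2: r x Cg) and B = (B1: d_e x r, B2: r x n_filter*k) are shared across
# pseudo-bulks; the delta varies only through the embedding. The left
# chain's output factor starts at zero, so every pseudo-bulk model starts
# exactly at the base model. Only adapter parameters train; base weights
# and batch-normalisation statistics stay frozen.

#' Per-layer LoRA adapter parameter count
#'
#' Follows the A/B factor shapes: (d_e*r + r*Cg) + (d_e*r +
#' r*n_filter*kernel) with Cg = n_filter/groups.
#' @param config a `SeqFootprintConfig`.
#' @param d_embed embedding dimension.
#' @param r adapter rank.
#' @export
lora_param_count <- function(config, d_embed, r) {
  cg <- config$n_filters %/% config$groups
  (d_embed * r + r * cg) +
    (d_embed * r + r * config$n_filters * config$kernel)
}

#' Initialise a LoRA adapter set
#'
#' @param config the base model's `SeqFootprintConfig`.
#' @param d_embed embedding dimension.
#' @param r adapter rank (default 32).
#' @param seed RNG seed (the left chain's output factor starts at zero).
#' @return a `LoRAAdapterSet`.
#' @export
lora_init <- function(config, d_embed, r = 32L, seed = 1) {
  stopifnot(r >= 1L)
  set.seed(seed)
  cg <- config$n_filters %/% config$groups
  k <- config$kernel
  # delta_W is the product of the A-chain (left) and B-chain (right)
  # factors: zero-initialising BOTH output factors would zero the gradient
  # as well (a saddle), so only the left chain starts at zero — the merged
  # delta is still exactly zero at initialisation
  layers <- lapply(seq_len(config$n_blocks), function(i) {
    list(A1 = nn_init_mat(d_embed, r), A2 = matrix(0, r, cg),
         B1 = nn_init_mat(d_embed, r),
         B2 = nn_init_mat(r, config$n_filters * k))
  })
  structure(list(layers = layers, d_embed = as.integer(d_embed),
                 r = as.integer(r), config = config),
            class = "LoRAAdapterSet")
}

#' @export
print.LoRAAdapterSet <- function(x, ...) {
  cat("LoRAAdapterSet: rank", x$r, ", embedding dim", x$d_embed, ",",
      length(x$layers), "adapted layer(s),",
      lora_param_count(x$config, x$d_embed, x$r), "parameters per layer\n")
  invisible(x)
}

# per-block weight deltas for one embedding row
lora_delta <- function(adapter, embedding, config = adapter$config) {
  if (length(embedding) != adapter$d_embed) {
    stop("embedding dimension ", length(embedding),
         " does not match adapter d_embed ", adapter$d_embed)
  }
  e <- matrix(embedding, 1L)
  cg <- config$n_filters %/% config$groups
  k <- config$kernel
  lapply(adapter$layers, function(ly) {
    left <- as.vector(e %*% ly$A1 %*% ly$A2)                # Cg
    right <- as.vector(e %*% ly$B1 %*% ly$B2)               # F*k
    Rmat <- matrix(right, config$n_filters, k)
    dW <- matrix(0, k * cg, config$n_filters)
    for (tap in seq_len(k)) {
      dW[(tap - 1L) * cg + seq_len(cg), ] <- outer(left, Rmat[, tap])
    }
    dW
  })
}

# chain conv-weight gradients into adapter-factor gradients for one
# embedding
lora_grads <- function(adapter, embedding, dW_list, config = adapter$config) {
  e <- matrix(embedding, 1L)
  cg <- config$n_filters %/% config$groups
  k <- config$kernel
  lapply(seq_along(adapter$layers), function(i) {
    ly <- adapter$layers[[i]]
    dW <- dW_list[[i]]
    left <- as.vector(e %*% ly$A1 %*% ly$A2)
    right <- as.vector(e %*% ly$B1 %*% ly$B2)
    Rmat <- matrix(right, config$n_filters, k)
    dleft <- numeric(cg)
    dR <- matrix(0, config$n_filters, k)
    for (tap in seq_len(k)) {
      Dt <- dW[(tap - 1L) * cg + seq_len(cg), , drop = FALSE]  # Cg x F
      dleft <- dleft + as.vector(Dt %*% Rmat[, tap])
      dR[, tap] <- as.vector(crossprod(Dt, left))
    }
    uA <- e %*% ly$A1                                        # 1 x r
    dA2 <- crossprod(uA, matrix(dleft, 1L))                  # r x Cg
    duA <- matrix(dleft, 1L) %*% t(ly$A2)                    # 1 x r
    dA1 <- crossprod(e, duA)                                 # d_e x r
    dright <- as.vector(dR)
    uB <- e %*% ly$B1
    dB2 <- crossprod(uB, matrix(dright, 1L))                 # r x F*k
    duB <- matrix(dright, 1L) %*% t(ly$B2)
    dB1 <- crossprod(e, duB)
    list(A1 = dA1, A2 = dA2, B1 = dB1, B2 = dB2)
  })
}

#' Fine-tune per-pseudo-bulk LoRA adapters
#'
#' The base model is frozen (weights and batch-normalisation statistics);
#' only the adapter factors are trained, with the footprint MSE loss,
#' cycling over pseudo-bulks. Early stopping uses the pooled validation
#' footprint loss over a held-out fraction of each bulk's regions.
#'
#' @param base a trained `SeqFootprintModel`.
#' @param embeddings pseudo-bulk x d_e numeric matrix (rownames = bulk
#'   ids).
#' @param data named list (per bulk id) of lists with `codes` (n x L) and
#'   `targets` (n x scales x L z arrays).
#' @param r adapter rank (default 32).
#' @param epochs,batch,lr,patience optimisation controls.
#' @param val_frac fraction of each bulk's regions held out.
#' @param seed RNG seed.
#' @param use_ema fine-tune from the EMA weights if present.
#' @return a `LoRAAdapterSet` with `embeddings` attached and `history` of
#'   validation losses.
#' @export
lora_finetune <- function(base, embeddings, data, r = 32L, epochs = 20,
                          batch = 8L, lr = 1e-3, patience = 4,
                          val_frac = 0.25, seed = 1, use_ema = TRUE) {
  stopifnot(inherits(base, "SeqFootprintModel"))
  bulks <- rownames(embeddings)
  if (is.null(bulks) || !all(bulks %in% names(data))) {
    stop("embeddings rownames must name entries of `data`")
  }
  set.seed(seed)
  m <- base
  if (use_ema && !is.null(base$ema)) m$params <- base$ema
  cfg <- m$config
  adapter <- lora_init(cfg, ncol(embeddings), r = r, seed = seed)
  opt <- nn_adam_init(adapter$layers)
  splits <- lapply(bulks, function(b) {
    n <- nrow(data[[b]]$codes)
    iva <- sample.int(n, max(1L, round(val_frac * n)))
    list(tr = setdiff(seq_len(n), iva), va = iva)
  })
  names(splits) <- bulks
  fp_loss_bulk <- function(adapter, b, idx) {
    delta <- lora_delta(adapter, embeddings[b, ])
    tot <- 0; nb <- 0L
    for (s in seq(1L, length(idx), by = batch)) {
      ii <- idx[s:min(s + batch - 1L, length(idx))]
      fw <- s2p_forward(m, data[[b]]$codes[ii, , drop = FALSE],
                        training = FALSE, lora_delta = delta)
      zt <- s2p_flatten_targets(data[[b]]$targets[ii, , , drop = FALSE])
      ok <- !is.na(zt)
      tot <- tot + mean((fw$fp[ok] - zt[ok])^2)
      nb <- nb + 1L
    }
    tot / nb
  }
  val_loss <- function(adapter) {
    mean(vapply(bulks, function(b) fp_loss_bulk(adapter, b, splits[[b]]$va),
                numeric(1)))
  }
  best <- list(loss = val_loss(adapter), layers = adapter$layers,
               epoch = 0L)
  wait <- 0L
  hist <- best$loss
  for (ep in seq_len(epochs)) {
    for (b in sample(bulks)) {
      e <- embeddings[b, ]
      idx <- sample(splits[[b]]$tr)
      delta <- lora_delta(adapter, e)
      for (s in seq(1L, length(idx), by = batch)) {
        ii <- idx[s:min(s + batch - 1L, length(idx))]
        fw <- s2p_forward(m, data[[b]]$codes[ii, , drop = FALSE],
                          training = FALSE, lora_delta = delta)
        zt <- s2p_flatten_targets(data[[b]]$targets[ii, , , drop = FALSE])
        ok <- !is.na(zt)
        dfp <- matrix(0, nrow(zt), ncol(zt))
        dfp[ok] <- 2 * (fw$fp[ok] - zt[ok]) / sum(ok)
        grads_full <- s2p_backward(m, fw, dfp, lora_delta = delta)
        dW_list <- lapply(grads_full$blocks, `[[`, "gW")
        g <- lora_grads(adapter, e, dW_list)
        res <- nn_adam_step(adapter$layers, g, opt, lr = lr)
        adapter$layers <- res$params
        opt <- res$state
        delta <- lora_delta(adapter, e)
      }
    }
    vl <- val_loss(adapter)
    hist <- c(hist, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, layers = adapter$layers, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  adapter$layers <- best$layers
  adapter$embeddings <- embeddings
  adapter$history <- hist
  adapter$val_loss <- best$loss
  adapter
}
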