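# Interpretation of the sequence model: reference-based per-base
# attribution scores (DeepLIFT rescale rule against dinucleotide-shuffled
# references), an attribution-based TF binding classifier, and in-silico
# motif perturbation (marginalized motif effects).

#' Dinucleotide-preserving sequence shuffle
#'
#' Generates shuffled versions of a sequence whose dinucleotide count table
#' equals the input's exactly, via a random Eulerian path over the
#' dinucleotide transition multigraph (Altschul-Erickson construction).
#' Runs of N split the sequence into segments that are shuffled
#' independently, with the N runs left in place.
#'
#' @param seq nucleotide string (length >= 2).
#' @param n_refs number of shuffles to return.
#' @param seed RNG seed.
#' @return character vector of `n_refs` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seq, n_refs = 20, seed = 1) {
  if (nchar(seq) < 2L) stop("sequence must have length >= 2")
  set.seed(seed)
  chars <- strsplit(toupper(seq), "")[[1]]
  is_n <- chars == "N"
  seg_id <- cumsum(c(TRUE, diff(is_n) != 0))
  vapply(seq_len(n_refs), function(i) {
    out <- chars
    for (sid in unique(seg_id)) {
      idx <- which(seg_id == sid)
      if (!is_n[idx[1]] && length(idx) >= 3L) {
        out[idx] <- euler_shuffle(chars[idx])
      }
    }
    paste(out, collapse = "")
  }, character(1))
}

# random Eulerian-path shuffle of one N-free segment (character vector)
euler_shuffle <- function(x) {
  m <- length(x)
  verts <- unique(x)
  if (length(verts) == 1L) return(x)
  # out-edge targets per vertex
  edges <- split(x[-1L], factor(x[-m], levels = verts))
  terminal <- x[m]
  for (attempt in 1:200) {
    last <- vapply(verts, function(v) {
      ev <- edges[[v]]
      if (v == terminal || length(ev) == 0L) NA_character_
      else ev[sample.int(length(ev), 1L)]
    }, character(1))
    # connectivity: following last edges from every vertex must reach the
    # terminal vertex
    ok <- TRUE
    for (v in verts) {
      cur <- v
      for (step in seq_along(verts)) {
        if (cur == terminal) break
        cur <- last[[cur]]
        if (is.na(cur)) break
      }
      if (cur != terminal) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(x)                      # degenerate graph: keep original
  arranged <- lapply(verts, function(v) {
    ev <- edges[[v]]
    if (length(ev) == 0L) return(character(0))
    if (v == terminal) return(ev[sample.int(length(ev))])
    li <- match(last[[v]], ev)
    rest <- ev[-li]
    c(rest[sample.int(length(rest))], last[[v]])
  })
  names(arranged) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  out <- character(m)
  out[1L] <- x[1L]
  cur <- x[1L]
  for (i in 2:m) {
    used[cur] <- used[cur] + 1L
    nxt <- arranged[[cur]][used[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Dinucleotide count table of a sequence
#' @param seq nucleotide string.
#' @return named integer vector of adjacent-pair counts.
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < 2L) return(integer(0))
  pairs <- paste0(chars[-length(chars)], chars[-1L])
  c(table(pairs))
}

## ---- DeepLIFT rescale attribution -------------------------------------------

# rescale multiplier: (f(x) - f(xr)) / (x - xr), falling back to the exact
# derivative where the difference underflows
rescale_mult <- function(x, xr, f, df, eps = 1e-7) {
  dx <- x - xr
  small <- abs(dx) < eps
  out <- (f(x) - f(xr)) / dx
  if (any(small)) out[small] <- df((x[small] + xr[small]) / 2)
  out
}

# -log10 p footprint score from a z-statistic, and its derivative
z_to_score <- function(z) -stats::pnorm(z, log.p = TRUE) / log(10)
z_to_score_grad <- function(z) {
  -exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE)) / log(10)
}

# backward pass propagating DeepLIFT rescale multipliers. fx / fr are eval-
# mode forward caches on the input and one reference. mfp: (L x S)
# multiplier on the footprint head output; macc: scalar multiplier on the
# accessibility output (propagated through the trunk here, unlike training).
s2p_rescale_backward <- function(model, fx, fr, mfp, macc = 0) {
  cfg <- model$config
  p <- model$params
  L <- fx$L
  m_T <- mfp %*% t(p$fp$W)
  if (macc != 0) {
    # accessibility head: GAP then dense; multiplier spreads uniformly
    m_T <- m_T + matrix(rep(as.vector(p$acc$W) * macc / L, each = L),
                        L, ncol(m_T))
  }
  mh <- m_T
  for (i in rev(seq_len(cfg$n_blocks))) {
    bl <- p$blocks[[i]]
    cx <- fx$caches$blocks[[i]]
    cr <- fr$caches$blocks[[i]]
    mf <- mh
    ma2 <- mf %*% t(bl$pW)
    mo2 <- ma2 * rescale_mult(cx$a2_pre, cr$a2_pre, nn_gelu, nn_gelu_grad)
    b2 <- nn_bn_backward(cx$o2, mo2, bl$bn2_gamma)   # eval mode: affine
    cb <- nn_conv1d_backward(cx$a1, cx$g1, b2$dX, p$blocks[[i]]$gW,
                             k = cfg$kernel, dilation = cfg$dilations[i],
                             groups = cfg$groups)
    mo1 <- cb$dX * rescale_mult(cx$a1_pre, cr$a1_pre, nn_gelu, nn_gelu_grad)
    b1 <- nn_bn_backward(cx$o1, mo1, bl$bn1_gamma)
    mh <- mh + b1$dX
  }
  mc1 <- mh * rescale_mult(fx$caches$f1$out, fr$caches$f1$out,
                           nn_gelu, nn_gelu_grad)
  cb1 <- nn_conv1d_backward(fx$caches$X, fx$caches$f1, mc1, p$c1$W,
                            k = cfg$first_width)
  cb1$dX                                   # multipliers on the one-hot input
}

#' Per-base attribution scores for a scalar model output
#'
#' DeepLIFT rescale-rule attributions of a chosen scalar against
#' dinucleotide-shuffled reference sequences (averaged over references).
#' Scalar targets: `count` (the accessibility output), `footprint_whole_peak`
#' (footprint z converted to -log10 p scores and summed over all scales and
#' positions) or `footprint_window` (the same sum restricted to given
#' scales/positions). The attribution satisfies completeness: summed over
#' the input it equals the scalar on the input minus its mean over the
#' references.
#'
#' @param model a `SeqFootprintModel`.
#' @param seq input sequence (string of the model's window length).
#' @param target scalar target selection.
#' @param scale_idx,pos_range for `footprint_window`: scale indices and a
#'   1-based position range (two-element vector).
#' @param n_refs number of dinucleotide-shuffled references.
#' @param seed RNG seed for the shuffles.
#' @param use_ema use EMA weights if present.
#' @return an `AttributionTrack`: list with `attr` (per-bp, length L),
#'   `per_channel` (L x 4), `value` (scalar on the input), `ref_value`
#'   (mean scalar over references), `target`, `n_refs`.
#' @export
attribution_scores <- function(model, seq,
                               target = c("count", "footprint_whole_peak",
                                          "footprint_window"),
                               scale_idx = NULL, pos_range = NULL,
                               n_refs = 20, seed = 1, use_ema = TRUE) {
  target <- match.arg(target)
  stopifnot(inherits(model, "SeqFootprintModel"))
  m <- model
  if (use_ema && !is.null(model$ema)) m$params <- model$ema
  codes <- matrix(seq_to_codes(seq), nrow = 1L)
  L <- ncol(codes)
  refs <- dinucleotide_shuffle(seq, n_refs = n_refs, seed = seed)
  fx <- s2p_forward(m, codes, training = FALSE)
  S <- length(m$config$scales)
  sel <- matrix(FALSE, L, S)
  if (target == "footprint_whole_peak") {
    sel[] <- TRUE
  } else if (target == "footprint_window") {
    if (is.null(scale_idx) || is.null(pos_range)) {
      stop("footprint_window needs scale_idx and pos_range")
    }
    sel[pos_range[1]:pos_range[2], scale_idx] <- TRUE
  }
  scalar_of <- function(fw) {
    if (target == "count") fw$acc else sum(z_to_score(fw$fp[sel]))
  }
  acc_attr <- matrix(0, L, 4L)
  ref_vals <- numeric(n_refs)
  for (i in seq_len(n_refs)) {
    fr <- s2p_forward(m, matrix(seq_to_codes(refs[i]), nrow = 1L),
                      training = FALSE)
    ref_vals[i] <- scalar_of(fr)
    if (target == "count") {
      mfp <- matrix(0, L, S)
      macc <- 1
    } else {
      mfp <- matrix(0, L, S)
      mfp[sel] <- rescale_mult(fx$fp[sel], fr$fp[sel],
                               z_to_score, z_to_score_grad)
      macc <- 0
    }
    mX <- s2p_rescale_backward(m, fx, fr, mfp, macc)
    Xr <- bias_one_hot(matrix(seq_to_codes(refs[i]), nrow = 1L))
    acc_attr <- acc_attr + mX * (fx$caches$X - Xr)
  }
  per_channel <- acc_attr / n_refs
  structure(list(attr = rowSums(per_channel), per_channel = per_channel,
                 value = scalar_of(fx), ref_value = mean(ref_vals),
                 target = target, n_refs = n_refs),
            class = "AttributionTrack")
}

#' @export
print.AttributionTrack <- function(x, ...) {
  cat("AttributionTrack (", x$target, "): length", length(x$attr),
      "; scalar", signif(x$value, 4), "vs reference mean",
      signif(x$ref_value, 4), "\n")
  invisible(x)
}

## ---- attribution-based TF features ------------------------------------------

#' Attribution-based TF feature vector for one motif site
#'
#' Concatenates the count attribution scores over +/-100 bp (201), the
#' footprint attribution scores over the same window (201), the
#' quantile-transformed motif score (1) and the Pearson correlation between
#' the motif's per-position expected log-odds pattern and each attribution
#' track at the match site (2): 405 dimensions in total. A constant
#' attribution window makes the correlation undefined; it is filled with 0
#' and flagged.
#'
#' @param count_attr,footprint_attr per-bp attribution vectors over the
#'   region.
#' @param site_start,site_end site coordinates within the region (0-based
#'   half-open).
#' @param motif the site's `MotifModel`.
#' @param motif_score site log-odds score.
#' @param motif_scores_all pooled score list of the motif.
#' @param half_width window half-width (default 100).
#' @return numeric vector of length 405, with attribute
#'   `constant_attribution` (logical flag).
#' @export
attribution_tf_features <- function(count_attr, footprint_attr, site_start,
                                    site_end, motif, motif_score,
                                    motif_scores_all, half_width = 100L) {
  hw <- as.integer(half_width)
  centre <- (site_start + site_end) %/% 2L + 1L
  lo <- centre - hw; hi <- centre + hw
  if (lo < 1L || hi > length(count_attr) || hi > length(footprint_attr)) {
    stop("attribution tracks must cover the site +/- ", hw, " bp")
  }
  w_count <- count_attr[lo:hi]
  w_fp <- footprint_attr[lo:hi]
  q <- mean(motif_scores_all <= motif_score)
  span <- (site_start + 1L):site_end
  pattern <- colSums(motif$pfm * motif$logodds)   # expected log-odds/column
  if (length(span) != length(pattern)) {
    stop("site span does not match motif length")
  }
  corr_of <- function(track) {
    v <- track[span]
    if (stats::sd(v) < 1e-12 || stats::sd(pattern) < 1e-12) NA_real_
    else stats::cor(v, pattern)
  }
  c1 <- corr_of(count_attr)
  c2 <- corr_of(footprint_attr)
  flag <- is.na(c1) || is.na(c2)
  v <- c(w_count, w_fp, q,
         ifelse(is.na(c1), 0, c1), ifelse(is.na(c2), 0, c2))
  stopifnot(length(v) == 405L)
  attr(v, "constant_attribution") <- flag
  v
}

#' Fit the attribution-based TF binding classifier
#'
#' Three hidden layers (256, 128, 64) with GELU activations and dropout
#' 0.25, sigmoid output, binary cross-entropy, Adam, early stopping.
#'
#' @param features 405-column matrix from [attribution_tf_features()].
#' @param labels 0/1 ChIP-overlap labels.
#' @param seed RNG seed.
#' @param epochs,patience,batch,lr optimisation controls.
#' @return an `AttributionTFModel`.
#' @export
fit_attribution_tf_model <- function(features, labels, seed = 1,
                                     epochs = 100, patience = 8,
                                     batch = 64, lr = 1e-3) {
  features <- as.matrix(features)
  if (ncol(features) != 405L) {
    stop("attribution TF features must have 405 columns; got ",
         ncol(features))
  }
  fit <- nn_fit_mlp(features, matrix(labels, ncol = 1L),
                    hidden = c(256L, 128L, 64L), act = "gelu",
                    dropout = 0.25, loss = "bce", batch = batch,
                    epochs = epochs, patience = patience, lr = lr,
                    standardize = TRUE, seed = seed)
  structure(list(fit = fit), class = "AttributionTFModel")
}

#' Predict from the attribution-based TF classifier
#' @param object an `AttributionTFModel`.
#' @param features 405-column matrix.
#' @param ... unused.
#' @export
predict.AttributionTFModel <- function(object, features, ...) {
  as.vector(nn_mlp_predict(object$fit, as.matrix(features)))
}

## ---- marginalized motif effects ---------------------------------------------

#' Marginalized effect of a motif on predicted footprints
#'
#' Plant mode: the motif consensus is written at the centre of `n_regions`
#' sampled regions and the mean prediction difference (planted minus
#' original) is returned. Scramble mode: existing match sites are
#' dinucleotide-shuffled and the difference (original minus scrambled) is
#' returned. Both measure presence minus absence of the motif.
#'
#' @param model a `SeqFootprintModel` (or fold-model list).
#' @param motif a `MotifModel` (consensus used in plant mode).
#' @param region_seqs character vector of region sequences (model window
#'   length).
#' @param mode "plant" or "scramble".
#' @param n_regions regions to sample (default 25,000, capped at the number
#'   available).
#' @param sites for scramble mode: data.frame with `region` (index into
#'   `region_seqs`), `start`, `end` (0-based half-open within the region).
#' @param seed RNG seed.
#' @param batch prediction batch size.
#' @return a `MotifEffect`: `delta` (scales x window matrix of mean z
#'   change), `n_regions`, `mode`.
#' @export
marginalize_motif_effect <- function(model, motif, region_seqs,
                                     mode = c("plant", "scramble"),
                                     n_regions = 25000, sites = NULL,
                                     seed = 1, batch = 16L) {
  mode <- match.arg(mode)
  set.seed(seed)
  cfg <- if (inherits(model, "SeqFootprintModel")) model$config
         else model[[1]]$config
  L <- cfg$window
  mean_pred <- function(seqs) {
    acc <- 0
    n <- length(seqs)
    for (s in seq(1L, n, by = batch)) {
      idx <- s:min(s + batch - 1L, n)
      codes <- do.call(rbind, lapply(seqs[idx], seq_to_codes))
      z <- predict_seqfp(model, codes)$z
      acc <- acc + apply(z, c(2L, 3L), sum)
    }
    acc / n
  }
  if (mode == "plant") {
    n_use <- min(n_regions, length(region_seqs))
    pick <- sample.int(length(region_seqs), n_use)
    orig <- region_seqs[pick]
    cons <- motif_consensus(motif)
    w <- nchar(cons)
    at <- L %/% 2L - w %/% 2L + 1L
    planted <- vapply(orig, function(s) {
      substr(s, at, at + w - 1L) <- cons
      s
    }, character(1), USE.NAMES = FALSE)
    delta <- mean_pred(planted) - mean_pred(orig)
  } else {
    if (is.null(sites) || nrow(sites) == 0L) {
      stop("scramble mode requires at least one match site")
    }
    n_use <- min(n_regions, nrow(sites))
    pick <- sample.int(nrow(sites), n_use)
    orig <- region_seqs[sites$region[pick]]
    scrambled <- vapply(seq_along(pick), function(j) {
      s <- orig[j]
      st <- sites$start[pick[j]] + 1L
      en <- sites$end[pick[j]]
      sub <- substr(s, st, en)
      substr(s, st, en) <- dinucleotide_shuffle(sub, n_refs = 1L,
                                                seed = seed + j)[1]
      s
    }, character(1))
    delta <- mean_pred(orig) - mean_pred(scrambled)
  }
  rownames(delta) <- cfg$scales
  structure(list(delta = delta, n_regions = n_use, mode = mode,
                 motif = motif$name),
            class = "MotifEffect")
}

#' @export
print.MotifEffect <- function(x, ...) {
  cat("MotifEffect (", x$mode, ") for", x$motif, ":", x$n_regions,
      "regions; max |delta z| =", signif(max(abs(x$delta)), 4), "\n")
  invisible(x)
}
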