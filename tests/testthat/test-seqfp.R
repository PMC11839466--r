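# Sequence-to-footprint model contracts: architecture arithmetic, gradient
# stop, EMA, batched targets, shuffling, attributions, LoRA algebra.
# (Training-quality checks live in the acceptance suite.)

tiny_cfg <- function(window = 160L) {
  seqfp_config(n_filters = 16, n_blocks = 2, groups = 4,
                   window = window, scales = c(20, 40))
}

tiny_model <- function(seed = 2, window = 160L) {
  m <- build_seqfp(tiny_cfg(window), seed = seed)
  set.seed(seed)
  codes <- matrix(sample(1:4, 6 * window, replace = TRUE), 6, window)
  for (i in 1:4) {                       # settle BN running stats
    fw <- fpkit:::s2p_forward(m, codes, training = TRUE)
    m$bn_run <- fw$bn_run
  }
  m
}

test_that("parameter count and receptive field follow closed forms", {
  cfg <- seqfp_config(n_filters = 64, n_blocks = 4, groups = 4,
                          window = 800)
  m <- build_seqfp(cfg, seed = 1)
  FF <- 64; cg <- FF / 4; S <- 6
  expected <- (21 * 4 * FF + FF) +                       # first conv
    4 * (2 * FF +                                       # bn1 gamma/beta
           3 * cg * FF + FF +                           # grouped conv
           2 * FF +                                     # bn2
           FF * FF + FF) +                              # pointwise
    (FF * S + S) +                                      # footprint head
    (FF + 1)                                            # accessibility head
  expect_equal(m$n_params, expected)
  # derived receptive half-width: 10 + sum of dilations (kernel 3)
  expect_equal(cfg$receptive_half_width, 10 + sum(2^(1:4)))
  # the full-scale schedule derives 10 + sum(2^i, i=1..8) = 520 per side
  big <- seqfp_config(n_filters = 1024, n_blocks = 8, groups = 8,
                          window = 1000)
  expect_equal(big$receptive_half_width, 10 + sum(2^(1:8)))
  expect_error(seqfp_config(n_filters = 10, groups = 4), "divisible")
})

test_that("footprint head output has shape (scales, window)", {
  m <- tiny_model()
  codes <- matrix(sample(1:4, 2 * 160, replace = TRUE), 2, 160)
  pred <- predict_seqfp(m, codes, use_ema = FALSE)
  expect_equal(dim(pred$z), c(2L, 2L, 160L))
  expect_length(pred$acc, 2L)
})

test_that("an accessibility-only step leaves every trunk parameter bitwise unchanged", {
  m <- tiny_model()
  codes <- matrix(sample(1:4, 3 * 160, replace = TRUE), 3, 160)
  fw <- fpkit:::s2p_forward(m, codes, training = TRUE)
  gr <- fpkit:::s2p_backward(m, fw, matrix(0, nrow(fw$fp), ncol(fw$fp)),
                             dacc = rep(1, 3))
  res <- fpkit:::nn_adam_step(m$params, gr, fpkit:::nn_adam_init(m$params),
                              lr = 1e-3)
  expect_identical(res$params$c1, m$params$c1)
  expect_identical(res$params$blocks, m$params$blocks)
  expect_identical(res$params$fp, m$params$fp)
  expect_false(identical(res$params$acc, m$params$acc))
})

test_that("trunk gradients match finite differences through blocks and heads", {
  m <- tiny_model(seed = 4, window = 80L)
  set.seed(4)
  codes <- matrix(sample(1:4, 2 * 80, replace = TRUE), 2, 80)
  zt <- array(stats::rnorm(2 * 2 * 80), c(2, 2, 80))
  ztf <- fpkit:::s2p_flatten_targets(zt)
  loss_of <- function(params) {
    mm <- m; mm$params <- params
    f <- fpkit:::s2p_forward(mm, codes, training = TRUE)
    mean((f$fp - ztf)^2)
  }
  fw <- fpkit:::s2p_forward(m, codes, training = TRUE)
  gr <- fpkit:::s2p_backward(m, fw, 2 * (fw$fp - ztf) / length(ztf))
  eps <- 1e-5
  worst <- 0
  probe <- function(get, set, gval) {
    v <- get()
    for (i in sample(length(v), 3)) {
      v1 <- v; v1[i] <- v[i] + eps
      v2 <- v; v2[i] <- v[i] - eps
      gn <- (loss_of(set(v1)) - loss_of(set(v2))) / (2 * eps)
      worst <<- max(worst, abs(gn - gval[i]) / max(abs(gn), 1e-8))
    }
  }
  p0 <- m$params
  probe(function() p0$c1$W,
        function(v) { p <- p0; p$c1$W <- matrix(v, nrow(p0$c1$W)); p },
        gr$c1$W)
  probe(function() p0$blocks[[1]]$gW,
        function(v) { p <- p0
          p$blocks[[1]]$gW <- matrix(v, nrow(p0$blocks[[1]]$gW)); p },
        gr$blocks[[1]]$gW)
  probe(function() p0$blocks[[2]]$bn2_gamma,
        function(v) { p <- p0; p$blocks[[2]]$bn2_gamma <- v; p },
        gr$blocks[[2]]$bn2_gamma)
  expect_lt(worst, 1e-4)
})

test_that("EMA equals the closed-form exponentially weighted average of iterates", {
  decay <- 0.9
  set.seed(9)
  iterates <- lapply(1:6, function(i) list(w = stats::rnorm(4)))
  ema <- iterates[[1]]
  saved <- list(iterates[[1]])
  for (i in 2:6) {
    ema <- fpkit:::nn_walk2(ema, iterates[[i]],
                            function(e, w) decay * e + (1 - decay) * w)
    saved[[i]] <- iterates[[i]]
  }
  # closed form: d^5 w1 + sum_{i=2..6} (1-d) d^(6-i) wi
  closed <- decay^5 * saved[[1]]$w
  for (i in 2:6) closed <- closed + (1 - decay) * decay^(6 - i) * saved[[i]]$w
  expect_lt(max(abs(ema$w - closed)), 1e-6)
})

test_that("fold assignment is round-robin by size and rejects duplicates", {
  fold <- seqfp_fold_assignment(paste0("c", 1:7),
                                    sizes = c(70, 60, 50, 40, 30, 20, 10),
                                    n_folds = 3, seed = 1)
  expect_equal(unname(fold[order(-c(70, 60, 50, 40, 30, 20, 10))]),
               rep_len(1:3, 7))
  expect_error(
    train_seqfp_cv(NULL, NULL, NULL, NULL, NULL,
                       folds = stats::setNames(c(1L, 2L), c("a", "a"))),
    "two folds")
})

test_that("dinucleotide shuffle preserves the pair-count table exactly", {
  expect_equal(dinucleotide_shuffle("AAAA", 1, 1), "AAAA")
  set.seed(14)
  for (i in 1:40) {
    n <- sample(c(10, 37, 80), 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    for (r in dinucleotide_shuffle(s, n_refs = 2, seed = i)) {
      expect_identical(dinucleotide_counts(r), dinucleotide_counts(s))
    }
  }
  expect_equal(formals(dinucleotide_shuffle)$n_refs, 20)
  expect_error(dinucleotide_shuffle("A"), ">= 2")
})

test_that("attributions are zero for a zero-weight model and satisfy completeness", {
  m <- tiny_model(seed = 6)
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
             collapse = "")
  mz <- m
  mz$params <- fpkit:::nn_walk2(mz$params, mz$params, function(a, b) a * 0)
  atz <- attribution_scores(mz, s, target = "count", n_refs = 3, seed = 2,
                            use_ema = FALSE)
  expect_equal(max(abs(atz$attr)), 0)
  for (tgt in c("count", "footprint_whole_peak")) {
    at <- attribution_scores(m, s, target = tgt, n_refs = 5, seed = 3,
                             use_ema = FALSE)
    expect_lt(abs(sum(at$attr) - (at$value - at$ref_value)), 1e-3)
    expect_length(at$attr, 160L)
  }
  # windowed target restricted to one scale also satisfies completeness
  atw <- attribution_scores(m, s, target = "footprint_window",
                            scale_idx = 2, pos_range = c(60, 100),
                            n_refs = 4, seed = 5, use_ema = FALSE)
  expect_lt(abs(sum(atw$attr) - (atw$value - atw$ref_value)), 1e-3)
  expect_error(attribution_scores(m, s, target = "footprint_window"),
               "scale_idx")
})

test_that("the rescale multiplier is exact for linear maps", {
  x <- stats::rnorm(8); r <- stats::rnorm(8)
  mlt <- fpkit:::rescale_mult(x, r, function(z) 3 * z + 1,
                              function(z) rep(3, length(z)))
  expect_lt(max(abs(mlt - 3)), 1e-12)
})

test_that("attribution-based TF features are 405-dimensional with flagged correlations", {
  motif <- fx_motif()
  set.seed(16)
  ca <- stats::rnorm(400); fa <- stats::rnorm(400)
  v <- attribution_tf_features(ca, fa, site_start = 196, site_end = 204,
                               motif, motif_score = 5,
                               motif_scores_all = c(1, 5, 3))
  expect_length(v, 405L)
  expect_false(attr(v, "constant_attribution"))
  expect_equal(v[403], 1)                  # max score -> 1
  expect_equal(v[1:201], ca[101:301])
  expect_equal(v[202:402], fa[101:301])
  # direct-formula oracle for the correlation dims
  pattern <- colSums(motif$pfm * motif$logodds)
  expect_equal(v[404], stats::cor(ca[197:204], pattern))
  expect_equal(v[405], stats::cor(fa[197:204], pattern))
  # constant attribution -> correlation dims zero with a flag
  vc <- attribution_tf_features(rep(1, 400), fa, 196, 204, motif, 5,
                                c(1, 5, 3))
  expect_true(attr(vc, "constant_attribution"))
  expect_equal(vc[404], 0)
})

test_that("LoRA: zero-init identity, parameter-count formula, delta algebra", {
  cfg <- tiny_cfg()
  m <- tiny_model(seed = 8)
  expect_equal(lora_param_count(cfg, d_embed = 8, r = 2),
               (8 * 2 + 2 * 4) + (8 * 2 + 2 * 16 * 3))
  ad <- lora_init(cfg, d_embed = 8, r = 2, seed = 3)
  e <- stats::rnorm(8)
  delta <- fpkit:::lora_delta(ad, e)
  expect_true(all(vapply(delta, function(d) max(abs(d)) == 0, logical(1))))
  codes <- matrix(sample(1:4, 3 * 160, replace = TRUE), 3, 160)
  p0 <- predict_seqfp(m, codes, use_ema = FALSE)
  p1 <- predict_seqfp(m, codes, use_ema = FALSE, lora = ad,
                          embedding = e)
  expect_lt(max(abs(p0$z - p1$z)), 1e-5)
  # delta structure: rank-1 outer product per tap once factors are nonzero
  ad$layers[[1]]$A2[] <- stats::rnorm(8) * 0.3
  ad$layers[[1]]$B2[] <- stats::rnorm(2 * 48) * 0.3
  d1 <- fpkit:::lora_delta(ad, e)[[1]]
  left <- as.vector(matrix(e, 1) %*% ad$layers[[1]]$A1 %*%
                      ad$layers[[1]]$A2)
  right <- matrix(as.vector(matrix(e, 1) %*% ad$layers[[1]]$B1 %*%
                              ad$layers[[1]]$B2), 16, 3)
  for (tap in 1:3) {
    expect_equal(d1[(tap - 1) * 4 + 1:4, ], outer(left, right[, tap]))
  }
  expect_error(fpkit:::lora_delta(ad, c(1, 2)), "dimension")
})

test_that("adapter gradients match finite differences through the merge", {
  cfg <- tiny_cfg(window = 80L)
  m <- tiny_model(seed = 10, window = 80L)
  ad <- lora_init(cfg, d_embed = 4, r = 2, seed = 4)
  set.seed(10)
  for (ly in 1:2) {
    ad$layers[[ly]]$A2[] <- stats::rnorm(length(ad$layers[[ly]]$A2)) * 0.1
    ad$layers[[ly]]$B2[] <- stats::rnorm(length(ad$layers[[ly]]$B2)) * 0.1
  }
  e <- stats::rnorm(4)
  codes <- matrix(sample(1:4, 2 * 80, replace = TRUE), 2, 80)
  zt <- array(stats::rnorm(2 * 2 * 80), c(2, 2, 80))
  ztf <- fpkit:::s2p_flatten_targets(zt)
  loss_of <- function(ad) {
    d <- fpkit:::lora_delta(ad, e)
    f <- fpkit:::s2p_forward(m, codes, training = FALSE, lora_delta = d)
    mean((f$fp - ztf)^2)
  }
  d <- fpkit:::lora_delta(ad, e)
  fw <- fpkit:::s2p_forward(m, codes, training = FALSE, lora_delta = d)
  gr <- fpkit:::s2p_backward(m, fw, 2 * (fw$fp - ztf) / length(ztf),
                             lora_delta = d)
  gl <- fpkit:::lora_grads(ad, e, lapply(gr$blocks, `[[`, "gW"))
  eps <- 1e-6
  worst <- 0
  for (ly in 1:2) for (nm in c("A1", "A2", "B1", "B2")) {
    v <- ad$layers[[ly]][[nm]]
    for (i in sample(length(v), 2)) {
      a1 <- ad; a1$layers[[ly]][[nm]][i] <- v[i] + eps
      a2 <- ad; a2$layers[[ly]][[nm]][i] <- v[i] - eps
      gn <- (loss_of(a1) - loss_of(a2)) / (2 * eps)
      worst <- max(worst, abs(gn - gl[[ly]][[nm]][i]) / max(abs(gn), 1e-7))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("marginalization records the sample size and validates scramble input", {
  m <- tiny_model(seed = 12)
  motif <- fx_motif()
  set.seed(12)
  seqs <- vapply(1:8, function(i) {
    paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE), collapse = "")
  }, character(1))
  eff <- marginalize_motif_effect(m, motif, seqs, mode = "plant",
                                  n_regions = 5, seed = 3)
  expect_equal(eff$n_regions, 5L)
  expect_equal(dim(eff$delta), c(2L, 160L))
  expect_equal(formals(marginalize_motif_effect)$n_regions, 25000)
  expect_error(
    marginalize_motif_effect(m, motif, seqs, mode = "scramble",
                             sites = NULL),
    "at least one")
})
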