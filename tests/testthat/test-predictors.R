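# TF and nucleosome predictors and their evaluation metrics.

make_msf <- function(values, scales = c(20, 40, 60, 100, 160, 200),
                     width = 400) {
  m <- matrix(values, length(scales), width)
  rownames(m) <- scales
  structure(list(scores = m, scales = as.integer(scales)),
            class = "MultiscaleFootprint")
}

test_that("TF feature vectors have length 1,207 with ecdf motif score", {
  msf <- make_msf(stats::rnorm(6 * 400))
  v <- build_tf_features(msf, center_index = 200, motif_score = 9,
                         motif_scores_all = c(1, 4, 9, 2))
  expect_length(v, 1207L)
  expect_equal(v[1207], 1.0)            # maximum score -> 1.0
  v2 <- build_tf_features(msf, 200, 2, c(1, 4, 9, 2))
  expect_equal(v2[1207], 0.5)
  # window must stay inside the scored region and be fully scored
  expect_error(build_tf_features(msf, 50, 1, 1:4), "window")
  msf$scores[3, 180] <- NA
  expect_error(build_tf_features(msf, 200, 1, 1:4), "missing")
  # five scales violate the TF-model contract
  msf5 <- make_msf(stats::rnorm(5 * 400), scales = c(20, 40, 60, 100, 160))
  expect_error(build_tf_features(msf5, 200, 1, 1:4), "scales")
})

test_that("feature window is scale-major and mirrors correctly", {
  msf <- make_msf(seq_len(6 * 400))
  v <- build_tf_features(msf, 200, 1, 1:4)
  expect_equal(v[1:201], msf$scores[1, 100:300])
  expect_equal(v[202:402], msf$scores[2, 100:300])
  X <- matrix(v[1:1207], 1, 1207)
  m <- fpkit:::tf_mirror_features(X)
  expect_equal(m[1, 1:201], rev(v[1:201]))
  expect_equal(m[1, 1207], v[1207])
})

test_that("TF training excludes low-ChIP-overlap TFs and rejects single-class data", {
  set.seed(55)
  n <- 160
  X <- matrix(stats::rnorm(n * 1207), n, 1207)
  tf <- rep(c("GOOD", "BAD"), each = n / 2)
  lab <- c(rbinom(n / 2, 1, 0.5), rbinom(n / 2, 1, 0.05))
  lab[1:2] <- c(0, 1)                  # both classes present for GOOD
  expect_message(
    m <- fit_tf_model(X, lab, tf, seed = 2, epochs = 3),
    "BAD")
  expect_true("BAD" %in% m$excluded)
  expect_error(
    suppressMessages(fit_tf_model(X[tf == "GOOD", ],
                                  rep(1, n / 2), seed = 1)),
    "single-class")
})

test_that("the TF classifier separates linearly separable footprint patterns", {
  set.seed(56)
  # footprint-like features: smooth across positions, with bound sites
  # carrying a centred bump at every scale (mimics a real footprint dip)
  make_x <- function(n, lab) {
    bump <- exp(-((1:201 - 101)^2) / (2 * 15^2))
    X <- matrix(0, n, 1207)
    for (i in seq_len(n)) {
      for (s in 1:6) {
        base <- stats::filter(stats::rnorm(241), rep(1 / 41, 41),
                              sides = 2)[21:221]
        v <- base * 3 + lab[i] * bump * 1.5
        X[i, (s - 1) * 201 + 1:201] <- v
      }
    }
    X[, 1207] <- stats::runif(n)
    X
  }
  lab <- rbinom(500, 1, 0.5)
  X <- make_x(500, lab)
  m <- suppressMessages(fit_tf_model(X, lab, seed = 3, epochs = 30))
  lab_ho <- rbinom(200, 1, 0.5)
  ho <- make_x(200, lab_ho)
  p <- predict(m, ho)
  expect_true(all(p > 0 & p < 1))      # sigmoid head
  expect_gt(fpkit:::nn_auroc(p, lab_ho), 0.95)
})

test_that("top-decile precision matches its brute-force definition", {
  # single top-ranked true positive among 10
  expect_equal(precision_at_top_decile(c(9, 1:8, 0.5),
                                       c(1, rep(0, 9))), 1)
  # perfect ranking with 30% positives
  set.seed(57)
  lab <- c(rep(1, 30), rep(0, 70))
  sc <- c(stats::runif(30, 0.7, 1), stats::runif(70, 0, 0.6))
  expect_equal(precision_at_top_decile(sc, lab), 1)
  # random instances vs oracle, n <= 100
  for (i in 1:25) {
    n <- sample(10:100, 1)
    sc <- stats::runif(n)
    lab <- rbinom(n, 1, 0.4)
    k <- ceiling(n / 10)
    oracle <- mean(lab[order(-sc, seq_len(n))][1:k])
    expect_equal(precision_at_top_decile(sc, lab), oracle)
  }
  # binomial null: random scores, precision within 3 sigma of pi
  n <- 10000; pi0 <- 0.3
  lab <- rbinom(n, 1, pi0)
  sc <- stats::runif(n)
  prec <- precision_at_top_decile(sc, lab)
  expect_lt(abs(prec - pi0), 3 * sqrt(pi0 * (1 - pi0) / (n / 10)))
  expect_warning(precision_at_top_decile(rep(1, 20), rbinom(20, 1, 0.5)),
                 "equal")
  expect_error(precision_at_top_decile(1:5, rep(1, 5)), ">= 10")
})

test_that("nucleosome target rescaling anchors the 5th/95th percentiles", {
  set.seed(58)
  occ <- stats::rnorm(5000, 10, 3)
  cov <- stats::runif(5000, 0, 30)
  tg <- prepare_nucleosome_targets(occ, cov)
  usable <- occ[cov > 10]
  q <- stats::quantile(usable, c(0.05, 0.5, 0.95), names = FALSE)
  expect_equal(stats::quantile(tg$values[tg$mask], 0.05, names = FALSE), 0,
               tolerance = 1e-10)
  expect_equal(stats::quantile(tg$values[tg$mask], 0.95, names = FALSE), 1,
               tolerance = 1e-10)
  # median maps to the closed-form affine image
  expect_equal(stats::median(tg$values[tg$mask]),
               (q[2] - q[1]) / (q[3] - q[1]))
  # strict threshold: coverage exactly 10 is masked
  tg2 <- prepare_nucleosome_targets(c(1, 2, 3), c(10, 10.5, 11))
  expect_true(is.na(tg2$values[1]))
  # exact inversion
  expect_lt(max(abs(denormalize_nucleosome(tg, tg$values[tg$mask]) -
                      occ[cov > 10])), 1e-10)
  expect_error(prepare_nucleosome_targets(rep(5, 100),
                                          rep(20, 100)), "degenerate")
})

test_that("nucleosome model recovers a planted linear map and validates inputs", {
  set.seed(59)
  n <- 1200
  # smooth footprint-like features (running-mean filtered noise), as real
  # multiscale scores are; occupancy is a linear function of the
  # 100-bp-scale block mean
  X <- matrix(0, n, 1005)
  for (i in seq_len(n)) {
    for (s in 1:5) {
      X[i, (s - 1) * 201 + 1:201] <-
        stats::filter(stats::rnorm(241), rep(1 / 31, 31),
                      sides = 2)[21:221] * 4
    }
  }
  block4 <- (3 * 201 + 1):(4 * 201)
  y <- rowMeans(X[, block4]) * 5 + 0.02 * stats::rnorm(n)
  chrom <- sample(paste0("c", 1:6), n, replace = TRUE)
  split <- list(train = c("c1", "c2", "c3"), val = "c4",
                test = c("c5", "c6"))
  m <- fit_nucleosome_model(X, y, chrom, split, seed = 5, epochs = 60)
  expect_gt(m$test_cor, 0.9)
  expect_error(fit_nucleosome_model(cbind(X, X[, 1:201]), y, chrom, split),
               "1,005")
  bad <- list(train = c("c1", "c2"), val = "c2", test = "c3")
  expect_error(fit_nucleosome_model(X, y, chrom, bad), "two partitions")
})

test_that("nucleosome training is stable across seeds", {
  set.seed(60)
  n <- 600
  X <- matrix(0, n, 1005)
  for (i in seq_len(n)) {
    X[i, ] <- rep(stats::filter(stats::rnorm(241), rep(1 / 31, 31),
                                sides = 2)[21:221] * 4, 5)
  }
  y <- rowMeans(X[, 1:201]) * 3 + 0.4 * stats::rnorm(n)
  chrom <- sample(paste0("c", 1:5), n, replace = TRUE)
  split <- list(train = c("c1", "c2", "c3"), val = "c4", test = "c5")
  m1 <- fit_nucleosome_model(X, y, chrom, split, seed = 1, epochs = 30)
  m2 <- fit_nucleosome_model(X, y, chrom, split, seed = 2, epochs = 30)
  expect_lt(abs(m1$test_mse - m2$test_mse) /
              max(m1$test_mse, m2$test_mse), 0.1)
})

test_that("summit matching equals a brute-force all-pairs matcher", {
  # single predicted summit at 100, true at 130
  tr1 <- numeric(300); tr1[c(50, 130)] <- c(0.1, 1)
  pd1 <- numeric(300); pd1[100] <- 1
  r50 <- match_summits(pd1, tr1, cutoff_bp = 50)
  expect_equal(r50$precision, 1)
  r25 <- match_summits(pd1, tr1, cutoff_bp = 25)
  expect_equal(r25$precision, 0)
  # identical tracks are perfect
  set.seed(61)
  x <- pmax(0, stats::rnorm(500))
  x[sample(500, 5)] <- 3
  ri <- match_summits(x, x, cutoff_bp = 50)
  expect_equal(ri$precision, 1)
  expect_equal(ri$recall, 1)
  # random small instances vs oracle
  for (i in 1:10) {
    a <- numeric(400); b <- numeric(400)
    a[sample(5:395, 4)] <- stats::runif(4, 0.5, 1)
    b[sample(5:395, 5)] <- stats::runif(5, 0.5, 1)
    got <- match_summits(a, b, cutoff_bp = 30)
    ps <- find_summits(a); ts <- find_summits(b)
    prec <- mean(sapply(ps, function(p) any(abs(ts - p) <= 30)))
    rec <- mean(sapply(ts, function(t) any(abs(ps - t) <= 30)))
    expect_equal(got$precision, prec)
    expect_equal(got$recall, rec)
  }
  # no summits -> metrics missing
  r0 <- match_summits(numeric(100), tr1[1:100], 50)
  expect_true(is.na(r0$precision))
})

test_that("fitted TF models standardize footprint dims to mean 0, sd 1", {
  set.seed(62)
  n <- 120
  X <- matrix(stats::rnorm(n * 1207, mean = 2, sd = 3), n, 1207)
  lab <- rbinom(n, 1, 0.5)
  m <- suppressMessages(fit_tf_model(X, lab, seed = 7, epochs = 2))
  # reconstruct the standardized training matrix the model saw
  Xs <- sweep(sweep(X[, 1:1206], 2, m$mu[1:1206], "-"), 2,
              m$sd[1:1206], "/")
  expect_lt(max(abs(colMeans(Xs))), 0.5)  # balancing/augmentation shifts
})
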