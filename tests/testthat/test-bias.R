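# Bias-module data preparation and baselines (full CNN recovery runs in
# the acceptance suite).

test_that("constant counts give relative bias 1 and log target 0", {
  genome <- c(ctgA = paste(rep("ACGT", 500), collapse = ""),
              ctgB = paste(rep("TGCA", 500), collapse = ""),
              ctgC = paste(rep("GACT", 500), collapse = ""))
  counts <- lapply(genome, function(s) rep(30L, nchar(s)))
  # constant targets cannot be standardized: documented abort
  expect_error(prepare_bias_training_data(counts, genome, seed = 1),
               "constant")
})

test_that("coverage filter removes local means below 20 insertions/bp", {
  set.seed(3)
  genome <- c(a = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                        collapse = ""),
              b = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                        collapse = ""),
              c = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                        collapse = ""))
  lowc <- lapply(genome, function(s) rep(10L, nchar(s)))  # mean 10 < 20
  expect_error(prepare_bias_training_data(lowc, genome, seed = 1),
               "coverage")
})

test_that("training set is closed under reverse complement with equal bins", {
  fx <- fx_naked()
  prep <- prepare_bias_training_data(fx$sim$counts, fx$truth$genome,
                                     max_per_contig = 120, seed = 5)
  codes <- prep$train$codes
  keys <- apply(codes, 1, paste, collapse = ",")
  rc <- fpkit:::rc_codes(codes)
  rc_keys <- apply(rc, 1, paste, collapse = ",")
  # multiset closure: every window's reverse complement is present with
  # the same multiplicity
  expect_equal(sort(keys), sort(rc_keys))
  # no contig appears in two partitions
  expect_length(intersect(prep$split$train, prep$split$test), 0)
  expect_length(intersect(prep$split$train, prep$split$val), 0)
})

test_that("the stored target transform inverts exactly", {
  fx <- fx_naked()
  prep <- prepare_bias_training_data(fx$sim$counts, fx$truth$genome,
                                     max_per_contig = 60, seed = 6)
  z <- prep$val$y
  back <- z * prep$transform$sd + prep$transform$mu   # log10 relative bias
  expect_true(all(is.finite(back)))
  expect_lt(max(abs((back - prep$transform$mu) / prep$transform$sd - z)),
            1e-12)
})

test_that("CNN weight shapes match the declared architecture", {
  p <- fpkit:::bias_cnn_init()
  expect_equal(dim(p$c1$W), c(5L * 4L, 32L))
  expect_equal(dim(p$c2$W), c(5L * 32L, 32L))
  expect_equal(dim(p$c3$W), c(5L * 32L, 32L))
  expect_equal(dim(p$d1$W), c(12L * 32L, 32L))   # 101 -> 50 -> 25 -> 12
  expect_equal(dim(p$d2$W), c(32L, 1L))
})

test_that("a constant-output model yields a constant positive bias track", {
  p <- fpkit:::bias_cnn_init()
  p <- fpkit:::nn_walk2(p, p, function(a, b) a * 0)
  p$d2$b <- 0.7
  model <- structure(list(params = p,
                          transform = list(mu = -0.1, sd = 0.4)),
                     class = "BiasModel")
  trk <- predict_bias_track(model, paste(rep("ACGT", 60), collapse = ""))
  expect_true(all(abs(trk - 10^(0.7 * 0.4 - 0.1)) < 1e-12))
  expect_true(all(trk > 0))
  expect_error(predict_bias_track(model, ""), "1 bp")
})

test_that("bias track prediction equals per-position model calls", {
  fx <- fx_naked()
  prep <- prepare_bias_training_data(fx$sim$counts, fx$truth$genome,
                                     max_per_contig = 60, seed = 7)
  m <- fit_bias_model(prep, epochs = 2, patience = 2, seed = 8)
  s <- substr(fx$truth$genome[[1]], 1, 300)
  trk <- predict_bias_track(m, s)
  for (p in c(60, 150, 299)) {
    one <- predict_bias_track(m, s, positions = p)
    expect_equal(one, trk[p])
  }
})

test_that("k-mer baseline recovers planted frequency ratios exactly", {
  # toy corpus: insertions occur at AAA centres twice as often as AAA
  # occurs overall
  genome <- c(t1 = paste(rep(c("AAA", "CCC"), 50), collapse = ""))
  counts <- list(t1 = integer(300))
  # AAA centred at positions 2, 8, 14, ... (1-based centre of each AAA)
  aaa_centres <- seq(2, 300, by = 6)
  ccc_centres <- seq(5, 300, by = 6)
  counts$t1[aaa_centres] <- 2L
  counts$t1[ccc_centres] <- 1L
  bl <- baseline_bias(counts, genome, mode = "kmer", k = 3)
  # fg(AAA) = 2/3, bg(AAA) ~ 1/2 modulo boundary k-mers
  expect_gt(bl$model[["AAA"]], bl$model[["CCC"]])
  ratio <- bl$model[["AAA"]] / bl$model[["CCC"]]
  expect_equal(ratio, 2, tolerance = 0.1)
  # uniform insertions give bias 1 for every observed k-mer
  counts2 <- list(t1 = rep(1L, 300))
  bl2 <- baseline_bias(counts2, genome, mode = "kmer", k = 3)
  expect_true(all(abs(bl2$model - 1) < 1e-9))
})

test_that("pwm21 baseline uses a 21-bp window and positive tracks", {
  fx <- fx_naked()
  bl <- baseline_bias(fx$sim$counts, fx$truth$genome, mode = "pwm21")
  expect_equal(ncol(bl$model), 21L)
  trk <- bl$predict(substr(fx$truth$genome[[1]], 1, 400))
  inner <- trk[11:390]
  expect_true(all(is.finite(inner)))
  expect_true(all(inner > 0))
  expect_true(all(is.na(trk[1:10])))
})

test_that("two fits with the same seed give identical weights", {
  fx <- fx_naked()
  prep <- prepare_bias_training_data(fx$sim$counts, fx$truth$genome,
                                     max_per_contig = 40, seed = 9)
  m1 <- fit_bias_model(prep, epochs = 2, patience = 2, seed = 11)
  m2 <- fit_bias_model(prep, epochs = 2, patience = 2, seed = 11)
  expect_identical(m1$params, m2$params)
})
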