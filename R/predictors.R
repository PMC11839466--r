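# Supervised models on top of multiscale footprints: TF binding
# (classification against ChIP-style labels) and nucleosome occupancy
# (regression against chemical-mapping-style signal), with their evaluation
# procedures.

TF_SCALES <- c(20L, 40L, 60L, 100L, 160L, 200L)
NUC_SCALES <- c(20L, 40L, 60L, 100L, 160L)  # 200 bp excluded: adjacent-
                                            # nucleosome co-occupancy leak

#' Build the footprint-to-TF feature vector for one motif site
#'
#' Concatenates the per-position footprint scores over +/-100 bp (201
#' positions) at the six scales, scale-major (all 201 positions of scale 20,
#' then scale 40, ...), followed by the site's motif match score quantile-
#' transformed against the pooled score list of the same motif
#' (rank / (n + 1)). Total length 6 x 201 + 1 = 1,207. Standardization of
#' the footprint dimensions happens at model fitting with stored training
#' statistics.
#'
#' @param msf a `MultiscaleFootprint` for the region containing the site
#'   (must carry the six TF scales).
#' @param center_index 1-based position of the motif centre within the
#'   scored region.
#' @param motif_score the site's motif log-odds score.
#' @param motif_scores_all numeric vector of scores of all sites of this
#'   motif (the quantile reference).
#' @param half_width window half-width (default 100).
#' @return numeric vector of length 1,207.
#' @export
build_tf_features <- function(msf, center_index, motif_score,
                              motif_scores_all, half_width = 100L) {
  stopifnot(inherits(msf, "MultiscaleFootprint"))
  if (!identical(as.integer(msf$scales), TF_SCALES)) {
    stop("TF features require scales ", paste(TF_SCALES, collapse = "/"),
         " bp; got ", paste(msf$scales, collapse = "/"))
  }
  hw <- as.integer(half_width)
  lo <- center_index - hw
  hi <- center_index + hw
  if (lo < 1L || hi > ncol(msf$scores)) {
    stop("site window exceeds the scored region")
  }
  win <- msf$scores[, lo:hi, drop = FALSE]
  if (anyNA(win)) {
    stop("missing footprint values inside the site window; ",
         "the +/-", hw, " bp window must be fully scored")
  }
  q <- mean(motif_scores_all <= motif_score)   # empirical CDF: max -> 1.0
  v <- c(as.vector(t(win)), q)
  if (length(v) != 6L * (2L * hw + 1L) + 1L) {
    stop("feature length ", length(v), " does not match the TF-model ",
         "contract of ", 6L * (2L * hw + 1L) + 1L)
  }
  v
}

#' Quantile-transform motif scores to (0, 1]
#'
#' Empirical-CDF transform against the pooled score list of the same motif:
#' each score maps to the fraction of scores less than or equal to it, so
#' the maximum maps to exactly 1.
#' @param scores numeric vector.
#' @export
quantile_transform <- function(scores) {
  vapply(scores, function(s) mean(scores <= s), numeric(1))
}

#' Fit the footprint-to-TF binding classifier
#'
#' Two hidden layers (128 and 32 ReLU units) with a single sigmoid output,
#' binary cross-entropy, Adam, batch 128, early stopping on validation
#' loss. TFs whose motif sites overlap ChIP at 10\% or less are excluded
#' from training and testing (low motif or ChIP quality); reverse-
#' complement-derived copies (the footprint window mirrored) are appended
#' as augmentation, and negatives are subsampled or reused to a 1:1 ratio
#' with positives per TF.
#'
#' @param features numeric matrix (rows = sites, 1,207 columns).
#' @param labels 0/1 vector (1 = site overlaps a ChIP peak of the TF).
#' @param tf factor/character of the TF each site belongs to.
#' @param val_frac fraction held out for early stopping.
#' @param seed RNG seed.
#' @param epochs,patience,lr optimisation controls.
#' @return a `TFModel` with standardization statistics, the excluded TFs
#'   and augmentation tallies.
#' @export
fit_tf_model <- function(features, labels, tf = rep("TF1", length(labels)),
                         val_frac = 0.1, seed = 1, epochs = 100,
                         patience = 8, lr = 1e-3) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0, 1)))
  if (ncol(features) != 1207L) {
    stop("TF features must have 1,207 columns; got ", ncol(features))
  }
  tf <- as.character(tf)
  ov <- tapply(labels, tf, mean)
  excluded <- names(ov)[ov <= 0.10]
  if (length(excluded)) {
    message("excluding TF(s) with <=10% ChIP overlap: ",
            paste(excluded, collapse = ", "))
  }
  keep <- !(tf %in% excluded)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  tf <- tf[keep]
  if (length(unique(labels)) < 2L) {
    stop("single-class training set after TF exclusion")
  }
  set.seed(seed)
  # per-TF 1:1 negative balancing (sample with replacement if too few)
  bal_idx <- unlist(lapply(unique(tf), function(t) {
    it <- which(tf == t)
    pos <- it[labels[it] == 1]
    neg <- it[labels[it] == 0]
    if (length(pos) == 0L || length(neg) == 0L) return(it)
    c(pos, sample(neg, length(pos), replace = length(neg) < length(pos)))
  }))
  X <- features[bal_idx, , drop = FALSE]
  y <- labels[bal_idx]
  n_before_aug <- nrow(X)
  # reverse-complement augmentation: mirror the 201 positions of each scale
  mir <- tf_mirror_features(X)
  X <- rbind(X, mir)
  y <- c(y, y)
  # standardize footprint dims (first 1,206) with training statistics
  mu <- colMeans(X[, 1:1206, drop = FALSE])
  sdv <- apply(X[, 1:1206, drop = FALSE], 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- X
  Xs[, 1:1206] <- sweep(sweep(X[, 1:1206, drop = FALSE], 2L, mu, "-"),
                        2L, sdv, "/")
  fit <- nn_fit_mlp(Xs, matrix(y, ncol = 1L), hidden = c(128L, 32L),
                    loss = "bce", batch = 128L, epochs = epochs,
                    patience = patience, lr = lr, seed = seed,
                    val_idx = sample.int(nrow(Xs),
                                         max(1L, round(val_frac * nrow(Xs)))))
  structure(list(fit = fit, mu = mu, sd = sdv, excluded = excluded,
                 n_train = nrow(Xs), n_before_aug = n_before_aug),
            class = "TFModel")
}

# mirror the 201-position window of each scale (positions -100..100 ->
# 100..-100); the motif-score dimension is unchanged
tf_mirror_features <- function(X) {
  out <- X
  for (s in seq_len(6L)) {
    cols <- (s - 1L) * 201L + 1:201
    out[, cols] <- X[, rev(cols), drop = FALSE]
  }
  out
}

#' @export
print.TFModel <- function(x, ...) {
  cat("TFModel: MLP(128, 32) + sigmoid;", x$n_train, "training rows;",
      length(x$excluded), "TF(s) excluded\n")
  invisible(x)
}

#' Predict TF binding probabilities
#' @param object a `TFModel`.
#' @param features 1,207-column matrix.
#' @param ... unused.
#' @export
predict.TFModel <- function(object, features, ...) {
  features <- as.matrix(features)
  X <- features
  X[, 1:1206] <- sweep(sweep(features[, 1:1206, drop = FALSE], 2L,
                             object$mu, "-"), 2L, object$sd, "/")
  as.vector(nn_mlp_predict(object$fit, X))
}

#' Precision over the top decile of ranked sites
#'
#' Sites are ranked by score descending; precision is the positive fraction
#' among the top ceiling(n/10). Ties at the decile boundary are broken by
#' stable input order (earlier rows win); with all-equal scores this reduces
#' to the first ceiling(n/10) rows and a warning is emitted.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 truth.
#' @return precision in [0, 1].
#' @export
precision_at_top_decile <- function(scores, labels) {
  n <- length(scores)
  stopifnot(n == length(labels))
  if (n < 10L) stop("need >= 10 sites")
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; top decile by stable input order")
  }
  k <- ceiling(n / 10)
  ord <- order(-scores, seq_len(n))   # stable: ties by input order
  mean(labels[ord[seq_len(k)]])
}

#' Rescale nucleosome occupancy to percentile-anchored units
#'
#' Positions with local coverage <= `coverage_min` (strict "above" rule) are
#' masked; the remaining values are affinely rescaled so the empirical 5th
#' percentile maps to 0 and the 95th to 1 (values outside may exceed
#' [0, 1]). The transform is stored for exact inversion.
#'
#' @param occupancy per-position occupancy signal.
#' @param coverage per-position ATAC coverage.
#' @param coverage_min strict lower bound on usable coverage (default 10).
#' @return a `NucleosomeTargets`: list with `values` (rescaled, NA at
#'   masked positions), `mask`, `q05`, `q95`.
#' @export
prepare_nucleosome_targets <- function(occupancy, coverage,
                                       coverage_min = 10) {
  stopifnot(length(occupancy) == length(coverage))
  mask <- coverage > coverage_min
  usable <- occupancy[mask]
  if (length(usable) == 0L) stop("no position passes the coverage filter")
  q <- stats::quantile(usable, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("degenerate percentiles: q95 <= q05")
  values <- rep(NA_real_, length(occupancy))
  values[mask] <- (occupancy[mask] - q[1]) / (q[2] - q[1])
  structure(list(values = values, mask = mask, q05 = q[1], q95 = q[2]),
            class = "NucleosomeTargets")
}

#' Invert the nucleosome target rescaling
#' @param targets a `NucleosomeTargets`.
#' @param values rescaled values.
#' @export
denormalize_nucleosome <- function(targets, values) {
  values * (targets$q95 - targets$q05) + targets$q05
}

#' Fit the footprint-to-nucleosome regressor
#'
#' Hidden layers of 64 and 16 ReLU units with a linear output, MSE loss,
#' Adam, early stopping. Input is 5 scales x 201 positions = 1,005
#' dimensions (the 200-bp scale is excluded). The data split is by
#' chromosome: train/val/test chromosome sets must be disjoint.
#'
#' @param features matrix of 1,005 columns (scale-major as in
#'   [build_tf_features()], without the motif score).
#' @param targets rescaled occupancy values (rows aligned with features).
#' @param chrom chromosome of each row.
#' @param split list with `train`, `val`, `test` chromosome vectors.
#' @param seed RNG seed.
#' @param epochs,patience,batch,lr optimisation controls.
#' @return a `NucleosomeModel`.
#' @export
fit_nucleosome_model <- function(features, targets, chrom, split,
                                 seed = 1, epochs = 100, patience = 8,
                                 batch = 128, lr = 1e-3) {
  features <- as.matrix(features)
  if (ncol(features) != 1005L) {
    stop("nucleosome features must have 5 x 201 = 1,005 columns (the ",
         "200-bp scale is not an input); got ", ncol(features))
  }
  parts <- c(split$train, split$val, split$test)
  if (anyDuplicated(parts)) {
    stop("chromosome assigned to two partitions: ",
         paste(unique(parts[duplicated(parts)]), collapse = ", "))
  }
  ok <- !is.na(targets)
  features <- features[ok, , drop = FALSE]
  targets <- targets[ok]
  chrom <- chrom[ok]
  itr <- which(chrom %in% split$train)
  iva <- which(chrom %in% split$val)
  ite <- which(chrom %in% split$test)
  X <- features[c(itr, iva), , drop = FALSE]
  y <- matrix(targets[c(itr, iva)], ncol = 1L)
  fit <- nn_fit_mlp(X, y, hidden = c(64L, 16L), loss = "mse",
                    val_idx = length(itr) + seq_along(iva),
                    standardize = TRUE, batch = batch, epochs = epochs,
                    patience = patience, lr = lr, seed = seed)
  test_pred <- if (length(ite)) {
    as.vector(nn_mlp_predict(fit, features[ite, , drop = FALSE]))
  } else numeric(0)
  structure(list(fit = fit,
                 test_mse = if (length(ite)) {
                   mean((test_pred - targets[ite])^2)
                 } else NA_real_,
                 test_cor = if (length(ite) > 2L) {
                   stats::cor(test_pred, targets[ite])
                 } else NA_real_,
                 split = split),
            class = "NucleosomeModel")
}

#' @export
print.NucleosomeModel <- function(x, ...) {
  cat("NucleosomeModel: MLP(64, 16) + linear; test MSE",
      signif(x$test_mse, 4), "\n")
  invisible(x)
}

#' Predict nucleosome occupancy
#' @param object a `NucleosomeModel`.
#' @param features 1,005-column matrix.
#' @param ... unused.
#' @export
predict.NucleosomeModel <- function(object, features, ...) {
  as.vector(nn_mlp_predict(object$fit, as.matrix(features)))
}

#' Detect summits of a per-position track
#'
#' Strict local maxima above a prominence floor (default 0.2 of the track
#' maximum).
#' @param track numeric vector (NA allowed).
#' @param floor_frac prominence floor as a fraction of the track maximum.
#' @return integer positions of summits.
#' @export
find_summits <- function(track, floor_frac = 0.2) {
  n <- length(track)
  if (n < 3L) return(integer(0))
  floor_val <- floor_frac * max(track, na.rm = TRUE)
  x <- track
  x[is.na(x)] <- -Inf
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
          x[2:(n - 1)] >= floor_val) + 1L
}

#' Summit-level precision and recall between two tracks
#'
#' Precision: fraction of predicted summits with a true summit within
#' `cutoff_bp`; recall: fraction of true summits with a predicted summit
#' within `cutoff_bp` (50 or 75 bp are the usual choices).
#'
#' @param predicted_track,true_track aligned per-position tracks.
#' @param cutoff_bp maximum matching distance.
#' @param floor_frac summit prominence floor (see [find_summits()]).
#' @return list with `precision`, `recall`, `n_predicted`, `n_true`;
#'   metrics are NA when either track has no summit.
#' @export
match_summits <- function(predicted_track, true_track, cutoff_bp = 50,
                          floor_frac = 0.2) {
  stopifnot(cutoff_bp > 0)
  ps <- find_summits(predicted_track, floor_frac)
  ts <- find_summits(true_track, floor_frac)
  if (length(ps) == 0L || length(ts) == 0L) {
    return(list(precision = NA_real_, recall = NA_real_,
                n_predicted = length(ps), n_true = length(ts)))
  }
  dmin_p <- vapply(ps, function(p) min(abs(ts - p)), numeric(1))
  dmin_t <- vapply(ts, function(t) min(abs(ps - t)), numeric(1))
  list(precision = mean(dmin_p <= cutoff_bp),
       recall = mean(dmin_t <= cutoff_bp),
       n_predicted = length(ps), n_true = length(ts))
}
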