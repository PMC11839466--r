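# Background dispersion of the centre/(centre+flank) insertion ratio.
#
# On protein-free DNA the ratio's distribution depends only on sequence bias
# and local coverage. For each sampled naked-DNA position we record (centre
# bias, flank bias, coverage, observed ratio), find its nearest neighbours in
# standardized feature space, and summarise the neighbours' ratios by mean
# and SD. A small neural network then interpolates (mean, SD) from the
# features so footprint scoring can query the background cheaply.
#
# Because footprint scoring performs centre-vs-left and centre-vs-right
# tests, observations here are one-sided: ratio = centre / (centre + single
# flank), with the left flank used for table building (the feature space is
# side-symmetric). One model is fitted per footprint radius; window bias
# features are sums of per-bp bias over the window.

#' Build a background dispersion table from naked-DNA insertions
#'
#' @param counts list of per-bp insertion count vectors per contig
#'   (protein-free data).
#' @param bias list of per-bp bias vectors per contig (same shape).
#' @param radius footprint radius r: centre window is the 2r bp spanning
#'   positions p-r .. p+r-1; the flank is the 2r bp immediately left.
#' @param n_sample total positions sampled per depth replicate (split
#'   evenly across contigs).
#' @param k_nn number of nearest neighbours (self excluded; ties at the k-th
#'   distance broken by lowest row index).
#' @param downsample_fractions depth fractions added as thinned replicates of
#'   the sampled positions, widening the coverage range seen in training.
#' @param seed RNG seed.
#' @return a data.frame (`BackgroundTable`) with columns `centre_bias`,
#'   `flank_bias`, `coverage`, `ratio`, `bg_mean`, `bg_sd`, `fraction`, and
#'   attribute `radius`.
#' @export
build_background_table <- function(counts, bias, radius, n_sample = 100000,
                                   k_nn = 500,
                                   downsample_fractions = c(0.5, 0.2, 0.1,
                                                            0.05, 0.01),
                                   seed = 1) {
  stopifnot(radius >= 1, n_sample >= k_nn)
  set.seed(seed)
  r <- as.integer(radius)
  n_contig <- length(counts)
  per_contig <- ceiling(n_sample / n_contig)
  rows <- list()
  for (frac in c(1, downsample_fractions)) {
    obs <- lapply(names(counts), function(ctg) {
      cnt <- counts[[ctg]]
      if (frac < 1) cnt <- stats::rbinom(length(cnt), cnt, frac)
      b <- bias[[ctg]]
      b[is.na(b)] <- 0
      L <- length(cnt)
      lo <- 3L * r + 1L
      hi <- L - r
      if (hi <= lo) return(NULL)
      p <- sort(sample(lo:hi, min(per_contig, hi - lo + 1L)))
      cs <- cumsum(c(0, cnt))
      bs <- cumsum(c(0, b))
      centre <- cs[p + r] - cs[p - r]
      flank <- cs[p - r] - cs[p - 3L * r]
      centre_bias <- bs[p + r] - bs[p - r]
      flank_bias <- bs[p - r] - bs[p - 3L * r]
      cov <- centre + flank
      keep <- cov >= 1 & centre_bias > 0 & flank_bias > 0
      data.frame(centre_bias = centre_bias[keep],
                 flank_bias = flank_bias[keep],
                 coverage = cov[keep],
                 ratio = centre[keep] / cov[keep],
                 fraction = frac)
    })
    rows[[length(rows) + 1L]] <- do.call(rbind, obs)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < k_nn + 1L) {
    stop("fewer eligible positions (", if (is.null(tab)) 0 else nrow(tab),
         ") than k_nn + 1; reduce k_nn or simulate deeper")
  }
  nn <- knn_mean_sd(as.matrix(tab[, c("centre_bias", "flank_bias",
                                      "coverage")]),
                    tab$ratio, k = k_nn)
  tab$bg_mean <- nn$mean
  tab$bg_sd <- nn$sd
  attr(tab, "radius") <- r
  attr(tab, "k_nn") <- as.integer(k_nn)
  tab
}

# exhaustive chunked kNN (self excluded, ties at the boundary broken by
# lowest row index): mean and population SD of the neighbours' values
knn_mean_sd <- function(X, values, k) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
  n <- nrow(Z)
  sq <- rowSums(Z^2)
  out_mean <- numeric(n)
  out_sd <- numeric(n)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    D <- outer(sq[idx], sq, "+") - 2 * Z[idx, , drop = FALSE] %*% t(Z)
    for (i in seq_along(idx)) {
      d <- D[i, ]
      d[idx[i]] <- Inf                      # exclude self
      # partial selection, then stable tie-break by index at the boundary
      kth <- sort(d, partial = k)[k]
      cand <- which(d <= kth)
      if (length(cand) > k) {
        cand <- cand[order(d[cand], cand)][seq_len(k)]
      }
      nb <- values[cand]
      out_mean[idx[i]] <- mean(nb)
      out_sd[idx[i]] <- sqrt(mean((nb - mean(nb))^2))
    }
  }
  list(mean = out_mean, sd = out_sd)
}

#' Fit a dispersion model for one footprint radius
#'
#' A single-hidden-layer network (32 ReLU nodes, linear 2-output head for
#' background mean and SD) fitted with MSE loss, Adam and early stopping on
#' a random 10 percent validation split; a further 10 percent is held out as a test set
#' whose MSE is stored. Features are standardized with stored statistics.
#'
#' @param table a `BackgroundTable` from [build_background_table()].
#' @param radius footprint radius (defaults to the table's).
#' @param seed RNG seed.
#' @param epochs,patience,batch,lr,lr_decay optimisation controls.
#' @return a `DispersionModel`.
#' @export
fit_dispersion_model <- function(table, radius = attr(table, "radius"),
                                 seed = 1, epochs = 100, patience = 8,
                                 batch = 64, lr = 3e-3, lr_decay = 0.99) {
  if (nrow(table) < 100L) stop("background table needs >= 100 rows")
  X <- as.matrix(table[, c("centre_bias", "flank_bias", "coverage")])
  Y <- as.matrix(table[, c("bg_mean", "bg_sd")])
  set.seed(seed)
  n <- nrow(X)
  idx <- sample.int(n)
  n_te <- max(1L, round(0.1 * n))
  n_va <- max(1L, round(0.1 * n))
  te <- idx[seq_len(n_te)]
  va <- idx[n_te + seq_len(n_va)]
  keep <- idx[(n_te + n_va + 1L):n]
  # standardize the two outputs: the SD target is orders of magnitude
  # smaller than the mean at large radii and would otherwise be ignored by
  # the joint MSE (collapsing the SD head onto its floor)
  y_mu <- colMeans(Y)
  y_sd <- apply(Y, 2L, stats::sd)
  y_sd[y_sd < 1e-12] <- 1
  Ys <- sweep(sweep(Y, 2L, y_mu, "-"), 2L, y_sd, "/")
  fit <- nn_fit_mlp(X[c(keep, va), , drop = FALSE],
                    Ys[c(keep, va), , drop = FALSE],
                    hidden = 32L, loss = "mse",
                    val_idx = length(keep) + seq_along(va),
                    standardize = TRUE, batch = batch, epochs = epochs,
                    patience = patience, lr = lr, lr_decay = lr_decay,
                    seed = seed)
  predict_raw <- function(fit, Xq) {
    out <- nn_mlp_predict(fit, Xq)
    sweep(sweep(out, 2L, y_sd, "*"), 2L, y_mu, "+")
  }
  pred_te <- predict_raw(fit, X[te, , drop = FALSE])
  structure(list(fit = fit, y_mu = y_mu, y_sd = y_sd,
                 radius = as.integer(radius),
                 test_mse = mean((pred_te - Y[te, , drop = FALSE])^2)),
            class = "DispersionModel")
}

#' @export
print.DispersionModel <- function(x, ...) {
  cat("DispersionModel: radius", x$radius, "bp; test MSE",
      signif(x$test_mse, 4), "\n")
  invisible(x)
}

#' Create / extend a per-radius dispersion model registry
#'
#' Separate models are kept per footprint radius; querying an unregistered
#' radius is an explicit error.
#'
#' @param ... `DispersionModel` objects.
#' @return a `DispersionModelSet`.
#' @export
dispersion_set <- function(...) {
  models <- list(...)
  set <- structure(list(), class = "DispersionModelSet")
  for (m in models) set <- dispersion_register(set, m)
  set
}

#' @rdname dispersion_set
#' @param set a `DispersionModelSet`.
#' @param model a `DispersionModel`.
#' @param overwrite allow replacing an already-registered radius.
#' @export
dispersion_register <- function(set, model, overwrite = FALSE) {
  key <- as.character(model$radius)
  if (!is.null(set[[key]]) && !overwrite) {
    stop("radius ", key, " already registered; use overwrite = TRUE")
  }
  set[[key]] <- model
  class(set) <- "DispersionModelSet"
  set
}

#' @export
print.DispersionModelSet <- function(x, ...) {
  cat("DispersionModelSet: radii",
      paste(sort(as.integer(names(x))), collapse = ", "), "bp\n")
  invisible(x)
}

#' Predict the background ratio mean and SD
#'
#' @param set a `DispersionModelSet`.
#' @param radius footprint radius (must be registered).
#' @param centre_bias,flank_bias,coverage numeric vectors of features
#'   (window bias sums and total centre+flank insertion count).
#' @return list with `mean` and `sd` (SD clamped to >= 1e-4).
#' @export
predict_background <- function(set, radius, centre_bias, flank_bias,
                               coverage) {
  key <- as.character(as.integer(radius))
  model <- set[[key]]
  if (is.null(model)) {
    stop("no dispersion model registered for radius ", radius,
         "; registered radii: ", paste(names(set), collapse = ", "))
  }
  if (any(coverage <= 0)) stop("coverage must be positive")
  X <- cbind(centre_bias, flank_bias, coverage)
  out <- nn_mlp_predict(model$fit, X)
  out <- sweep(sweep(out, 2L, model$y_sd, "*"), 2L, model$y_mu, "+")
  list(mean = unname(out[, 1L]), sd = unname(pmax(out[, 2L], 1e-4)))
}
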