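# Cell-population operations: pseudo-bulk centre sampling on a kNN graph,
# PCA-based TF-binding-complexity scores per cCRE, and binding-timing AUC
# along a pseudo-time axis.

#' Sample pseudo-bulk centres and members from a cell embedding
#'
#' Scaffold cells are sampled, a directed kNN graph (k = `k_graph`) is built
#' among them, and the `n_centers` scaffolds with the lowest in-degree are
#' chosen as pseudo-bulk centres (low in-degree marks sparsely connected
#' neighbourhoods, preventing oversampling of dense regions). Each centre's
#' `k_members` nearest cells over all cells become its members. Ties in
#' in-degree and in distance are broken by cell index, making the
#' assignment deterministic given the seed.
#'
#' @param embedding cells x dims numeric matrix.
#' @param n_scaffold scaffold sample size (default 10,000).
#' @param k_graph kNN-graph degree among scaffolds (default 10).
#' @param n_centers number of pseudo-bulk centres (default 1,000).
#' @param k_members members per pseudo-bulk (default 5,000).
#' @param seed RNG seed.
#' @return a `PseudobulkAssignment`: list with `centers` (cell indices),
#'   `members` (list of member index vectors, each containing its centre),
#'   `in_degree` (named by scaffold index) and `params`.
#' @export
sample_pseudobulks <- function(embedding, n_scaffold = 10000, k_graph = 10,
                               n_centers = 1000, k_members = 5000,
                               seed = 1) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  n_scaffold <- min(n_scaffold, n)
  if (n_centers > n_scaffold) {
    stop("n_centers (", n_centers, ") exceeds n_scaffold (", n_scaffold, ")")
  }
  set.seed(seed)
  scaffold <- sort(sample.int(n, n_scaffold))
  Z <- embedding[scaffold, , drop = FALSE]
  k_g <- min(k_graph, n_scaffold - 1L)
  indeg <- integer(n_scaffold)
  sq <- rowSums(Z^2)
  chunk <- max(1L, floor(2e7 / n_scaffold))
  for (s in seq(1L, n_scaffold, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n_scaffold)
    D <- outer(sq[idx], sq, "+") - 2 * Z[idx, , drop = FALSE] %*% t(Z)
    for (i in seq_along(idx)) {
      d <- D[i, ]
      d[idx[i]] <- Inf
      nb <- order(d, seq_len(n_scaffold))[seq_len(k_g)]
      indeg[nb] <- indeg[nb] + 1L
    }
  }
  centers_scaffold <- order(indeg, seq_len(n_scaffold))[seq_len(n_centers)]
  centers <- scaffold[centers_scaffold]
  k_m <- min(k_members, n)
  sq_all <- rowSums(embedding^2)
  members <- lapply(centers, function(ci) {
    d <- sq_all + sum(embedding[ci, ]^2) -
      2 * as.vector(embedding %*% embedding[ci, ])
    sort(order(d, seq_len(n))[seq_len(k_m)])
  })
  structure(list(centers = centers, members = members,
                 in_degree = stats::setNames(indeg, scaffold),
                 params = list(n_scaffold = n_scaffold, k_graph = k_graph,
                               n_centers = n_centers,
                               k_members = k_members, seed = seed)),
            class = "PseudobulkAssignment")
}

#' @export
print.PseudobulkAssignment <- function(x, ...) {
  cat("PseudobulkAssignment:", length(x$centers), "centres,",
      length(x$members[[1]]), "members each (scaffold",
      x$params$n_scaffold, ", graph k", x$params$k_graph, ")\n")
  invisible(x)
}

#' TF-binding-pattern complexity of a cCRE
#'
#' TF binding scores of a cCRE across cell types are averaged into
#' fixed-width windows (default 10 bp); PCA on the resulting cell-type x
#' window matrix gives the complexity score: the minimum number of
#' principal components whose cumulative explained variance reaches the
#' threshold (default 98\%). A zero-variance matrix has complexity 1 (with
#' a flag): a single flat pattern.
#'
#' @param tf_scores cell-types x positions numeric matrix.
#' @param window_bp window width for position averaging.
#' @param variance_threshold cumulative explained-variance threshold.
#' @return a `ComplexityScore`: list with `score` (integer >= 1),
#'   `explained` (per-PC variance fractions), `flag_zero_variance`.
#' @export
binding_complexity <- function(tf_scores, window_bp = 10L,
                               variance_threshold = 0.98) {
  tf_scores <- as.matrix(tf_scores)
  if (nrow(tf_scores) == 0L || ncol(tf_scores) == 0L) {
    stop("tf_scores must be non-empty")
  }
  nw <- ncol(tf_scores) %/% window_bp
  if (nw == 0L) {
    W <- rowMeans(tf_scores)
    W <- matrix(W, ncol = 1L)
  } else {
    W <- vapply(seq_len(nw), function(i) {
      cols <- ((i - 1L) * window_bp + 1L):(i * window_bp)
      rowMeans(tf_scores[, cols, drop = FALSE])
    }, numeric(nrow(tf_scores)))
    W <- matrix(W, nrow = nrow(tf_scores))
  }
  vr <- tryCatch({
    pc <- stats::prcomp(W, center = TRUE, scale. = FALSE)
    pc$sdev^2
  }, error = function(e) numeric(0))
  vr <- vr[vr > 1e-12]
  if (length(vr) == 0L) {
    return(structure(list(score = 1L, explained = numeric(0),
                          flag_zero_variance = TRUE),
                     class = "ComplexityScore"))
  }
  expl <- vr / sum(vr)
  score <- which(cumsum(expl) >= variance_threshold - 1e-12)[1]
  structure(list(score = as.integer(score), explained = expl,
                 flag_zero_variance = FALSE),
            class = "ComplexityScore")
}

#' @export
print.ComplexityScore <- function(x, ...) {
  cat("ComplexityScore:", x$score,
      if (x$flag_zero_variance) "(zero-variance matrix)" else "", "\n")
  invisible(x)
}

#' Binding-timing AUC along pseudo-time
#'
#' The score series is min-max rescaled to [0, 1] and integrated by the
#' trapezoid rule over pseudo-time normalised to [0, 1]; values near 1 mark
#' sites whose binding signal rises early along the trajectory. A constant
#' series has no defined timing and returns NA with a flag. The AUC is
#' invariant to affine rescaling of a non-constant score series.
#'
#' @param scores binding scores along the trajectory.
#' @param pseudotime strictly increasing time grid (default equally
#'   spaced).
#' @return a `TimingAUC`: list with `auc` (in [0, 1] or NA), `flag_constant`.
#' @export
binding_timing_auc <- function(scores, pseudotime = seq_along(scores)) {
  if (length(scores) < 2L) stop("need >= 2 time points")
  if (length(scores) != length(pseudotime)) {
    stop("scores and pseudotime must align")
  }
  if (any(diff(pseudotime) <= 0)) {
    stop("pseudotime must be strictly increasing")
  }
  rng <- range(scores)
  if (rng[2] - rng[1] < 1e-300) {
    return(structure(list(auc = NA_real_, flag_constant = TRUE),
                     class = "TimingAUC"))
  }
  y <- (scores - rng[1]) / (rng[2] - rng[1])
  t <- (pseudotime - pseudotime[1]) /
    (pseudotime[length(pseudotime)] - pseudotime[1])
  auc <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(auc = auc, flag_constant = FALSE), class = "TimingAUC")
}

#' @export
print.TimingAUC <- function(x, ...) {
  cat("TimingAUC:", if (x$flag_constant) "NA (constant series)"
      else signif(x$auc, 4), "\n")
  invisible(x)
}

#' Threshold filter for trajectory-linked sites
#'
#' Reusable filter encoding the trajectory site-selection defaults: genes
#' with RNA-pseudo-time correlation above `rna_cor`, cCREs within
#' `tss_dist` bp of a related TSS with accessibility correlation above
#' `acc_cor`, and binding sites with TF-score-pseudo-time correlation above
#' `tf_cor`.
#'
#' @param sites data.frame with columns `rna_cor`, `tss_dist`, `acc_cor`,
#'   `tf_cor`.
#' @param rna_cor,tss_dist,acc_cor,tf_cor thresholds (defaults 0.5, 50e3,
#'   0.5, 0).
#' @return logical vector of retained rows.
#' @export
filter_trajectory_sites <- function(sites, rna_cor = 0.5, tss_dist = 5e4,
                                    acc_cor = 0.5, tf_cor = 0) {
  sites$rna_cor > rna_cor & abs(sites$tss_dist) <= tss_dist &
    sites$acc_cor > acc_cor & sites$tf_cor > tf_cor
}
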