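# Multiscale footprint scores.
#
# At a footprint radius r, each position p has a centre window (the 2r bp at
# p-r .. p+r-1) and equal-width flanking windows immediately left and right.
# A bound protein depletes insertions in the centre relative to the flanks,
# so the observed one-sided ratios centre/(centre+left) and
# centre/(centre+right) drop below the background expected from bias and
# coverage alone. Each side is tested with a lower-tailed z-test against the
# dispersion model's background (mean, SD); the higher of the two p-values
# is retained so that depletion on one side only is not called a footprint.
# Scores are -log10(P), then running-max and running-mean smoothed, which
# plateaus the score across the protected span.

# one-sided z statistics for one region; returns list(z, p) with NA at
# positions lacking a complete centre+flank window or with zero coverage
footprint_z_single <- function(counts, bias, set, radius) {
  r <- as.integer(radius)
  L <- length(counts)
  stopifnot(length(bias) == L)
  b <- bias
  b[is.na(b)] <- 0
  cs <- cumsum(c(0, counts))
  bs <- cumsum(c(0, b))
  z <- rep(NA_real_, L)
  lo <- 3L * r + 1L
  hi <- L - 3L * r + 1L
  if (hi < lo) return(z)
  p <- lo:hi
  centre <- cs[p + r] - cs[p - r]
  left <- cs[p - r] - cs[p - 3L * r]
  right <- cs[p + 3L * r] - cs[p + r]
  centre_b <- bs[p + r] - bs[p - r]
  left_b <- bs[p - r] - bs[p - 3L * r]
  right_b <- bs[p + 3L * r] - bs[p + r]
  z_side <- function(flank, flank_b) {
    covr <- centre + flank
    ok <- covr > 0 & centre_b > 0 & flank_b > 0
    zz <- rep(NA_real_, length(p))
    if (any(ok)) {
      bg <- predict_background(set, r, centre_b[ok], flank_b[ok], covr[ok])
      zz[ok] <- (centre[ok] / covr[ok] - bg$mean) / bg$sd
    }
    zz
  }
  zl <- z_side(left, left_b)
  zr <- z_side(right, right_b)
  z[p] <- pmax(zl, zr)                    # max z <=> max (retained) p-value
  z
}

# running max with half-width hw; NA poisons every window it touches,
# and positions whose window overruns the vector are NA
run_max <- function(x, hw) {
  if (hw == 0L) return(x)
  n <- length(x)
  out <- x
  for (o in seq_len(hw)) {
    lead <- c(x[(o + 1L):n], rep(NA_real_, o))
    lag <- c(rep(NA_real_, o), x[1L:(n - o)])
    out <- pmax(out, lead)
    out <- pmax(out, lag)
    out[is.na(lead) | is.na(lag)] <- NA_real_
  }
  out
}

run_mean <- function(x, hw) {
  if (hw == 0L) return(x)
  as.numeric(stats::filter(x, rep(1 / (2 * hw + 1), 2 * hw + 1), sides = 2))
}

#' Footprint score track at a single scale
#'
#' @param counts per-bp insertion counts for one region.
#' @param bias per-bp Tn5 bias for the same region.
#' @param set a `DispersionModelSet` with the radius registered.
#' @param radius footprint radius in bp (scale diameter / 2).
#' @param smooth_max,smooth_mean half-widths of the running-max and
#'   running-mean smoothing (default: the footprint radius).
#' @return a `FootprintTrack`: list with `score` (-log10 P, smoothed; NA =
#'   missing), `z`, `scale` (diameter), `radius`.
#' @export
score_footprints_single_scale <- function(counts, bias, set, radius,
                                          smooth_max = radius,
                                          smooth_mean = radius) {
  z <- footprint_z_single(counts, bias, set, radius)
  p <- stats::pnorm(z)
  raw <- -log10(pmax(p, 1e-300))
  score <- run_mean(run_max(raw, as.integer(smooth_max)),
                    as.integer(smooth_mean))
  structure(list(score = score, z = z, raw = raw,
                 scale = 2L * as.integer(radius),
                 radius = as.integer(radius)),
            class = "FootprintTrack")
}

#' @export
print.FootprintTrack <- function(x, ...) {
  cat("FootprintTrack: scale", x$scale, "bp;", sum(!is.na(x$score)),
      "scored positions of", length(x$score), "\n")
  invisible(x)
}

#' Multiscale footprints for one region
#'
#' @param counts,bias per-bp vectors for the region.
#' @param set a `DispersionModelSet` covering all requested radii.
#' @param scales footprint window diameters in bp (even, increasing).
#' @param ... passed to [score_footprints_single_scale()].
#' @return a `MultiscaleFootprint`: `scores` is a scales x positions matrix
#'   (rownames = scale diameters).
#' @export
compute_multiscale <- function(counts, bias, set,
                               scales = c(20, 40, 60, 100, 160, 200), ...) {
  scales <- as.integer(scales)
  if (any(scales %% 2L != 0L) || any(diff(scales) <= 0L)) {
    stop("scales must be even diameters in increasing order")
  }
  radii <- scales %/% 2L
  missing_r <- setdiff(as.character(radii), names(set))
  if (length(missing_r)) {
    stop("unregistered scale radius/radii ",
         paste(missing_r, collapse = ", "), "; registered: ",
         paste(names(set), collapse = ", "))
  }
  rows <- lapply(radii, function(r) {
    score_footprints_single_scale(counts, bias, set, r, ...)$score
  })
  m <- do.call(rbind, rows)
  rownames(m) <- scales
  structure(list(scores = m, scales = scales),
            class = "MultiscaleFootprint")
}

#' @export
print.MultiscaleFootprint <- function(x, ...) {
  cat("MultiscaleFootprint:", nrow(x$scores), "scales x", ncol(x$scores),
      "positions; scales", paste(x$scales, collapse = "/"), "bp\n")
  invisible(x)
}

#' Strand-aware aggregate profile around motif sites
#'
#' Windows of `2 * half_width + 1` bp centred on each site are extracted
#' from a per-bp track; windows of reverse-strand sites are mirrored so all
#' sites are aligned in the motif's reading direction, then averaged.
#' Sites whose window exceeds the contig bounds are skipped and tallied.
#'
#' @param track named list of per-bp numeric vectors (e.g. insertion counts
#'   or bias), one per contig.
#' @param sites data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param half_width half-width of the aggregation window.
#' @return an `AggregateProfile`: list with `profile` (length
#'   `2*half_width+1`), `n_sites`, `n_skipped`.
#' @export
aggregate_footprint <- function(track, sites, half_width = 100L) {
  if (nrow(sites) == 0L) stop("sites must be non-empty")
  hw <- as.integer(half_width)
  acc <- numeric(2L * hw + 1L)
  n_used <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    ctg <- sites$contig[i]
    v <- track[[ctg]]
    if (is.null(v)) { n_skipped <- n_skipped + 1L; next }
    centre <- (sites$start[i] + sites$end[i]) %/% 2L + 1L   # 1-based
    lo <- centre - hw; hi <- centre + hw
    if (lo < 1L || hi > length(v)) { n_skipped <- n_skipped + 1L; next }
    w <- v[lo:hi]
    if (identical(sites$strand[i], "-")) w <- rev(w)
    acc <- acc + w
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("all site windows exceeded region bounds")
  structure(list(profile = acc / n_used, n_sites = n_used,
                 n_skipped = n_skipped, half_width = hw),
            class = "AggregateProfile")
}

#' @export
print.AggregateProfile <- function(x, ...) {
  cat("AggregateProfile:", x$n_sites, "sites averaged (",
      x$n_skipped, "skipped ); width", length(x$profile), "bp\n")
  invisible(x)
}
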