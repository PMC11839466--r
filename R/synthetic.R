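# Seeded generator of ground-truth fixtures: genome, per-k-mer Tn5 bias,
# naked / chromatinized insertion data with planted occupancy events, and
# labelled motif sites. This is the test substrate for every other module:
# simulated data here emulate deproteinized (naked) DNA incubated with Tn5,
# and chromatin with TF- or nucleosome-sized protections at known positions.

#' Generate a synthetic genome with a known per-k-mer Tn5 bias
#'
#' Bases are drawn i.i.d. at the requested GC content. The true Tn5 bias of a
#' position is a lookup of the k-mer centred on it: log-bias per k-mer is
#' drawn from a seeded normal and exponentiated, so all multipliers are
#' positive and the per-position bias track is fully known.
#'
#' @param n_contigs number of contigs.
#' @param length length of each contig in bp (>= 1000).
#' @param gc GC content in (0, 1).
#' @param k k-mer size for the bias table (3 or 5).
#' @param log_sd standard deviation of the per-k-mer natural-log bias.
#' @param structure `"pwm_pair"` (default): the per-k-mer log bias is a sum
#'   of seeded-normal per-position base effects and pairwise position
#'   interaction effects, standardized to `log_sd` — mimicking the
#'   PWM-plus-interaction structure of real transposase preference, which a
#'   small convolutional model can learn and a centred 3-mer table can only
#'   partially capture. `"iid"`: one independent seeded-normal draw per
#'   k-mer (an unstructured lookup; useful as a hard reference case).
#' @param seed RNG seed; regeneration with the same seed is identical.
#' @return an object of class `SyntheticTruth`: list with `genome` (named
#'   character vector of contig sequences), `bias_table` (named numeric,
#'   4^k entries), `bias` (list of per-bp bias vectors, NA within k/2 of
#'   contig ends), `k`, `seed`.
#' @export
make_genome_and_bias <- function(n_contigs = 4, length = 10000, gc = 0.41,
                                 k = 5, log_sd = 0.6,
                                 structure = c("pwm_pair", "iid"),
                                 seed = 1) {
  structure <- match.arg(structure)
  if (length < 1000) stop("contig length must be >= 1,000 bp")
  if (!(k %in% c(3L, 5L))) stop("k must be 3 or 5")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(seed)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(names(base_p), length, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1))
  names(genome) <- paste0("ctg", seq_len(n_contigs))
  grid <- rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                          stringsAsFactors = FALSE))   # col 1 = position 1
  kmers <- do.call(paste0, grid)
  if (structure == "iid") {
    lb <- stats::rnorm(length(kmers), sd = log_sd)
  } else {
    code <- vapply(grid, function(col) match(col, c("A", "C", "G", "T")),
                   integer(length(kmers)))             # n x k base codes
    # transposase preference peaks a few bp off the dyad centre (the two
    # cut sites flank the insertion centre), so outer positions carry more
    # weight than the centre base
    pos_w <- if (k == 5L) c(1, 0.6, 0.4, 0.6, 1) else c(1, 0.6, 1)
    pos_eff <- matrix(stats::rnorm(k * 4L), k, 4L) * pos_w
    pos_eff <- pos_eff - rowMeans(pos_eff)
    lb_pos <- numeric(length(kmers))
    for (j in seq_len(k)) lb_pos <- lb_pos + pos_eff[j, code[, j]]
    lb_pair <- numeric(length(kmers))
    for (j1 in seq_len(k - 1L)) {
      for (j2 in (j1 + 1L):k) {
        pe <- matrix(stats::rnorm(16L), 4L, 4L)
        # double-centre: pure interaction, no positional main effects
        pe <- pe - outer(rowMeans(pe), rep(1, 4L)) -
          outer(rep(1, 4L), colMeans(pe)) + mean(pe)
        lb_pair <- lb_pair + pe[cbind(code[, j1], code[, j2])]
      }
    }
    # positional effects dominate real transposase preference (a plain PWM
    # is already a decent bias model); interactions get a 30% variance share
    pos_share <- 0.7
    lb <- sqrt(pos_share) * lb_pos / stats::sd(lb_pos) +
      sqrt(1 - pos_share) * lb_pair / stats::sd(lb_pair)
    lb <- lb / stats::sd(lb) * log_sd
  }
  # Tn5 inserts with a symmetric dyad: its sequence preference is reverse-
  # complement symmetric, so the truth table must be too (this is also what
  # makes reverse-complement training augmentation label-correct).
  names(lb) <- kmers
  rc <- chartr("ACGT", "TGCA", kmers)
  rc <- vapply(strsplit(rc, ""), function(x) paste(rev(x), collapse = ""),
               character(1))
  lb <- (lb + lb[rc]) / 2
  lb <- lb / stats::sd(lb) * log_sd
  bias_table <- exp(unname(lb))
  names(bias_table) <- kmers
  flank <- (k - 1L) %/% 2L
  bias <- lapply(genome, function(s) {
    kv <- substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
    b <- rep(NA_real_, nchar(s))
    b[(flank + 1L):(nchar(s) - flank)] <- unname(bias_table[kv])
    b
  })
  structure(list(genome = genome, bias_table = bias_table, bias = bias,
                 k = k, gc = gc, seed = seed),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", length(x$genome), "contig(s) of",
      nchar(x$genome[[1]]), "bp;", length(x$bias_table),
      paste0(x$k, "-mer"), "bias multipliers; seed", x$seed, "\n")
  invisible(x)
}

#' Define a protein occupancy event
#'
#' @param contig contig name.
#' @param center 1-based centre position of the protected span.
#' @param width protected width in bp.
#' @param protection fractional insertion suppression when bound, in [0, 1].
#' @param occupancy fraction of molecules bound, in [0, 1].
#' @return a one-row data.frame.
#' @export
occupancy_event <- function(contig, center, width, protection = 1,
                            occupancy = 1) {
  stopifnot(protection >= 0, protection <= 1, occupancy >= 0, occupancy <= 1,
            width >= 1)
  data.frame(contig = contig, center = as.integer(center),
             width = as.integer(width), protection = protection,
             occupancy = occupancy, stringsAsFactors = FALSE)
}

#' Simulate Tn5 insertions on the synthetic genome
#'
#' Per-bp insertion rates are proportional to the true sequence bias,
#' multiplied by `1 - occupancy * protection` inside each planted occupancy
#' event (protein protection scales insertion rates multiplicatively, so a
#' fully occupied, fully protective event yields zero insertions in its
#' span). Counts are Poisson with expected total `depth_per_bp * genome
#' size`. Insertions are paired into fragments with lengths drawn from a
#' sub-nucleosomal/nucleosomal mixture so the fragment-parsing path is
#' exercised; only insertion centres matter downstream.
#'
#' @param truth a `SyntheticTruth`.
#' @param depth_per_bp expected insertions per bp (before protection).
#' @param events data.frame of occupancy events (see [occupancy_event()]),
#'   or NULL for naked DNA.
#' @param seed RNG seed.
#' @param fragments_path optional path; if given, a fragment TSV
#'   (chrom, start, end, barcode, count) is written (gzipped if the path
#'   ends in .gz).
#' @param group barcode/sample id recorded in the fragment file.
#' @return list with `counts` (list of per-bp integer insertion vectors per
#'   contig), `rate` (expected per-bp rate), `fragments` (data.table),
#'   `fragments_path`.
#' @export
simulate_insertions <- function(truth, depth_per_bp = 20, events = NULL,
                                seed = 1, fragments_path = NULL,
                                group = "sample1") {
  stopifnot(inherits(truth, "SyntheticTruth"), depth_per_bp > 0)
  set.seed(seed)
  rate <- lapply(truth$bias, function(b) {
    r <- b
    r[is.na(r)] <- 0
    r
  })
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (!ev$contig %in% names(rate)) {
        stop("event on unknown contig: ", ev$contig)
      }
      L <- length(rate[[ev$contig]])
      lo <- ev$center - ev$width %/% 2L
      hi <- lo + ev$width - 1L
      if (lo < 1L || hi > L) stop("event outside contig bounds: ", ev$contig)
      rate[[ev$contig]][lo:hi] <- rate[[ev$contig]][lo:hi] *
        (1 - ev$occupancy * ev$protection)
    }
  }
  total_rate <- sum(unlist(lapply(rate, sum)))
  gsize <- sum(nchar(truth$genome))
  scale <- depth_per_bp * gsize / total_rate
  counts <- lapply(rate, function(r) stats::rpois(length(r), r * scale))
  names(counts) <- names(truth$genome)

  # pair insertion events into fragments so that parsing the fragment file
  # with the +4/-4 shift recovers exactly these insertion centres (each
  # fragment carries two events). Pairing is a seeded random matching within
  # each contig; an odd leftover event is not emitted.
  frags <- data.table::rbindlist(lapply(names(counts), function(ctg) {
    pos <- rep.int(seq_along(counts[[ctg]]), counts[[ctg]])
    if (length(pos) < 2L) return(NULL)
    pos <- pos[sample.int(length(pos))]
    n2 <- (length(pos) %/% 2L) * 2L
    p <- pos[seq(1L, n2, by = 2L)]
    q <- pos[seq(2L, n2, by = 2L)]
    a0 <- pmin(p, q) - 1L                 # 0-based left insertion centre
    b0 <- pmax(p, q) - 1L                 # 0-based right insertion centre
    keep <- b0 > a0 & a0 >= 4L            # distinct and shiftable
    data.table::data.table(chrom = ctg, start = a0[keep] - 4L,
                           end = b0[keep] + 5L, barcode = group, count = 1L)
  }))
  if (!is.null(fragments_path) && nrow(frags) > 0) {
    data.table::fwrite(frags, fragments_path, sep = "\t", col.names = FALSE,
                       compress = if (grepl("\\.gz$", fragments_path)) "gzip"
                                  else "none")
  }
  list(counts = counts, rate = lapply(rate, function(r) r * scale),
       fragments = frags, fragments_path = fragments_path,
       depth_per_bp = depth_per_bp)
}

#' Plant labelled motif sites on a synthetic genome
#'
#' The motif consensus (optionally with seeded point mutations) is written
#' into the genome at non-overlapping positions. Bound sites receive an
#' occupancy event covering the motif; unbound sites do not. The returned
#' truth has its sequence and per-bp bias re-derived after planting.
#'
#' @param truth a `SyntheticTruth` (modified copy returned).
#' @param motif a `MotifModel` (see [motif_from_pfm()]).
#' @param n_bound,n_unbound numbers of bound / unbound sites.
#' @param mutation_rate per-base probability of a planted-site mutation.
#' @param protection,occupancy protection parameters for bound sites.
#' @param width protected width of the bound-site event (default motif
#'   length rounded up to even).
#' @param margin minimum distance between site centres and to contig ends.
#' @param avoid optional data.frame with `contig`, `center`: candidate
#'   positions closer than `margin` to one of these are not used (lets two
#'   motifs be planted on the same genome without overlap).
#' @param seed RNG seed.
#' @return list with `truth` (updated), `sites` (data.frame: contig, start,
#'   end 0-based half-open, strand, label) and `events`.
#' @export
make_labelled_sites <- function(truth, motif, n_bound, n_unbound,
                                mutation_rate = 0, protection = 0.95,
                                occupancy = 0.9, width = NULL,
                                margin = 150, avoid = NULL, seed = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(seed)
  cons <- motif_consensus(motif)
  w <- nchar(cons)
  if (is.null(width)) width <- w + (w %% 2L)
  n_total <- n_bound + n_unbound
  # spread candidate slots across contigs, evenly spaced, then sample
  slots <- data.table::rbindlist(lapply(names(truth$genome), function(ctg) {
    L <- nchar(truth$genome[[ctg]])
    cen <- seq(margin, L - margin, by = 2L * margin)
    if (length(cen) == 0L) return(NULL)
    data.table::data.table(contig = ctg, center = as.integer(cen))
  }))
  if (!is.null(avoid) && nrow(avoid) > 0) {
    keep <- vapply(seq_len(nrow(slots)), function(i) {
      near <- avoid$contig == slots$contig[i] &
        abs(avoid$center - slots$center[i]) < margin
      !any(near)
    }, logical(1))
    slots <- slots[keep, ]
  }
  if (nrow(slots) < n_total) {
    stop("genome too short to host ", n_total,
         " non-overlapping sites; use longer contigs")
  }
  pick <- slots[sample.int(nrow(slots), n_total), ]
  lab <- c(rep(1L, n_bound), rep(0L, n_unbound))[sample.int(n_total)]
  bases <- c("A", "C", "G", "T")
  events <- NULL
  for (i in seq_len(nrow(pick))) {
    ctg <- pick$contig[i]
    cen <- pick$center[i]
    start1 <- cen - w %/% 2L               # 1-based motif start
    site_seq <- strsplit(cons, "")[[1]]
    if (mutation_rate > 0) {
      mut <- stats::runif(w) < mutation_rate
      if (any(mut)) {
        site_seq[mut] <- vapply(site_seq[mut], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
    }
    s <- truth$genome[[ctg]]
    substr(s, start1, start1 + w - 1L) <- paste(site_seq, collapse = "")
    truth$genome[[ctg]] <- s
    if (lab[i] == 1L) {
      events <- rbind(events, occupancy_event(ctg, cen, width,
                                              protection, occupancy))
    }
  }
  # re-derive per-bp bias from the edited sequence
  flank <- (truth$k - 1L) %/% 2L
  truth$bias <- lapply(truth$genome, function(s) {
    kv <- substring(s, seq_len(nchar(s) - truth$k + 1L),
                    seq_len(nchar(s) - truth$k + 1L) + truth$k - 1L)
    b <- rep(NA_real_, nchar(s))
    b[(flank + 1L):(nchar(s) - flank)] <- unname(truth$bias_table[kv])
    b
  })
  sites <- data.frame(contig = pick$contig,
                      start = pick$center - w %/% 2L - 1L,  # 0-based
                      end = pick$center - w %/% 2L - 1L + w,
                      strand = "+", label = lab,
                      stringsAsFactors = FALSE)
  list(truth = truth, sites = sites, events = events)
}

#' Write a synthetic genome as FASTA
#' @param truth a `SyntheticTruth`.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(truth, path) {
  dss <- Biostrings::DNAStringSet(truth$genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Assemble a complete synthetic chromatin study
#'
#' One-stop generator of the fixtures needed to exercise the whole
#' footprinting stack end to end: a genome with known k-mer Tn5 bias, a
#' planted TF motif whose bound instances carry TF-sized protection and a
#' second, nucleosome-anchoring motif whose instances carry ~140-bp
#' protection, deep naked-DNA insertion data, fitted per-radius background
#' dispersion models, chromatinized insertion data, tiled regions, and
#' batched footprint z-statistic targets for the sequence model.
#'
#' @param n_contigs,contig_length genome geometry.
#' @param region_width tiled region width in bp (the sequence-model
#'   window).
#' @param depth_naked,depth_chromatin expected insertions/bp for the
#'   naked-DNA and chromatin simulations.
#' @param tf_motif,nuc_motif `MotifModel`s to plant (defaults built in).
#' @param n_tf_bound,n_tf_unbound,n_nuc TF site and nucleosome-anchor
#'   counts.
#' @param protection,occupancy TF protection parameters; nucleosome events
#'   use protection 0.85 / occupancy 0.85 over 140 bp.
#' @param scales footprint diameters for the targets.
#' @param radii dispersion radii to fit (defaults to `scales / 2`).
#' @param n_sample_bg,k_nn dispersion table size per depth fraction and
#'   neighbour count.
#' @param seed master seed; all internal seeds derive from it.
#' @return list with `truth`, `tf_motif`, `nuc_motif`, `tf_sites`,
#'   `nuc_sites`, `events`, `naked`, `chromatin`, `dispersion`,
#'   `regions` (data.frame contig/start/end, 0-based), `codes`
#'   (regions x width base codes), `bias_mat`, `counts_mat`, `targets`
#'   (regions x scales x width z array), `n_obs`, `chrom`.
#' @export
make_chromatin_study <- function(n_contigs = 4, contig_length = 16000,
                                 region_width = 800, depth_naked = 60,
                                 depth_chromatin = 80, tf_motif = NULL,
                                 nuc_motif = NULL, n_tf_bound = 30,
                                 n_tf_unbound = 30, n_nuc = 30,
                                 protection = 0.95, occupancy = 0.9,
                                 scales = c(20, 40, 60, 100, 160, 200),
                                 radii = scales %/% 2,
                                 n_sample_bg = 1200, k_nn = 60, seed = 1) {
  if (is.null(tf_motif)) {
    pfm <- matrix(c(0.05, 0.05, 0.10, 0.80,  0.05, 0.10, 0.05, 0.80,
                    0.10, 0.10, 0.70, 0.10,  0.10, 0.70, 0.10, 0.10,
                    0.10, 0.10, 0.70, 0.10,  0.10, 0.70, 0.10, 0.10,
                    0.80, 0.05, 0.10, 0.05,  0.80, 0.05, 0.05, 0.10),
                  nrow = 4)
    tf_motif <- motif_from_pfm(pfm, name = "TF_planted")
  }
  if (is.null(nuc_motif)) {
    pfm2 <- matrix(c(0.80, 0.05, 0.05, 0.10,  0.05, 0.80, 0.10, 0.05,
                     0.05, 0.10, 0.80, 0.05,  0.80, 0.05, 0.05, 0.10,
                     0.05, 0.80, 0.10, 0.05,  0.05, 0.10, 0.80, 0.05,
                     0.80, 0.05, 0.05, 0.10,  0.05, 0.80, 0.10, 0.05),
                   nrow = 4)
    nuc_motif <- motif_from_pfm(pfm2, name = "NUC_anchor")
  }
  truth <- make_genome_and_bias(n_contigs = n_contigs,
                                length = contig_length, gc = 0.45, k = 5,
                                log_sd = 0.6, seed = seed)
  tf <- make_labelled_sites(truth, tf_motif, n_bound = n_tf_bound,
                            n_unbound = n_tf_unbound, mutation_rate = 0,
                            protection = protection, occupancy = occupancy,
                            width = 20, margin = 200, seed = seed + 1)
  truth <- tf$truth
  tf_centres <- data.frame(contig = tf$sites$contig,
                           center = (tf$sites$start + tf$sites$end) %/% 2 + 1)
  nuc <- make_labelled_sites(truth, nuc_motif, n_bound = n_nuc,
                             n_unbound = 0, mutation_rate = 0,
                             protection = 0.85, occupancy = 0.85,
                             width = 140, margin = 200,
                             avoid = tf_centres, seed = seed + 2)
  truth <- nuc$truth
  events <- rbind(tf$events, nuc$events)
  naked <- simulate_insertions(truth, depth_per_bp = depth_naked,
                               seed = seed + 3)
  set <- dispersion_set()
  for (r in radii) {
    tab <- build_background_table(naked$counts, truth$bias, radius = r,
                                  n_sample = n_sample_bg, k_nn = k_nn,
                                  seed = seed + 100 + r)
    set <- dispersion_register(set,
                               fit_dispersion_model(tab, seed = seed + r,
                                                    epochs = 30,
                                                    batch = 128))
  }
  chromatin <- simulate_insertions(truth, depth_per_bp = depth_chromatin,
                                   events = events, seed = seed + 4)
  # tile regions, keeping a margin for the footprint windows
  regions <- do.call(rbind, lapply(names(truth$genome), function(ctg) {
    L <- nchar(truth$genome[[ctg]])
    starts <- seq(200L, L - region_width - 200L, by = region_width)
    data.frame(contig = ctg, start = starts,
               end = starts + region_width)          # 0-based half-open
  }))
  n <- nrow(regions)
  codes <- matrix(0L, n, region_width)
  counts_mat <- matrix(0, n, region_width)
  bias_mat <- matrix(0, n, region_width)
  for (i in seq_len(n)) {
    ctg <- regions$contig[i]
    idx <- (regions$start[i] + 1L):regions$end[i]
    codes[i, ] <- seq_to_codes(substr(truth$genome[[ctg]],
                                      regions$start[i] + 1L,
                                      regions$end[i]))
    counts_mat[i, ] <- chromatin$counts[[ctg]][idx]
    b <- truth$bias[[ctg]][idx]
    b[is.na(b)] <- 1
    bias_mat[i, ] <- b
  }
  targets <- compute_footprint_targets(counts_mat, bias_mat, set,
                                       scales = scales)
  list(truth = truth, tf_motif = tf_motif, nuc_motif = nuc_motif,
       tf_sites = tf$sites, nuc_sites = nuc$sites, events = events,
       naked = naked, chromatin = chromatin, dispersion = set,
       regions = regions, codes = codes, bias_mat = bias_mat,
       counts_mat = counts_mat, targets = targets,
       n_obs = rowSums(counts_mat), chrom = regions$contig,
       scales = as.integer(scales), seed = seed)
}
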