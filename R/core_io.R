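# Input parsing and count-tensor construction.
#
# Coordinate convention: 0-based half-open (BED-native) everywhere in this
# file's external interfaces; GRanges objects used internally are the usual
# 1-based closed representation and converted at the boundary.

#' Parse a fragment file and emit Tn5 insertion events
#'
#' Fragment files are TSV (optionally gzipped) with columns
#' `chrom, start, end[, barcode[, count]]`, 0-based half-open. Each fragment
#' represents one transposition pair; the two insertion centres are obtained
#' by shifting the ends +4/-4 to the middle of the 9-bp staggered Tn5 cut:
#' left insertion = `start + 4`, right insertion = `(end - 1) - 4` (both
#' 0-based positions). Fragments shorter than 10 bp are dropped (their
#' shifted ends would touch or cross) and tallied. A `count` column
#' multiplies the weight of both events.
#'
#' @param path fragment TSV path (`.gz` allowed).
#' @param shift apply the +4/-4 shift; set `FALSE` (CLI `--pre-shifted`) for
#'   files whose ends were already centred upstream.
#' @return a `data.table` with columns `contig`, `pos` (0-based insertion
#'   centre), `group`, `weight`, and attributes `dropped` (count-weighted
#'   dropped fragments) and `n_fragments` (count-weighted total).
#' @export
parse_and_shift_fragments <- function(path, shift = TRUE) {
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), header = FALSE, sep = "\t",
                      colClasses = list(character = 1))
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1))
  }
  if (ncol(dt) < 3L) stop("fragment file needs >= 3 columns: ", path)
  if (ncol(dt) == 3L) dt[, V4 := "all"]
  if (ncol(dt) == 4L) dt[, V5 := 1L]
  dt <- dt[, 1:5]
  data.table::setnames(dt, c("contig", "start", "end", "group", "count"))
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                 dt$start != floor(dt$start) | dt$end != floor(dt$end))
  if (length(bad)) stop("malformed fragment row at line ", bad[1], " of ", path)
  if (any(dt$start < 0 | dt$end < 0)) {
    stop("negative coordinates at line ", which(dt$start < 0 | dt$end < 0)[1],
         " of ", path)
  }
  if (any(dt$end <= dt$start)) {
    stop("end <= start at line ", which(dt$end <= dt$start)[1], " of ", path)
  }
  if (any(dt$count < 1)) stop("count column must be >= 1 in ", path)
  min_len <- if (shift) 10L else 1L
  drop <- dt$end - dt$start < min_len
  dropped <- sum(dt$count[drop])
  total <- sum(dt$count)
  dt <- dt[!drop]
  off <- if (shift) 4L else 0L
  ev <- data.table::rbindlist(list(
    dt[, .(contig, pos = start + off, group, weight = count)],
    dt[, .(contig, pos = end - 1L - off, group, weight = count)]
  ))
  data.table::setattr(ev, "dropped", dropped)
  data.table::setattr(ev, "n_fragments", total)
  ev[]
}

#' Read regions from a BED file
#' @param path BED path.
#' @return a `GRanges`.
#' @export
read_regions_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Resize regions about their centres
#'
#' Used e.g. to extend peak summits by a fixed flank or resize peaks to a
#' uniform width while preserving centres.
#' @param regions a `GRanges`.
#' @param width target width in bp.
#' @export
resize_regions <- function(regions, width) {
  if (width <= 0) stop("width must be > 0")
  GenomicRanges::resize(regions, width = width, fix = "center")
}

#' Count insertion events into a group x region x position tensor
#'
#' @param events insertion events from [parse_and_shift_fragments()] (or any
#'   data.table with `contig`, `pos`, `group`, `weight`).
#' @param regions a `GRanges` of uniform width.
#' @param groups group levels (default: sorted unique groups in `events`).
#' @param contigs optional character vector of known contig names; a region
#'   on a contig outside this universe is an error.
#' @return an `InsertionMatrix`: list with `counts` (array groups x regions
#'   x width), `regions`, `groups`, and tallies `in_region`,
#'   `out_of_region`.
#' @export
count_insertions <- function(events, regions, groups = NULL, contigs = NULL) {
  if (length(regions) == 0L) stop("regions must be non-empty")
  w <- unique(GenomicRanges::width(regions))
  if (length(w) != 1L) stop("regions must have uniform width")
  if (!is.null(contigs)) {
    unknown <- setdiff(as.character(GenomicRanges::seqnames(regions)), contigs)
    if (length(unknown)) stop("region on unknown contig: ", unknown[1])
  }
  if (is.null(groups)) groups <- sort(unique(events$group))
  ev <- events[events$group %in% groups]
  arr <- array(0, dim = c(length(groups), length(regions), w),
               dimnames = list(groups, NULL, NULL))
  # positions (0-based) -> 1-based GRanges points
  pts <- GenomicRanges::GRanges(ev$contig,
                                IRanges::IRanges(ev$pos + 1L, ev$pos + 1L))
  hits <- GenomicRanges::findOverlaps(pts, regions)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    offset <- ev$pos[qh] - (GenomicRanges::start(regions)[sh] - 1L)  # 0-based
    gi <- match(ev$group[qh], groups)
    dt <- data.table::data.table(g = gi, r = sh, p = offset + 1L,
                                 wgt = ev$weight[qh])
    agg <- dt[, .(wgt = sum(wgt)), by = .(g, r, p)]
    arr[cbind(agg$g, agg$r, agg$p)] <- agg$wgt
  }
  # an event overlapping multiple regions is counted once per region in the
  # tensor; the in-region tally counts distinct events
  in_region <- sum(ev$weight[unique(qh)])
  structure(list(counts = arr, regions = regions, groups = groups,
                 in_region = in_region,
                 out_of_region = sum(ev$weight) - in_region),
            class = "InsertionMatrix")
}

#' @export
print.InsertionMatrix <- function(x, ...) {
  d <- dim(x$counts)
  cat("InsertionMatrix:", d[1], "group(s) x", d[2], "region(s) x", d[3],
      "bp;", sum(x$counts), "in-region insertions\n")
  invisible(x)
}

## ---- motifs -----------------------------------------------------------------

#' Build a motif model from a position frequency matrix
#'
#' Columns are normalised to sum to one after adding a pseudocount; the
#' log-odds matrix against the background is rounded to a fixed precision
#' (`granularity`) so that match p-values can be computed by exact dynamic
#' programming over the integerised score distribution.
#'
#' @param pfm 4 x w numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param name motif name.
#' @param background background base frequencies (A, C, G, T); default
#'   uniform.
#' @param pseudocount added to the PFM before normalisation.
#' @param granularity score discretisation unit for the exact p-value DP.
#' @return a `MotifModel`.
#' @export
motif_from_pfm <- function(pfm, name = "motif",
                           background = rep(0.25, 4), pseudocount = 0.01,
                           granularity = 1e-4) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (any(pfm < 0)) stop("PFM entries must be >= 0")
  background <- background / sum(background)
  p <- sweep(pfm + pseudocount, 2L, colSums(pfm + pseudocount), "/")
  lo <- log2(p / background)
  if (any(!is.finite(lo))) stop("non-finite log-odds; check background")
  iscore <- round(lo / granularity)
  storage.mode(iscore) <- "integer"
  rownames(p) <- rownames(lo) <- rownames(iscore) <- c("A", "C", "G", "T")
  structure(list(name = name, pfm = p, background = background,
                 logodds = lo, iscore = iscore, granularity = granularity),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat("MotifModel", x$name, "- length", ncol(x$pfm), "consensus",
      motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a motif (highest-probability base per column)
#' @param motif a `MotifModel`.
#' @export
motif_consensus <- function(motif) {
  paste(c("A", "C", "G", "T")[apply(motif$pfm, 2L, which.max)], collapse = "")
}

#' Reverse-complement a motif model
#' @param motif a `MotifModel`.
#' @export
motif_reverse_complement <- function(motif) {
  rc <- motif$pfm[4:1, rev(seq_len(ncol(motif$pfm))), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  out <- motif_from_pfm(rc, name = paste0(motif$name, "_rc"),
                        background = motif$background[4:1], pseudocount = 0,
                        granularity = motif$granularity)
  out
}

#' Read motifs from a JASPAR-format text file
#'
#' Supports the JASPAR 2020+ format: a `>` header line followed by four rows
#' `A [ ... ]` etc.
#' @param path file path.
#' @param ... passed to [motif_from_pfm()].
#' @return a list of `MotifModel`.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    name <- sub("^>\\s*", "", lines[h])
    rows <- lines[(h + 1):(h + 4)]
    vals <- lapply(rows, function(r) {
      as.numeric(strsplit(gsub("^[ACGT]\\s*\\[?|\\]", "", r), "\\s+")[[1]] |>
                   (\(x) x[nzchar(x)])())
    })
    pfm <- do.call(rbind, vals)
    out[[name]] <- motif_from_pfm(pfm, name = name, ...)
  }
  out
}

#' Read motifs from a MEME minimal-format text file
#' @param path file path.
#' @param ... passed to [motif_from_pfm()].
#' @return a list of `MotifModel`.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  heads <- grep("^MOTIF", lines)
  out <- list()
  for (h in heads) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[h])), "\\s+")[[1]][1]
    li <- grep("^letter-probability matrix", lines[h:length(lines)])[1] + h - 1L
    wtxt <- sub(".*w=\\s*(\\d+).*", "\\1", lines[li])
    w <- as.integer(wtxt)
    rows <- lines[(li + 1):(li + w)]
    pfm <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4)))
    out[[name]] <- motif_from_pfm(t(pfm), name = name, ...)
  }
  out
}

## ---- motif scanning with exact p-values -------------------------------------

# exact pmf of the integerised motif score under independent background
# positions: named by integer offset from the minimum achievable sum
motif_null_pmf <- function(motif) {
  is <- motif$iscore
  w <- ncol(is)
  lo <- sum(apply(is, 2L, min))
  hi <- sum(apply(is, 2L, max))
  pmf <- numeric(hi - lo + 1L)
  # start: delta at 0 relative to cumulative minimum
  pmf[1L] <- 1
  cur_min <- 0L
  cur_len <- 1L
  for (j in seq_len(w)) {
    col <- is[, j]
    cmin <- min(col)
    new_min <- cur_min + cmin
    new_len <- cur_len + (max(col) - cmin)
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- col[b] - cmin
      idx <- seq_len(cur_len) + off
      new[idx] <- new[idx] + pmf[seq_len(cur_len)] * motif$background[b]
    }
    pmf <- new
    cur_min <- new_min
    cur_len <- new_len
  }
  list(pmf = pmf, min = cur_min)
}

# p-value of integer score s: P(bg >= s) via reverse cumulative sum
motif_pvalue_fun <- function(motif) {
  null <- motif_null_pmf(motif)
  tail <- rev(cumsum(rev(null$pmf)))
  function(iscore_sum) {
    idx <- iscore_sum - null$min + 1L
    p <- ifelse(idx <= 1L, 1, ifelse(idx > length(tail), 0, tail[pmax(idx, 1L)]))
    pmin(pmax(p, 0), 1)
  }
}

#' Scan a sequence for motif matches with exact p-values
#'
#' Both strands are scanned. The match score of a window is the sum of
#' per-position log-odds (integerised at the motif's granularity); its
#' p-value is the exact tail probability of that score under independent
#' background positions, computed by dynamic programming, so the significance
#' threshold is auditable rather than delegated to an external matcher.
#' Windows containing N are skipped. The default retention threshold is the
#' TF-model site cutoff 5e-5.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param motif a `MotifModel`.
#' @param p_threshold retain sites with match p-value strictly below this.
#' @param contig optional contig name recorded in the output.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `score` (log2 odds), `p`.
#' @export
scan_motifs <- function(seq, motif, p_threshold = 5e-5, contig = NA_character_) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  w <- ncol(motif$iscore)
  L <- nchar(seq)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p = numeric())
  if (w > L) return(empty)
  oh <- nn_one_hot(seq)
  valid_base <- rowSums(oh) > 0
  pfun <- motif_pvalue_fun(motif)
  n_win <- L - w + 1L
  # window validity: all w bases defined
  vb <- cumsum(c(0, valid_base))
  win_ok <- (vb[(w + 1):(L + 1)] - vb[1:n_win]) == w
  res <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") motif else motif_reverse_complement(motif)
    # per-position integer score contribution, then windowed sum
    contrib <- oh %*% m$iscore      # L x w: contrib[p, j] = score of base p at col j
    s <- numeric(n_win)
    for (j in seq_len(w)) s <- s + contrib[j:(j + n_win - 1L), j]
    s <- round(s)
    p <- pfun(s)
    keep <- win_ok & p < p_threshold
    if (any(keep)) {
      res[[strand]] <- data.frame(
        contig = contig, start = which(keep) - 1L,
        end = which(keep) - 1L + w, strand = strand,
        score = s[keep] * motif$granularity, p = p[keep])
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$strand), ]
}

## ---- per-bp track I/O -------------------------------------------------------

#' Write a per-bp numeric track as bedGraph
#'
#' Consecutive equal values are run-length collapsed.
#' @param values numeric vector (one value per bp); NA positions are skipped.
#' @param contig contig name.
#' @param path output path.
#' @param start0 0-based start coordinate of `values[1]`.
#' @export
write_bedgraph <- function(values, contig, path, start0 = 0L) {
  ok <- !is.na(values)
  idx <- which(ok)
  if (length(idx) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  # split into maximal runs of consecutive defined positions w/ equal value
  brk <- c(TRUE, diff(idx) != 1L | diff(values[idx]) != 0)
  run_id <- cumsum(brk)
  starts <- tapply(idx, run_id, min) - 1L + start0
  ends <- tapply(idx, run_id, max) + start0
  vals <- values[tapply(idx, run_id, min)]
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(starts + 1L, ends),
                               score = vals)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track into a per-bp numeric vector
#' @param path bedGraph path.
#' @param contig contig to extract.
#' @param length contig length (bp); positions not covered are NA.
#' @export
read_bedgraph <- function(path, contig, length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  out <- rep(NA_real_, length)
  if (base::length(gr)) {
    for (i in seq_along(gr)) {
      out[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
        S4Vectors::mcols(gr)$score[i]
    }
  }
  out
}
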