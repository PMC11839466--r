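# Fragment parsing, insertion counting, motif scanning.

test_that("fragment ends are shifted +4/-4 to insertion centres", {
  path <- fx_fragment_file()
  ev <- parse_and_shift_fragments(path)
  # fragment (ctg1, 100, 200): left = 104, right = 199 - 4 = 195
  e1 <- ev[ev$contig == "ctg1" & ev$group == "c1" & ev$weight == 1, ]
  expect_setequal(e1$pos, c(104L, 195L))
  # length-8 fragment dropped and tallied
  expect_equal(attr(ev, "dropped"), 1)
  # count = 3 fragment contributes weight 3 at each end
  e2 <- ev[ev$group == "c2", ]
  expect_equal(sort(e2$pos), c(204L, 255L))
  expect_equal(e2$weight, c(3L, 3L))
  # --pre-shifted reading keeps raw ends and keeps short fragments
  ev0 <- parse_and_shift_fragments(path, shift = FALSE)
  e0 <- ev0[ev0$contig == "ctg1" & ev0$group == "c1" & ev0$weight == 1, ]
  expect_setequal(e0$pos, c(100L, 199L, 150L, 157L))
  expect_equal(attr(ev0, "dropped"), 0)
})

test_that("count-weighted events match naive per-row expansion", {
  path <- fx_fragment_file()
  ev <- parse_and_shift_fragments(path)
  # expand each fragment `count` times by hand and recount
  df <- read.table(path, sep = "\t",
                   col.names = c("chrom", "start", "end", "bc", "count"))
  df <- df[df$end - df$start >= 10, ]
  naive <- sum(df$count) * 2
  expect_equal(sum(ev$weight), naive)
})

test_that("malformed and negative rows error with a line number", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("ctg1\t10\t100", "ctg1\t-5\t60"), p)
  expect_error(parse_and_shift_fragments(p), "line 2")
  writeLines(c("ctg1\t10\t100", "ctg1\t5\tx"), p)
  expect_error(parse_and_shift_fragments(p))
})

test_that("insertion tensor places events at region offsets and conserves totals", {
  regions <- GenomicRanges::GRanges("ctg1",
                                    IRanges::IRanges(c(101, 501), width = 300))
  ev <- data.table::data.table(
    contig = c("ctg1", "ctg1", "ctg2"),
    pos = c(107L, 700L, 50L),      # 0-based; region1 starts at 0-based 100
    group = "g1", weight = c(1L, 2L, 1L))
  im <- count_insertions(ev, regions)
  expect_equal(dim(im$counts), c(1L, 2L, 300L))
  expect_equal(unname(im$counts[1, 1, 8]), 1)       # offset 7 -> index 8
  expect_equal(unname(im$counts[1, 2, 201]), 2)     # 700 - 500 = offset 200
  expect_equal(im$in_region, 3)
  expect_equal(im$out_of_region, 1)
  expect_equal(sum(im$counts), 3)
  # unknown contig error names the contig
  bad <- GenomicRanges::GRanges("ctgX", IRanges::IRanges(1, 300))
  expect_error(count_insertions(ev, bad, contigs = c("ctg1", "ctg2")),
               "ctgX")
})

test_that("random events: tensor grand total equals a linear-scan oracle", {
  set.seed(31)
  regions <- GenomicRanges::GRanges(
    sample(c("c1", "c2"), 5, replace = TRUE),
    IRanges::IRanges(start = sample(1000, 5) + 100, width = 400))
  ev <- data.table::data.table(
    contig = sample(c("c1", "c2", "c3"), 1000, replace = TRUE),
    pos = sample(0:1500, 1000, replace = TRUE),
    group = sample(c("a", "b"), 1000, replace = TRUE),
    weight = sample(1:3, 1000, replace = TRUE))
  im <- count_insertions(ev, regions)
  # oracle: per-event membership scan over all regions
  oracle <- 0
  for (i in seq_len(nrow(ev))) {
    for (r in seq_along(regions)) {
      if (ev$contig[i] == as.character(GenomicRanges::seqnames(regions)[r]) &&
          ev$pos[i] >= GenomicRanges::start(regions)[r] - 1 &&
          ev$pos[i] <= GenomicRanges::end(regions)[r] - 1) {
        oracle <- oracle + ev$weight[i]
      }
    }
  }
  expect_equal(sum(im$counts), oracle)
})

test_that("conservation: tensor + out-of-region + 2x dropped = 2x fragments", {
  truth <- fx_naked()$truth
  path <- tempfile(fileext = ".tsv.gz")
  sim <- simulate_insertions(truth, depth_per_bp = 5, seed = 77,
                             fragments_path = path)
  ev <- parse_and_shift_fragments(path)
  regions <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(501, 1300))
  im <- count_insertions(ev, regions)
  total_events <- 2 * attr(ev, "n_fragments")
  expect_equal(sum(im$counts) + im$out_of_region + 2 * attr(ev, "dropped"),
               total_events)
})

test_that("motif scan: uniform PFM yields no sites, DP tail is exact, threshold honoured", {
  uni <- motif_from_pfm(matrix(0.25, 4, 5), "uniform")
  s <- paste(rep("ACGT", 50), collapse = "")
  expect_equal(nrow(scan_motifs(s, uni, p_threshold = 5e-5)), 0L)
  # length-4 motif: DP tail equals enumeration over all 256 background 4-mers
  set.seed(91)
  pfm <- matrix(stats::runif(16) + 0.05, 4, 4)
  m <- motif_from_pfm(pfm, "rand4")
  pf <- fpkit:::motif_pvalue_fun(m)
  grid <- as.matrix(expand.grid(rep(list(1:4), 4)))
  scores <- apply(grid, 1, function(kk) sum(m$iscore[cbind(kk, 1:4)]))
  probs <- apply(grid, 1, function(kk) prod(m$background[kk]))
  for (s0 in unique(scores)) {
    expect_equal(pf(s0), sum(probs[scores >= s0]))
  }
  # every retained site satisfies the threshold
  motif <- fx_motif()
  genome <- fx_naked()$truth$genome
  sites <- scan_motifs(genome[[1]], motif, p_threshold = 5e-5)
  if (nrow(sites)) expect_true(all(sites$p < 5e-5))
})

test_that("scanning the reverse complement mirrors sites with strands flipped", {
  motif <- fx_motif()
  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  s <- paste0(substr(s, 1, 200), motif_consensus(motif), substr(s, 209, 500))
  fwd <- scan_motifs(s, motif, p_threshold = 1e-3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- scan_motifs(rc, motif, p_threshold = 1e-3)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = nchar(s) - rev$end,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score, p = rev$p)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  fwd_o <- fwd[order(fwd$start, fwd$strand), ]
  expect_equal(fwd_o$start, mirrored$start)
  expect_equal(fwd_o$strand, mirrored$strand)
  expect_equal(fwd_o$score, mirrored$score)
  expect_equal(fwd_o$p, mirrored$p)
})

test_that("windows containing N are skipped; short sequences give empty results", {
  motif <- fx_motif()
  cons <- motif_consensus(motif)
  s <- paste0("AAAA", cons, "NNN", cons, "TTTT")
  hits <- scan_motifs(s, motif, p_threshold = 1e-3)
  # both planted copies found, none overlapping the Ns
  expect_true(all(hits$end <= 4 + nchar(cons) |
                    hits$start >= 4 + nchar(cons) + 3))
  expect_equal(nrow(scan_motifs("ACG", motif)), 0L)
})

test_that("JASPAR and MEME motif files round-trip through the parsers", {
  jp <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TEST",
               "A [ 10  2  0 ]",
               "C [  5  1 20 ]",
               "G [  3 15  0 ]",
               "T [  2  2  0 ]"), jp)
  mj <- read_jaspar(jp)[[1]]
  expect_equal(ncol(mj$pfm), 3L)
  expect_true(all(abs(colSums(mj$pfm) - 1) < 1e-9))
  mm <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TEST2", "letter-probability matrix: alength= 4 w= 2",
               " 0.7 0.1 0.1 0.1", " 0.1 0.1 0.1 0.7"), mm)
  m2 <- read_meme(mm)[[1]]
  expect_equal(motif_consensus(m2), "AT")
})

test_that("bedGraph round-trip preserves per-bp values to 1e-6", {
  set.seed(5)
  v <- round(stats::runif(400, 0.2, 3), 4)
  v[50:60] <- NA
  p <- tempfile(fileext = ".bedGraph")
  write_bedgraph(v, "ctg1", p)
  back <- read_bedgraph(p, "ctg1", 400)
  ok <- !is.na(v)
  expect_true(all(abs(back[ok] - v[ok]) < 1e-6))
  expect_true(all(is.na(back[!ok])))
})

test_that("region resizing preserves centres", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 400))  # width 300
  r2 <- resize_regions(gr, 1000)
  expect_equal(GenomicRanges::width(r2), 1000L)
  expect_equal(GenomicRanges::start(r2) + GenomicRanges::end(r2),
               GenomicRanges::start(gr) + GenomicRanges::end(gr))
  expect_error(resize_regions(gr, 0), "width")
})
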