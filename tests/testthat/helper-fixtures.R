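# Shared fixtures, built once per test run and memoised. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small naked-DNA world: genome + known 5-mer bias + deep insertion data
fx_naked <- function() {
  fixture("naked", function() {
    truth <- make_genome_and_bias(n_contigs = 3, length = 4000, gc = 0.45,
                                  k = 5, log_sd = 0.6, seed = 101)
    sim <- simulate_insertions(truth, depth_per_bp = 60, seed = 102)
    list(truth = truth, sim = sim)
  })
}

# dispersion model set over the default footprint radii, trained on the
# naked fixture with the true bias track
fx_dispersion <- function(radii = c(10, 20, 30, 50, 80, 100)) {
  fixture("dispersion", function() {
    fx <- fx_naked()
    set <- dispersion_set()
    for (r in radii) {
      tab <- build_background_table(fx$sim$counts, fx$truth$bias,
                                    radius = r, n_sample = 2000, k_nn = 50,
                                    downsample_fractions = c(0.5, 0.2, 0.1,
                                                             0.05, 0.01),
                                    seed = 200 + r)
      set <- dispersion_register(set,
                                 fit_dispersion_model(tab, seed = r,
                                                      epochs = 40))
    }
    set
  })
}

# a small CEBP-like motif used across tests
fx_motif <- function() {
  fixture("motif", function() {
    pfm <- matrix(c(
      # TTGCGCAA-ish consensus, moderately informative
      0.05, 0.05, 0.10, 0.80,
      0.05, 0.10, 0.05, 0.80,
      0.10, 0.10, 0.70, 0.10,
      0.10, 0.70, 0.10, 0.10,
      0.10, 0.10, 0.70, 0.10,
      0.10, 0.70, 0.10, 0.10,
      0.80, 0.05, 0.10, 0.05,
      0.80, 0.05, 0.05, 0.10), nrow = 4)
    motif_from_pfm(pfm, name = "CEBP_like")
  })
}

# deterministic tiny fragment file on disk
fx_fragment_file <- function(dir = tempdir()) {
  path <- file.path(dir, "fx_fragments.tsv")
  df <- data.frame(
    chrom = c("ctg1", "ctg1", "ctg1", "ctg2"),
    start = c(100L, 150L, 200L, 50L),
    end = c(200L, 158L, 260L, 400L),   # second row: length 8 -> dropped
    barcode = c("c1", "c1", "c2", "c1"),
    count = c(1L, 1L, 3L, 2L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Pearson correlation ignoring NA pairs
cor_ok <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])
}

# full chromatin study used by the sequence-model and LoRA checks: many
# short regions with densely planted sites (the sequence model needs data
# volume to generalise the motif -> footprint mapping)
fx_study <- function() {
  fixture("study", function() {
    make_chromatin_study(n_contigs = 24, contig_length = 16000,
                         region_width = 400, n_tf_bound = 300,
                         n_tf_unbound = 100, n_nuc = 150,
                         depth_chromatin = 100, protection = 1.0,
                         occupancy = 0.95, scales = c(20, 40, 60),
                         radii = c(10, 20, 30), seed = 21)
  })
}

fx_study_heldout <- c("ctg23", "ctg24")

# sequence model trained on the study (shared by recovery + LoRA tests)
fx_s2p_model <- function() {
  fixture("s2p_model", function() {
    st <- fx_study()
    cfg <- seqfp_config(n_filters = 32, n_blocks = 6, groups = 4,
                            scales = c(20, 40, 60), window = 400)
    model <- build_seqfp(cfg, seed = 333)
    train_seqfp(model, st$codes, st$targets, st$n_obs, st$chrom,
                    val_chroms = fx_study_heldout, epochs = 16, batch = 8,
                    lr = 2e-3, lr_decay = 0.97, patience = 16,
                    ema_decay = 0.95, seed = 334)
  })
}
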