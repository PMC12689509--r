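# Shared fixtures for the test suite.  Everything is generated in code;
# no data files are read from disk except those the tests themselves write.

TOY <- toy_engine()

# Stacking-aware variant: contiguous helices strictly beat scattered
# pairings of equal composition, as in nearest-neighbor models.  Used for
# ordered-structure (consensus recovery) studies.
TOY_STACK <- toy_engine(toy_energy_params(stack = -1))

has_rnafold <- nzchar(Sys.which("RNAfold"))
VIENNA <- if (has_rnafold) vienna_engine() else NULL

# Build an rna_scan object directly from crafted window rows, bypassing the
# folding engine, for tests of downstream modules that need exact control
# over per-window structures and z-scores.
fake_scan <- function(windows, temperature = 37, window_size = NULL,
                      compute_null = "z_score" %in% names(windows),
                      gene_id = "fake", sequence_length = NULL) {
  if (is.null(window_size))
    window_size <- windows$end[1] - windows$start[1]
  if (is.null(sequence_length)) sequence_length <- max(windows$end)
  if (is.null(windows$short)) windows$short <- FALSE
  cfg <- scan_config(window_size = max(10L, window_size), step = 1L,
                     num_shuffles = if (compute_null) 2L else 0L,
                     temperature = temperature, seed = 1L,
                     compute_null = compute_null)
  structure(list(windows = windows, config = cfg, engine = "fake 0",
                 gene_id = gene_id, sequence = NULL,
                 sequence_length = sequence_length),
            class = "rna_scan")
}

# A 200-nt gene with one strongly ordered GC hairpin planted mid-sequence;
# the workhorse fixture for consensus/motif recovery.
planted_gene <- function(seed, length = 200L, stem = 10L, loop = 4L,
                         position = 90L) {
  bg <- random_sequence(length, 0.5, seed = seed)
  plant_hairpin(bg, position, stem, loop, composition = "GC",
                seed = seed + 1L)
}

# Random gene model with both strands exercised.
random_gene_model <- function(seed, length = 120L) {
  with_seed <- get("with_seed", asNamespace("thermoscan"))
  with_seed(seed, gene_model(
    gene_id = sprintf("RG%03d", seed),
    chromosome = sample(c("chr1", "chr2"), 1),
    genomic_start = sample.int(100000L, 1),
    strand = sample(c("+", "-"), 1),
    length = length))
}
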