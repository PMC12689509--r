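#' Random RNA sequence of controlled composition
#'
#' Letters are i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(U) = (1 - gc_fraction) / 2`.
#'
#' @param length sequence length (>= 1).
#' @param gc_fraction target GC fraction in `[0, 1]`.
#' @param seed optional seed (draws from a private stream; the caller's
#'   RNG state is untouched).
#' @return an RNA string.
#' @export
random_sequence <- function(length, gc_fraction = 0.5, seed = NULL) {
  if (length < 1L) stop("length must be >= 1")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  draw <- function() paste(sample(c("G", "C", "A", "U"), length,
                                  replace = TRUE,
                                  prob = c(gc_fraction / 2, gc_fraction / 2,
                                           (1 - gc_fraction) / 2,
                                           (1 - gc_fraction) / 2)),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

.RC <- c(A = "U", C = "G", G = "C", U = "A")

#' Plant a hairpin element into a background sequence
#'
#' Overwrites `2 * stem_length + loop_length` nucleotides starting at
#' `position` with a perfect inverted repeat: the 5' stem half, a loop,
#' and the reverse complement of the stem half. `"GC"` composition
#' produces a deeply stable, sequence-ordered element (a strong negative
#' z-score signal); `"AU"` composition produces a marginally stable stem
#' that melts within a physiological temperature ramp (a thermometer-like,
#' positive delta-ED signal); `"mixed"` draws stem bases uniformly.
#'
#' @param background RNA string.
#' @param position 0-based start of the element.
#' @param stem_length,loop_length element geometry in nucleotides.
#' @param composition `"GC"`, `"AU"` or `"mixed"`.
#' @param seed optional seed for the stem/loop draw.
#' @return the modified sequence, with attribute `element`: a list with
#'   `start`, `end` (0-based half-open) and `pairs` (the planted stem
#'   pairs in transcript coordinates).
#' @export
plant_hairpin <- function(background, position, stem_length = 10L,
                          loop_length = 4L, composition = c("GC", "AU",
                                                            "mixed"),
                          seed = NULL) {
  composition <- match.arg(composition)
  n <- nchar(background)
  size <- 2L * stem_length + loop_length
  if (position < 0L || position + size > n)
    stop(sprintf(
      "hairpin of %d nt does not fit at position %d (sequence length %d)",
      size, position, n))
  if (loop_length < 3L)
    stop("loop_length must be >= 3 (minimum hairpin loop)")
  alphabet <- switch(composition, GC = c("G", "C"), AU = c("A", "U"),
                     mixed = c("A", "C", "G", "U"))
  draw <- function() {
    half <- sample(alphabet, stem_length, replace = TRUE)
    loop <- sample(c("A", "A", "A", "C"), loop_length, replace = TRUE)
    list(half = half, loop = loop)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  element <- paste(c(d$half, d$loop, rev(unname(.RC[d$half]))),
                   collapse = "")
  out <- paste0(substring(background, 1L, position),
                element,
                substring(background, position + size + 1L, n))
  t <- seq_len(stem_length) - 1L
  pairs <- cbind(i = position + t, j = position + size - 1L - t)
  structure(out, element = list(start = position, end = position + size,
                                pairs = as_pair_table(pairs),
                                composition = composition,
                                stem_length = stem_length,
                                loop_length = loop_length))
}

#' Generate a synthetic gene cohort
#'
#' Builds a cohort of random-composition genes with family labels, a
#' fraction of which are "thermometer" genes: they carry a regular array
#' of marginally stable AU-rich hairpins that are folded at moderate
#' temperature but melt within a moderate-to-extreme ramp, producing a
#' strongly positive delta-ED signal; the remainder are null genes.
#' Every gene receives a toy isoform layout (5'UTR, exons, an intron,
#' 3'UTR), and the first thermometer gene has one element anchored at its
#' 5'UTR-intron junction. Optionally writes per-gene FASTA files, a
#' combined GFF3 and a manifest TSV of every planted element to a
#' directory, so the full pipeline can be exercised with no external
#' data.
#'
#' @param n_genes number of genes (>= 2).
#' @param families named integer vector of family sizes summing to
#'   `n_genes` (default: one family `"fam"`).
#' @param thermometer_fraction fraction of genes carrying a thermometer
#'   element (0 gives a null cohort).
#' @param seed master seed; the cohort is fully reproducible.
#' @param length gene length in nucleotides.
#' @param gc_fraction background GC fraction.
#' @param stem_length,loop_length geometry of planted thermometer
#'   elements.
#' @param element_spacing distance between consecutive planted element
#'   starts in a thermometer gene.
#' @param dir optional output directory for FASTA/GFF3/manifest fixtures.
#' @return list of class `synthetic_cohort`: `sequences` (named vector),
#'   `models` (list of [gene_model()]), `manifest` (data frame with one
#'   row per planted element, plus one `NA` row per element-free gene:
#'   `gene_id`, `family`, `thermometer`, element coordinates), `dir`.
#' @export
make_cohort <- function(n_genes, families = NULL, thermometer_fraction = 0,
                        seed = 1L, length = 200L, gc_fraction = 0.5,
                        stem_length = 7L, loop_length = 4L,
                        element_spacing = 20L, dir = NULL) {
  if (n_genes < 2L) stop("a cohort needs at least 2 genes")
  if (element_spacing < 2L * stem_length + loop_length)
    stop("element_spacing smaller than the element size: elements overlap")
  if (length < 2L * stem_length + loop_length + 10L)
    stop("gene length too small for the planted element geometry")
  if (is.null(families)) families <- c(fam = n_genes)
  if (sum(families) != n_genes)
    stop("family sizes must sum to n_genes")
  fam <- rep(names(families), families)
  ids <- sprintf("SYNG%04d", seq_len(n_genes))
  n_thermo <- round(thermometer_fraction * n_genes)
  is_thermo <- seq_len(n_genes) <= n_thermo   # deterministic assignment
  seqs <- character(n_genes)
  models <- vector("list", n_genes)
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gseed <- derive_seed(seed, g)
    bg <- random_sequence(length, gc_fraction, seed = gseed)
    # toy isoform layout: a 5'UTR exon, an intron (so the gene has a
    # 5'UTR-intron junction), then one coding exon ending in a 3'UTR
    u5 <- max(10L, round(length * 0.15))
    intr <- max(10L, round(length * 0.25))
    u3 <- max(10L, round(length * 0.15))
    b <- c(u5, u5 + intr, length - u3)
    iso <- sprintf("%s_T001", ids[g])
    features <- data.frame(
      type = c("exon", "five_prime_UTR", "intron", "exon", "CDS",
               "three_prime_UTR"),
      start = c(0L, 0L, b[1L], b[2L], b[2L], b[3L]),
      end = c(b[1L], b[1L], b[2L], length, b[3L], length),
      isoform_id = iso)
    el_start <- NA_integer_; el_end <- NA_integer_
    if (is_thermo[g]) {
      size <- 2L * stem_length + loop_length
      positions <- seq.int(5L, length - size - 1L, by = element_spacing)
      if (g == 1L) {  # anchor one element at the 5'UTR-intron junction
        anchor <- max(0L, b[1L] - stem_length)
        positions <- positions[abs(positions - anchor) >= size]
        positions <- sort(c(positions, anchor))
      }
      for (e in seq_along(positions)) {
        bg <- plant_hairpin(as.character(bg), positions[e], stem_length,
                            loop_length, composition = "AU",
                            seed = derive_seed(seed, 200000L + 100L * g + e))
      }
      el_start <- positions; el_end <- positions + size
    }
    seqs[g] <- as.character(bg)
    models[[g]] <- gene_model(ids[g], paste0("chrS", (g %% 3L) + 1L),
                              genomic_start = 1000L + g * 5000L,
                              strand = if (g %% 2L == 0L) "-" else "+",
                              length = length, features = features)
    rows[[g]] <- data.frame(
      gene_id = ids[g], family = fam[g], thermometer = is_thermo[g],
      element_start = el_start, element_end = el_end,
      stem_length = if (is_thermo[g]) stem_length else NA_integer_,
      loop_length = if (is_thermo[g]) loop_length else NA_integer_,
      stringsAsFactors = FALSE)   # one row per element (NA if none)
  }
  names(seqs) <- ids
  names(models) <- ids
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in seq_len(n_genes))
      write_fasta(seqs[g], file.path(dir, paste0(ids[g], ".fasta")))
    write_gff3(models, file.path(dir, "cohort.gff3"))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(sequences = seqs, models = models, manifest = manifest,
                 dir = dir, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d genes (%d thermometer), families: %s\n",
    length(x$sequences), sum(x$manifest$thermometer),
    paste(unique(x$manifest$family), collapse = ", ")))
  invisible(x)
}
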