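#' Pipeline run configuration
#'
#' Settings for per-gene and cohort runs. One temperature (the "full"
#' temperature, default 37 degrees C) is scanned with the shuffled null and
#' z-scores and drives the consensus/motif outputs; the remaining
#' temperatures (default 28 and 42) are scan-only and drive the delta-ED
#' screen between the lowest and highest temperature.
#'
#' @param temperatures temperatures (degrees C) to scan at.
#' @param full_temperature the single temperature scanned with the
#'   shuffled null; must be one of `temperatures`, or `NA` for scan-only
#'   runs.
#' @param window_size,step,num_shuffles,seed see [scan_config()].
#' @param thresholds z thresholds for consensus/motif export (`NA` = no
#'   threshold).
#' @param min_gap motif-merging gap, nucleotides.
#' @param engine folding engine.
#' @param force overwrite existing non-empty gene output folders.
#' @return an object of class `run_config`.
#' @export
run_config <- function(temperatures = c(28, 37, 42), full_temperature = 37,
                       window_size = 120L, step = 1L, num_shuffles = 100L,
                       seed = 1L, thresholds = c(NA, -1, -2),
                       min_gap = 10L, engine = default_engine(),
                       force = FALSE) {
  if (!length(temperatures)) stop("at least one temperature is required")
  if (!is.na(full_temperature) &&
      !full_temperature %in% temperatures)
    stop("full_temperature must be one of temperatures (or NA)")
  structure(list(temperatures = sort(unique(temperatures)),
                 full_temperature = full_temperature,
                 window_size = as.integer(window_size),
                 step = as.integer(step),
                 num_shuffles = as.integer(num_shuffles),
                 seed = as.integer(seed), thresholds = thresholds,
                 min_gap = as.integer(min_gap), engine = engine,
                 force = isTRUE(force)),
            class = "run_config")
}

# 31-bit per-gene seed from the master seed and the gene id.
gene_seed <- function(master, gene_id) {
  h <- sum(utf8ToInt(gene_id) * seq_len(nchar(gene_id)))
  derive_seed(master, h)
}

.threshold_tag <- function(th) {
  if (is.na(th)) "no_threshold" else sprintf("z_le_%g", th)
}

#' Run the full pipeline on one gene
#'
#' Scans the gene at every configured temperature, builds the consensus
#' model and motifs from the full-temperature run, computes delta-ED
#' between the lowest and highest temperature, and writes the gene's
#' output folder:
#'
#' ```
#' <out_root>/<gene_id>[_<chrom>]/
#'   <gene_id>.fasta
#'   win_<W>_step_<s>_<T>C.tsv        (one per temperature)
#'   igv_files/      z-score, MFE, ED and delta-ED wig tracks; bp arcs
#'   extracted_structures/   motif .txt/.dbn/.ct at each z threshold
#'   run_metadata.json
#' ```
#'
#' @param gene_fasta path to a single-gene FASTA file.
#' @param config a [run_config()].
#' @param out_root output root directory.
#' @param gff3 optional GFF3 with the gene's model (for genome
#'   coordinates and region labels); without it, tracks are written in
#'   transcript coordinates.
#' @return (invisibly) a list of class `gene_run` with the scans, the
#'   consensus model, the motifs per threshold, the delta-ED records and
#'   the gene summary.
#' @export
run_gene <- function(gene_fasta, config = run_config(), out_root,
                     gff3 = NULL) {
  seqs <- read_fasta(gene_fasta)
  if (length(seqs) != 1L)
    stop("run_gene expects a single-record FASTA; got ", length(seqs),
         " records in ", gene_fasta)
  gene_id <- names(seqs)
  sequence <- seqs[[1L]]
  model <- if (!is.null(gff3)) read_gene_model(gff3, gene_id)
           else identity_gene_model(gene_id, nchar(sequence))
  dir_name <- if (model$chromosome != gene_id)
    paste0(gene_id, "_", model$chromosome) else gene_id
  gene_dir <- file.path(out_root, dir_name)
  if (dir.exists(gene_dir) && length(list.files(gene_dir)) &&
      !config$force)
    stop("output folder ", gene_dir,
         " exists and is not empty (use force = TRUE)")
  igv_dir <- file.path(gene_dir, "igv_files")
  str_dir <- file.path(gene_dir, "extracted_structures")
  for (d in c(gene_dir, igv_dir, str_dir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_fasta(seqs, file.path(gene_dir, paste0(gene_id, ".fasta")))

  gseed <- gene_seed(config$seed, gene_id)
  scans <- list()
  for (temp in config$temperatures) {
    full <- !is.na(config$full_temperature) &&
      temp == config$full_temperature
    cfg <- scan_config(config$window_size, config$step,
                       config$num_shuffles, temperature = temp,
                       seed = gseed, compute_null = full)
    sc <- scan_sequence(sequence, cfg, config$engine, gene_id = gene_id)
    scans[[as.character(temp)]] <- sc
    write_scan_tsv(sc, file.path(gene_dir,
                                 sprintf("win_%d_step_%d_%gC.tsv",
                                         config$window_size, config$step,
                                         temp)))
  }

  meta <- c(gene_id = gene_id, engine = scans[[1L]]$engine,
            seed = as.character(gseed))
  # per-window metric tracks at each temperature
  for (temp in names(scans)) {
    w <- scans[[temp]]$windows
    keep <- !w$short
    if (!any(keep)) next
    mk <- function(col) stats::setNames(w[[col]][keep], w$start[keep])
    write_wig(mk("ensemble_diversity"), model, paste0("ED_", temp, "C"),
              file.path(igv_dir, paste0("ed_", temp, "C.wig")), meta)
    write_wig(mk("mfe"), model, paste0("MFE_", temp, "C"),
              file.path(igv_dir, paste0("mfe_", temp, "C.wig")), meta)
    if (!is.null(w$z_score))
      write_wig(mk("z_score"), model, paste0("zscore_", temp, "C"),
                file.path(igv_dir, paste0("zscore_", temp, "C.wig")),
                meta)
  }

  # delta-ED between the temperature extremes
  delta <- NULL; summ <- NULL
  if (length(config$temperatures) >= 2L) {
    lo <- as.character(min(config$temperatures))
    hi <- as.character(max(config$temperatures))
    delta <- delta_ed(scans[[lo]], scans[[hi]])
    if (nrow(delta)) {
      summ <- gene_summary(gene_id, delta)
      write_wig(data.frame(window_start = delta$window_start,
                           value = delta$delta_ed),
                model, sprintf("deltaED_%sC_minus_%sC", hi, lo),
                file.path(igv_dir, sprintf("delta_ed_%sC_minus_%sC.wig",
                                           hi, lo)), meta)
    }
  }

  # consensus + motifs from the full run
  consensus <- NULL; motifs <- list()
  if (!is.na(config$full_temperature)) {
    full_scan <- scans[[as.character(config$full_temperature)]]
    consensus <- consensus_structure(full_scan)
    if (nrow(consensus$pairs))
      write_bp_track(consensus$pairs, model,
                     file.path(igv_dir, "consensus_pairs.bp"), meta)
    for (th in config$thresholds) {
      tag <- .threshold_tag(th)
      ms <- extract_motifs(consensus, threshold = th,
                           min_gap = config$min_gap)
      ms <- lapply(ms, function(m) {
        m$region_label <- region_label(m$start, model)
        m
      })
      motifs[[tag]] <- ms
      if (!length(ms)) next
      write_motif_txt(ms, sequence,
                      file.path(str_dir, paste0("motifs_", tag, ".txt")))
      for (q in seq_along(ms)) {
        m <- ms[[q]]
        mseq <- substring(sequence, m$start + 1L, m$end)
        base <- sprintf("motif_%02d_%s", q, tag)
        write_dbn(mseq, sweep_pairs(m$pairs, m$start),
                  file.path(str_dir, paste0(base, ".dbn")),
                  name = sprintf("%s %d-%d %s", gene_id, m$start + 1L,
                                 m$end, tag))
        write_ct(mseq, sweep_pairs(m$pairs, m$start),
                 file.path(str_dir, paste0(base, ".ct")),
                 name = sprintf("%s %d-%d", gene_id, m$start + 1L, m$end))
      }
    }
  }

  jsonlite::write_json(
    list(gene_id = gene_id, engine = scans[[1L]]$engine,
         seed = gseed, temperatures = config$temperatures,
         full_temperature = config$full_temperature,
         window_size = config$window_size, step = config$step,
         num_shuffles = config$num_shuffles,
         thresholds = config$thresholds, min_gap = config$min_gap,
         chromosome = model$chromosome, strand = model$strand),
    file.path(gene_dir, "run_metadata.json"), auto_unbox = TRUE,
    null = "null", na = "string")
  invisible(structure(list(gene_id = gene_id, dir = gene_dir,
                           scans = scans, consensus = consensus,
                           motifs = motifs, delta = delta,
                           summary = summ, model = model),
                      class = "gene_run"))
}

# shift a motif pair data frame to window-local (0-based) coordinates
sweep_pairs <- function(pairs, offset) {
  cbind(i = pairs$i - offset, j = pairs$j - offset)
}

#' Run a cohort of genes and aggregate delta-ED statistics
#'
#' Applies [run_gene()] to every `*.fasta` file in a directory, then
#' aggregates the per-gene delta-ED summaries into cohort statistics,
#' per-gene standard scores (against the cohort and, where family labels
#' are available from a `manifest.tsv` in the input directory, against
#' the gene's family) and a per-family one-sample t-test against the
#' cohort mean. Failures are logged and skipped; the run is flagged if
#' any gene failed.
#'
#' @param fasta_dir directory of single-gene FASTA files (optionally with
#'   a `manifest.tsv` carrying `gene_id` and `family` columns and a
#'   `cohort.gff3`).
#' @param config a [run_config()].
#' @param out_root output root directory.
#' @return list of class `cohort_run`: `summaries`, `population`
#'   ([population_stats()]), `table` (per-gene data frame with standard
#'   scores), `family_tests`, `failed` (character vector of failed
#'   files), `n_ok`.
#' @export
run_cohort <- function(fasta_dir, config = run_config(), out_root) {
  files <- list.files(fasta_dir, pattern = "\\.fasta$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", fasta_dir)
  manifest_path <- file.path(fasta_dir, "manifest.tsv")
  fam_map <- NULL
  if (file.exists(manifest_path)) {
    mf <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
    if (all(c("gene_id", "family") %in% names(mf)))
      fam_map <- stats::setNames(mf$family, mf$gene_id)
  }
  gff3 <- file.path(fasta_dir, "cohort.gff3")
  if (!file.exists(gff3)) gff3 <- NULL
  summaries <- list(); failed <- character(0)
  for (f in files) {
    res <- tryCatch(run_gene(f, config, out_root, gff3 = gff3),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("gene file %s failed: %s", basename(f),
                      conditionMessage(res)), call. = FALSE)
      failed <- c(failed, basename(f))
    } else if (!is.null(res$summary)) {
      summaries[[res$gene_id]] <- res$summary
    }
  }
  if (length(summaries) < 2L)
    stop("fewer than 2 genes produced delta-ED summaries; cannot ",
         "aggregate cohort statistics")
  pop <- population_stats(summaries)
  tab <- data.frame(
    gene_id = names(pop$gene_means),
    n_windows = vapply(summaries, function(s) s$n_windows, numeric(1)),
    mean_delta_ed = unname(pop$gene_means),
    score_vs_population = vapply(summaries, standard_score, numeric(1),
                                 pop = pop),
    stringsAsFactors = FALSE)
  tab$family <- if (!is.null(fam_map)) unname(fam_map[tab$gene_id])
                else NA_character_
  family_tests <- list()
  tab$score_vs_family <- NA_real_
  if (!is.null(fam_map)) {
    for (fam in unique(stats::na.omit(tab$family))) {
      fm <- tab$mean_delta_ed[tab$family == fam]
      family_tests[[fam]] <-
        if (length(fm) >= 2L && stats::sd(fm) > 0)
          one_sample_t_test(fm, reference_mean = pop$mean)
        else sprintf(
          "t-test refused for family '%s': needs >= 2 members with %s",
          fam, "non-zero spread")
      # family-relative standard scores
      if (length(fm) >= 2L && stats::sd(fm) > 0)
        tab$score_vs_family[tab$family == fam] <-
          (fm - mean(fm)) / stats::sd(fm)
    }
  }
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(tab, file.path(out_root, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- structure(list(summaries = summaries, population = pop,
                        table = tab, family_tests = family_tests,
                        failed = failed, n_ok = length(summaries)),
                   class = "cohort_run")
  if (length(failed))
    attr(out, "status") <- 1L
  out
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run> %d gene(s) analysed, %d failed\n", x$n_ok,
              length(x$failed)))
  print(x$population)
  for (fam in names(x$family_tests)) {
    cat(sprintf("family '%s': ", fam))
    ft <- x$family_tests[[fam]]
    if (inherits(ft, "thermo_ttest")) print(ft) else cat(ft, "\n")
  }
  invisible(x)
}
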