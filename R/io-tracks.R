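#' Gene model for coordinate mapping and region labels
#'
#' A light container describing one gene: its genomic anchor and strand,
#' its length, and exon/intron/UTR/CDS features in transcript coordinates
#' (0-based half-open, oriented 5' to 3' on the transcript). Used to map
#' per-window metrics and base pairs onto genome-browser coordinates and
#' to label motifs by region.
#'
#' @param gene_id gene identifier.
#' @param chromosome chromosome/sequence name.
#' @param genomic_start 0-based genomic coordinate of the gene's first
#'   base on the forward genomic strand.
#' @param strand `"+"` or `"-"`.
#' @param length gene length in nucleotides.
#' @param features data frame with columns `type` (exon, intron,
#'   five_prime_UTR, three_prime_UTR, CDS), `start`, `end` (transcript
#'   coordinates, 0-based half-open) and `isoform_id`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, genomic_start, strand, length,
                       features = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.null(features))
    features <- data.frame(type = character(0), start = integer(0),
                           end = integer(0), isoform_id = character(0))
  if (nrow(features) &&
      (any(features$start < 0L) || any(features$end > length) ||
       any(features$start >= features$end)))
    stop("gene model features must be half-open intervals within [0, length)")
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 genomic_start = as.integer(genomic_start), strand = strand,
                 length = as.integer(length), features = features),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d nt, %d feature(s)\n",
              x$gene_id, x$chromosome, x$genomic_start + 1L,
              x$genomic_start + x$length, x$strand, x$length,
              nrow(x$features)))
  invisible(x)
}

# Identity model: transcript coordinates are genome coordinates.  Used when
# no gene annotation is supplied.
identity_gene_model <- function(gene_id, length) {
  gene_model(gene_id, gene_id, 0L, "+", length)
}

#' Read a FASTA file
#'
#' @param path FASTA file (possibly multi-record, wrapped lines).
#' @return named character vector of uppercase sequences (T is kept; it is
#'   mapped to U at folding time).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("zero-length FASTA record: ", ids[nchar(seqs) == 0L][1L])
  names(seqs) <- ids
  seqs
}

#' Write a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a gene model from a GFF3 file
#'
#' Extracts one gene's isoform structure (exons, UTRs, CDS; introns are
#' derived as the gaps between each isoform's exons) and converts it from
#' 1-based inclusive genomic coordinates to the package's internal
#' transcript convention: 0-based half-open intervals oriented 5' to 3' on
#' the transcript, so that on the minus strand the first transcript base
#' is the highest genomic coordinate.
#'
#' @param gff3_path GFF3 file.
#' @param gene_id the `ID` (or `Name`) of the gene feature to extract.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(gff3_path, gene_id) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID)
  type <- as.character(mc$type)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  hit <- !is.na(ids) & ids == gene_id
  if (!is.null(mc$Name))
    hit <- hit | (!is.na(mc$Name) & as.character(mc$Name) == gene_id)
  gi <- which(type == "gene" & hit)
  if (!length(gi))
    stop("gene '", gene_id, "' not found in ", gff3_path)
  gi <- gi[1L]
  g_start1 <- GenomicRanges::start(gr)[gi]   # 1-based inclusive
  g_end1 <- GenomicRanges::end(gr)[gi]
  strand <- as.character(GenomicRanges::strand(gr)[gi])
  if (!strand %in% c("+", "-"))
    stop("gene '", gene_id, "' has no strand in ", gff3_path)
  chrom <- as.character(GenomicRanges::seqnames(gr)[gi])
  len <- g_end1 - g_start1 + 1L
  gene_gid <- ids[gi]
  # transcript coordinate of a genomic 1-based inclusive interval
  to_tx <- function(s1, e1) {
    if (strand == "+") c(s1 - g_start1, e1 - g_start1 + 1L)
    else c(g_end1 - e1, g_end1 - s1 + 1L)
  }
  mrna <- which(parent == gene_gid & type %in% c("mRNA", "transcript"))
  feats <- list()
  add_feat <- function(type, s1, e1, iso) {
    tx <- to_tx(s1, e1)
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, start = tx[1L], end = tx[2L], isoform_id = iso)
  }
  for (m in mrna) {
    iso <- ids[m]
    kids <- which(parent == iso)
    for (k in kids) {
      kt <- type[k]
      if (!kt %in% c("exon", "five_prime_UTR", "three_prime_UTR", "CDS"))
        next
      add_feat(kt, GenomicRanges::start(gr)[k], GenomicRanges::end(gr)[k],
               iso)
    }
    # derive introns from this isoform's exons
    ex <- which(parent == iso & type == "exon")
    if (length(ex) > 1L) {
      es <- GenomicRanges::start(gr)[ex]
      ee <- GenomicRanges::end(gr)[ex]
      o <- order(es)
      if (any(es[o][-1L] <= ee[o][-length(o)]))
        stop("overlapping exons in isoform ", iso, " of gene ", gene_id)
      for (q in seq_len(length(o) - 1L))
        add_feat("intron", ee[o][q] + 1L, es[o][q + 1L] - 1L, iso)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  gene_model(gene_id, chrom, g_start1 - 1L, strand, len, features)
}

#' Transcript-to-genome coordinate mapping
#'
#' Maps a 0-based transcript position to its 0-based genomic coordinate
#' (`to_genome`), and back (`from_genome`). On the minus strand the first
#' transcript base maps to the highest genomic coordinate. The two
#' functions are mutually inverse.
#'
#' @param pos 0-based transcript position(s) in `[0, length)`.
#' @param model a [gene_model()].
#' @param genomic_pos 0-based genomic coordinate(s).
#' @return integer vector of mapped coordinates.
#' @export
to_genome <- function(pos, model) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= model$length))
    stop(sprintf("transcript position out of range [0, %d)", model$length))
  if (model$strand == "+") model$genomic_start + pos
  else model$genomic_start + model$length - 1L - pos
}

#' @rdname to_genome
#' @export
from_genome <- function(genomic_pos, model) {
  g <- as.integer(genomic_pos)
  if (any(g < model$genomic_start | g >= model$genomic_start + model$length))
    stop("genomic position outside the gene interval")
  if (model$strand == "+") g - model$genomic_start
  else model$genomic_start + model$length - 1L - g
}

# Map a pair table to genomic coordinates, reordering so i < j.
pairs_to_genome <- function(pairs, model) {
  gi <- to_genome(pairs[, 1L], model)
  gj <- to_genome(pairs[, 2L], model)
  m <- cbind(i = pmin(gi, gj), j = pmax(gi, gj))
  m[order(m[, 1L]), , drop = FALSE]
}

#' Region label for a transcript position
#'
#' The feature type covering a position (priority: UTRs, then intron, then
#' exon/CDS), or `NA` outside any feature.
#'
#' @param pos 0-based transcript position.
#' @param model a [gene_model()].
#' @return character label.
#' @export
region_label <- function(pos, model) {
  f <- model$features
  if (!NROW(f)) return(NA_character_)
  hit <- f[f$start <= pos & pos < f$end, , drop = FALSE]
  if (!nrow(hit)) return(NA_character_)
  for (pref in c("five_prime_UTR", "three_prime_UTR", "intron", "CDS",
                 "exon"))
    if (pref %in% hit$type) return(pref)
  hit$type[1L]
}

#' Write a fixedStep wig track
#'
#' Per-window metrics keyed by window start are anchored at the genomic
#' coordinate of each window's first transcript base and written as
#' fixedStep wiggle blocks (1-based starts). Minus-strand genes are
#' emitted in ascending genomic order; a gap in the value stream (e.g. an
#' excluded window) starts a new block.
#'
#' @param values numeric vector named by 0-based window start, or a data
#'   frame with columns `window_start` and a single value column.
#' @param model a [gene_model()].
#' @param track_name track name written in the header.
#' @param path output file.
#' @param metadata optional named character vector written as `#` comments.
#' @return `path`, invisibly.
#' @export
write_wig <- function(values, model, track_name, path, metadata = NULL) {
  if (is.data.frame(values)) {
    starts <- as.integer(values$window_start)
    vals <- as.numeric(values[[setdiff(names(values), "window_start")[1L]]])
  } else {
    starts <- as.integer(names(values))
    vals <- as.numeric(values)
  }
  if (!length(vals)) stop("no values to write")
  g <- to_genome(starts, model)
  o <- order(g)
  g <- g[o]; vals <- vals[o]
  step <- if (length(g) > 1L) min(diff(g)) else 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s=%s", names(metadata), metadata), con)
  writeLines(sprintf('track type=wiggle_0 name="%s"', track_name), con)
  block_start <- 1L
  brk <- c(which(diff(g) != step), length(g))
  for (b in brk) {
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=1",
                       model$chromosome, g[block_start] + 1L, step), con)
    writeLines(sprintf("%.6g", vals[block_start:b]), con)
    block_start <- b + 1L
  }
  invisible(path)
}

# z-score color classes used by the arc track (most specific bin wins).
.bp_color_class <- function(z) {
  ifelse(z <= -2, "z_le_-2",
         ifelse(z <= -1, "z_le_-1",
                ifelse(z < 0, "z_lt_0", "z_ge_0")))
}

#' Write / read a base-pair arc track
#'
#' Browser arc ("bp") format for consensus base pairs colored by mean
#' z-score: gray for z >= 0, yellow for z < 0, green for z <= -1 and blue
#' for z <= -2. The dialect is pinned by this package (there is no formal
#' bp standard): four `color:` declarations, then one tab-separated row
#' per arc with the genomic 1-based inclusive endpoints
#' (`chrom left_start left_end right_start right_end color_index`),
#' single-base anchors at each paired nucleotide.
#'
#' @param pairs data frame with columns `i`, `j` (0-based transcript
#'   coordinates) and `mean_z`.
#' @param model a [gene_model()].
#' @param path output file.
#' @param metadata optional named character vector written as `#` comments.
#' @return `write_bp_track` returns `path` invisibly; `read_bp_track`
#'   returns a data frame `i`, `j` (genomic, 0-based), `color_class`.
#' @export
write_bp_track <- function(pairs, model, path, metadata = NULL) {
  classes <- c("z_ge_0" = "183,183,183", "z_lt_0" = "255,210,0",
               "z_le_-1" = "0,160,0", "z_le_-2" = "0,90,255")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s=%s", names(metadata), metadata), con)
  writeLines(sprintf('track graphType=arc name="%s z-weighted base pairs"',
                     model$gene_id), con)
  writeLines(sprintf("color:\t%s\t%s", classes, names(classes)), con)
  if (NROW(pairs)) {
    cls <- .bp_color_class(pairs$mean_z)
    gi <- to_genome(pairs$i, model)
    gj <- to_genome(pairs$j, model)
    left <- pmin(gi, gj) + 1L; right <- pmax(gi, gj) + 1L
    o <- order(left)
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%d", model$chromosome,
                       left[o], left[o], right[o], right[o],
                       match(cls, names(classes))[o]), con)
  }
  invisible(path)
}

#' @rdname write_bp_track
#' @export
read_bp_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^track", lines)]
  cls <- sub("^color:\t[0-9,]+\t", "", grep("^color:", lines, value = TRUE))
  rows <- grep("^color:", lines, invert = TRUE, value = TRUE)
  rows <- rows[nzchar(rows)]
  if (!length(rows))
    return(data.frame(i = integer(0), j = integer(0),
                      color_class = character(0)))
  f <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
  data.frame(i = as.integer(f[, 2L]) - 1L, j = as.integer(f[, 4L]) - 1L,
             color_class = cls[as.integer(f[, 6L])],
             stringsAsFactors = FALSE)
}

#' Write dot-bracket (dbn) structure files
#'
#' Three lines: a `>` header, the sequence and the dot-bracket string.
#'
#' @param sequence RNA string.
#' @param pairs nested pair table (0-based; crossings must be resolved
#'   upstream).
#' @param path output file.
#' @param name header text.
#' @return `path`, invisibly.
#' @export
write_dbn <- function(sequence, pairs, path, name = "structure") {
  dbn <- pairs_to_dbn(pairs, nchar(sequence))
  writeLines(c(paste0(">", name), sequence, dbn), path)
  invisible(path)
}

#' Write / read connectivity-table (CT) structure files
#'
#' Standard 6-column CT, 1-based: index, base, index-1, index+1, pairing
#' partner (0 if unpaired), index.
#'
#' @param sequence RNA string.
#' @param pairs nested pair table (0-based).
#' @param path file path.
#' @param name header text.
#' @return `write_ct` returns `path` invisibly; `read_ct` returns
#'   `list(sequence, pairs)` with 0-based pairs.
#' @export
write_ct <- function(sequence, pairs, path, name = "structure") {
  m <- as_pair_table(pairs)
  n <- nchar(sequence)
  if (nrow(m) && pairs_cross(m))
    stop("crossing pairs cannot be written as CT; resolve first")
  partner <- integer(n)
  partner[m[, 1L] + 1L] <- m[, 2L] + 1L
  partner[m[, 2L] + 1L] <- m[, 1L] + 1L
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, name), con)
  writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), ch,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                     partner, seq_len(n)), con)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(hdr[1L])
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed CT file: bad header or truncated body")
  f <- do.call(rbind, strsplit(trimws(lines[2:(n + 1L)]), "\\s+"))
  idx <- as.integer(f[, 1L])
  partner <- as.integer(f[, 5L])
  if (any(idx != seq_len(n)))
    stop("malformed CT file: index column is not 1..n")
  paired <- which(partner > 0L)
  if (any(partner[partner[paired]] != paired))
    stop("malformed CT file: pairing column is not reciprocal")
  m <- cbind(idx[paired], partner[paired])
  m <- m[m[, 1L] < m[, 2L], , drop = FALSE] - 1L
  list(sequence = paste(f[, 2L], collapse = ""), pairs = as_pair_table(m))
}

#' Write a minimal Stockholm 1.0 alignment with a consensus structure
#'
#' Used to hand extracted motifs to covariation tooling: the motif's
#' dot-bracket becomes the `#=GC SS_cons` line of a single-block Stockholm
#' alignment.
#'
#' @param motif a `motif` object (its `dbn` is the consensus structure).
#' @param sequences named character vector of aligned sequences, all the
#'   same length as the motif structure.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(motif, sequences, path) {
  if (!length(sequences)) stop("empty alignment")
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("aligned sequences must all have the same length")
  if (len != nchar(motif$dbn))
    stop("alignment length does not match the motif structure length")
  idw <- max(nchar(names(sequences)), nchar("#=GC SS_cons"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("#=GF ID %s_%d-%d", motif$gene_id, motif$start + 1L,
                     motif$end), con)
  writeLines(sprintf("%-*s %s", idw, names(sequences), sequences), con)
  writeLines(sprintf("%-*s %s", idw, "#=GC SS_cons", motif$dbn), con)
  writeLines("//", con)
  invisible(path)
}

#' Write a minimal GFF3 file for a set of gene models
#'
#' Inverse of [read_gene_model()] for synthetic cohorts: emits gene, mRNA
#' and exon/UTR features with 1-based inclusive genomic coordinates.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    g1 <- m$genomic_start + 1L
    g2 <- m$genomic_start + m$length
    row <- function(type, s1, e1, attrs)
      sprintf("%s\tthermoscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$chromosome, type, s1, e1, m$strand, attrs)
    writeLines(row("gene", g1, g2, paste0("ID=", m$gene_id)), con)
    f <- m$features
    isoforms <- unique(f$isoform_id)
    for (iso in isoforms) {
      fi <- f[f$isoform_id == iso, , drop = FALSE]
      # back to genomic 1-based inclusive
      gs <- if (m$strand == "+") m$genomic_start + fi$start + 1L
            else m$genomic_start + m$length - fi$end + 1L
      ge <- if (m$strand == "+") m$genomic_start + fi$end
            else m$genomic_start + m$length - fi$start
      writeLines(row("mRNA", min(gs), max(ge),
                     sprintf("ID=%s;Parent=%s", iso, m$gene_id)), con)
      keep <- fi$type != "intron"   # introns are derived, not stored
      for (q in which(keep))
        writeLines(row(fi$type[q], gs[q], ge[q],
                       sprintf("ID=%s.%s%d;Parent=%s", iso, fi$type[q], q,
                               iso)), con)
    }
  }
  invisible(path)
}
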