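#' Accumulate base-pair evidence across scan windows
#'
#' Every MFE base pair predicted in any window is mapped to transcript
#' coordinates and annotated with the z-scores of the windows in which it
#' recurred. This is the raw material for the z-weighted consensus
#' structure: pairs that recur across many low-z windows carry strong
#' evidence of sequence-ordered stability.
#'
#' @param scan an `rna_scan` from a full run (`compute_null = TRUE`).
#' @return data frame of class `pair_evidence` with columns `i`, `j`
#'   (0-based transcript coordinates), `count`, `mean_z`, `min_window_z`
#'   and a list column `z_values`.
#' @export
accumulate_pair_evidence <- function(scan) {
  stopifnot(inherits(scan, "rna_scan"))
  if (is.null(scan$windows$z_score))
    stop("consensus requires a full run: scan was run without the ",
         "shuffled null (compute_null = FALSE)")
  w <- scan$windows
  ii <- integer(0); jj <- integer(0); zz <- numeric(0)
  for (r in seq_len(nrow(w))) {
    p <- dbn_to_pairs(w$mfe_dbn[r])
    if (!nrow(p)) next
    ii <- c(ii, p[, 1L] + w$start[r])
    jj <- c(jj, p[, 2L] + w$start[r])
    zz <- c(zz, rep(w$z_score[r], nrow(p)))
  }
  if (!length(ii)) {
    ev <- data.frame(i = integer(0), j = integer(0), count = integer(0),
                     mean_z = numeric(0), min_window_z = numeric(0))
    ev$z_values <- list()
  } else {
    key <- paste(ii, jj)
    grp <- split(zz, factor(key, levels = unique(key)))
    first <- !duplicated(key)
    ev <- data.frame(i = ii[first], j = jj[first],
                     count = lengths(grp),
                     mean_z = vapply(grp, mean, numeric(1)),
                     min_window_z = vapply(grp, min, numeric(1)))
    ev$z_values <- unname(grp)
    ev <- ev[order(ev$i, ev$j), , drop = FALSE]
    rownames(ev) <- NULL
  }
  attr(ev, "length") <- scan$sequence_length
  attr(ev, "gene_id") <- scan$gene_id
  class(ev) <- c("pair_evidence", "data.frame")
  ev
}

#' Resolve pairing competition into a consensus model
#'
#' Each transcript position nominates, among all pairs it was ever
#' predicted in, the one with the lowest mean z-score; a pair enters the
#' consensus only when both endpoints nominate it (mutual best). Ties are
#' broken by higher recurrence count, then smaller span, then smaller `i`.
#' The resulting model is a deterministic per-nucleotide partner map biased
#' toward sequence-ordered stability.
#'
#' @param evidence a `pair_evidence` object.
#' @param length transcript length (defaults to the evidence attribute).
#' @return an object of class `consensus_model`: list with `length`,
#'   `partner` (integer vector, 0-based partner or `NA`), `pairs` (data
#'   frame `i`, `j`, `mean_z`, `count`, `min_window_z`) and `evidence`.
#' @export
resolve_competition <- function(evidence, length = attr(evidence, "length")) {
  stopifnot(inherits(evidence, "pair_evidence"))
  ev <- as.data.frame(evidence)
  if (!nrow(ev)) {
    return(structure(list(length = length,
                          partner = rep(NA_integer_, length),
                          pairs = ev[, c("i", "j", "mean_z", "count",
                                         "min_window_z")],
                          evidence = evidence,
                          gene_id = attr(evidence, "gene_id")),
                     class = "consensus_model"))
  }
  # global preference order; each position's best pair = lowest rank
  rank_order <- order(ev$mean_z, -ev$count, ev$j - ev$i, ev$i)
  rk <- integer(nrow(ev)); rk[rank_order] <- seq_len(nrow(ev))
  pos <- c(ev$i, ev$j)
  pr <- c(rk, rk)
  best <- tapply(pr, pos, min)
  sel <- rk == best[as.character(ev$i)] & rk == best[as.character(ev$j)]
  cons <- ev[sel, c("i", "j", "mean_z", "count", "min_window_z"),
             drop = FALSE]
  rownames(cons) <- NULL
  partner <- rep(NA_integer_, length)
  partner[cons$i + 1L] <- cons$j
  partner[cons$j + 1L] <- cons$i
  structure(list(length = length, partner = partner, pairs = cons,
                 evidence = evidence, gene_id = attr(evidence, "gene_id")),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model> %s: %d nt, %d consensus pair(s)\n",
              x$gene_id %||% "seq", x$length, nrow(x$pairs)))
  if (nrow(x$pairs))
    cat(sprintf("  mean_z range [%.2f, %.2f]\n",
                min(x$pairs$mean_z), max(x$pairs$mean_z)))
  invisible(x)
}

#' Build a consensus model from a full scan
#'
#' Convenience wrapper: [accumulate_pair_evidence()] followed by
#' [resolve_competition()].
#'
#' @param scan an `rna_scan` from a full run.
#' @return a `consensus_model`.
#' @export
consensus_structure <- function(scan) {
  resolve_competition(accumulate_pair_evidence(scan))
}

#' Filter consensus pairs by z threshold
#'
#' @param model a `consensus_model`.
#' @param threshold keep pairs with `mean_z <= threshold`; `NULL` or `NA`
#'   keeps all consensus pairs.
#' @return data frame of surviving pairs (same columns as `model$pairs`).
#' @export
filter_by_threshold <- function(model, threshold = NULL) {
  stopifnot(inherits(model, "consensus_model"))
  p <- model$pairs
  if (is.null(threshold) || is.na(threshold)) return(p)
  p[p$mean_z <= threshold, , drop = FALSE]
}

#' Extract structural motifs from a consensus model
#'
#' Threshold-surviving pairs are grouped into contiguous structured
#' regions: two pairs belong to the same motif when their spans overlap or
#' are separated by fewer than `min_gap` unpaired nucleotides. Each motif
#' reports its coordinate hull, dot-bracket structure, per-pair mean z and
#' the lowest z among its contributing windows. Crossing pairs (possible
#' in principle, since consensus pairs arise from different windows) are
#' resolved at export by dropping the pair with the smaller `|mean_z|`.
#'
#' @param model a `consensus_model`.
#' @param threshold z threshold passed to [filter_by_threshold()].
#' @param min_gap motif-merging gap in nucleotides.
#' @return list of `motif` objects, disjoint and ordered 5' to 3'. Each is
#'   a list with `start`, `end` (0-based half-open), `dbn`, `pairs`,
#'   `min_window_z`, `mean_z`, `region_label` (`NA` unless annotated).
#' @export
extract_motifs <- function(model, threshold = NULL, min_gap = 10L) {
  p <- filter_by_threshold(model, threshold)
  if (!nrow(p)) return(list())
  p <- p[order(p$i, p$j), , drop = FALSE]
  group <- integer(nrow(p))
  g <- 1L
  group[1L] <- g
  hull_end <- p$j[1L] + 1L
  for (r in seq_len(nrow(p))[-1L]) {
    if (p$i[r] - hull_end >= min_gap) g <- g + 1L
    group[r] <- g
    hull_end <- max(hull_end, p$j[r] + 1L)
  }
  groups <- split(p, factor(group, levels = unique(group)))
  out <- lapply(groups, function(mp) {
    rc <- remove_crossings(mp[, c("i", "j")], weight = abs(mp$mean_z))
    if (nrow(rc$dropped))
      message(sprintf(
        "motif export: dropped %d crossing pair(s) with lower |mean_z|",
        nrow(rc$dropped)))
    keep <- paste(mp$i, mp$j) %in% paste(rc$kept[, 1L], rc$kept[, 2L])
    mp <- mp[keep, , drop = FALSE]
    start <- min(mp$i)
    end <- max(mp$j) + 1L
    structure(list(
      start = start, end = end,
      dbn = pairs_to_dbn(mp[, c("i", "j")], end - start, offset = start),
      pairs = mp, min_window_z = min(mp$min_window_z),
      mean_z = mean(mp$mean_z), region_label = NA_character_,
      gene_id = model$gene_id %||% "seq"), class = "motif")
  })
  unname(out)
}

#' Trim unpaired flanks from a motif
#'
#' Removes leading and trailing unpaired nucleotides (noise for downstream
#' covariation hand-off) and tightens the coordinates; internal structure
#' is untouched. Idempotent.
#'
#' @param motif a `motif` object.
#' @return the trimmed `motif`.
#' @export
trim_motif <- function(motif) {
  stopifnot(inherits(motif, "motif"))
  if (!nrow(motif$pairs)) stop("cannot trim a motif with zero pairs")
  start <- min(motif$pairs$i)
  end <- max(motif$pairs$j) + 1L
  motif$dbn <- pairs_to_dbn(motif$pairs[, c("i", "j")], end - start,
                            offset = start)
  motif$start <- start
  motif$end <- end
  motif
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s:%d-%d (1-based), %d pair(s), min window z %.2f\n",
              x$gene_id, x$start + 1L, x$end, nrow(x$pairs),
              x$min_window_z))
  cat("  ", x$dbn, "\n", sep = "")
  invisible(x)
}

#' Write motifs as a text file
#'
#' One block per motif: a header line (gene id, 1-based coordinates,
#' minimum contributing window z, mean pair z), the motif sequence and its
#' dot-bracket structure.
#'
#' @param motifs list of `motif` objects.
#' @param sequence the transcript sequence the motifs were extracted from.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_txt <- function(motifs, sequence, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %d %d min_z=%.4f mean_z=%.4f",
                       m$gene_id, m$start + 1L, m$end, m$min_window_z,
                       m$mean_z), con)
    writeLines(substring(sequence, m$start + 1L, m$end), con)
    writeLines(m$dbn, con)
  }
  invisible(path)
}
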