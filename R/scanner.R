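#' Scan configuration
#'
#' Parameters of a sliding-window scan. The defaults are the standard
#' transcript-screening settings: 120-nt windows advanced 1 nt at a time,
#' with a null distribution built from 100 mononucleotide shuffles per
#' window. "Scan-only" runs (`compute_null = FALSE`) skip the shuffling and
#' z-score step and report only the per-window thermodynamic metrics; they
#' are the mode used for temperature-contrast (delta-ED) scans.
#'
#' @param window_size window width in nucleotides (>= 10).
#' @param step window advance in nucleotides (>= 1).
#' @param num_shuffles shuffled refolds per window for the z-score null
#'   (>= 2 when `compute_null` is `TRUE`).
#' @param temperature folding temperature, degrees Celsius.
#' @param seed master RNG seed; per-window shuffle streams are derived from
#'   it and the window start, so results do not depend on evaluation order.
#' @param compute_null build the shuffled-MFE null and z-scores?
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(window_size = 120L, step = 1L, num_shuffles = 100L,
                        temperature = 37, seed = 1L, compute_null = TRUE) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  num_shuffles <- as.integer(num_shuffles)
  if (window_size < 10L) stop("window_size must be >= 10")
  if (step < 1L) stop("step must be >= 1")
  if (num_shuffles < 0L) stop("num_shuffles must be >= 0")
  if (compute_null && num_shuffles < 2L)
    stop("compute_null requires num_shuffles >= 2 (sd needs >= 2 values)")
  structure(list(window_size = window_size, step = step,
                 num_shuffles = num_shuffles, temperature = temperature,
                 seed = as.integer(seed), compute_null = isTRUE(compute_null)),
            class = "scan_config")
}

#' Window coordinates for a scan
#'
#' Windows are `[k * step, k * step + window_size)` in 0-based half-open
#' transcript coordinates, for every `k` with the window end inside the
#' sequence. A sequence shorter than the window yields a single
#' whole-sequence window flagged `short` (short transcripts are folded
#' rather than dropped, so that cohort statistics are not silently
#' truncated).
#'
#' @param sequence_length,window_size,step nucleotides.
#' @return data frame with columns `start`, `end`, `short`.
#' @export
window_iter <- function(sequence_length, window_size = 120L, step = 1L) {
  if (sequence_length < 1L) stop("sequence_length must be >= 1")
  if (sequence_length < window_size)
    return(data.frame(start = 0L, end = as.integer(sequence_length),
                      short = TRUE))
  starts <- seq.int(0L, sequence_length - window_size, by = step)
  data.frame(start = as.integer(starts),
             end = as.integer(starts + window_size), short = FALSE)
}

#' Mononucleotide shuffle
#'
#' A uniform random permutation of the sequence's characters: the
#' mononucleotide composition is preserved exactly. Draws from the current
#' RNG stream (the scanner seeds a dedicated substream per window).
#'
#' @param sequence RNA string.
#' @return a shuffled string.
#' @export
mononucleotide_shuffle <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  paste(ch[sample.int(length(ch))], collapse = "")
}

#' Thermodynamic z-score
#'
#' `(native - mean(shuffled)) / sd(shuffled)` with the sample (n - 1)
#' standard deviation: the number of standard deviations by which the
#' native window is more (negative) or less (positive) stable than
#' composition-matched random sequence. A degenerate null (`sd = 0`, e.g.
#' a homopolymer window) yields 0 with attribute `degenerate = TRUE`.
#'
#' @param native_mfe native window MFE (kcal/mol).
#' @param shuffled_mfes numeric vector of shuffled-window MFEs (>= 2).
#' @return the z-score, with attribute `degenerate`.
#' @export
z_score <- function(native_mfe, shuffled_mfes) {
  if (length(shuffled_mfes) < 2L)
    stop("z_score needs at least 2 shuffled MFE values")
  s <- stats::sd(shuffled_mfes)
  if (s == 0)
    return(structure(0, degenerate = TRUE))
  structure((native_mfe - mean(shuffled_mfes)) / s, degenerate = FALSE)
}

#' Scan a sequence with a sliding folding window
#'
#' Folds every window at the configured temperature and, for full runs,
#' builds a per-window null from mononucleotide shuffles to compute the
#' thermodynamic z-score and an empirical p-value (the fraction of shuffled
#' MFEs at or below the native MFE). Scans are fully deterministic given
#' `(sequence, config$seed, engine)`: each window's shuffle stream is
#' seeded from the master seed and the window start.
#'
#' @param sequence RNA string.
#' @param config a [scan_config()].
#' @param engine a folding engine ([toy_engine()], [vienna_engine()]).
#' @param gene_id identifier recorded in the result metadata.
#' @return an object of class `rna_scan`: list with `windows` (data frame,
#'   one row per window), `config`, `engine`, `gene_id`,
#'   `sequence_length`. Window columns: `start`, `end`, `short`,
#'   `sequence`, `gc_fraction`, `mfe`, `dg` (synonym of `mfe`),
#'   `ensemble_diversity`, `centroid_dbn`, `mfe_dbn`, and for full runs
#'   `shuffled_mean`, `shuffled_sd`, `z_score`, `p_value`, `degenerate`.
#' @export
scan_sequence <- function(sequence, config = scan_config(),
                          engine = default_engine(), gene_id = "seq") {
  s <- normalize_rna(sequence)
  n <- nchar(s)
  win <- window_iter(n, config$window_size, config$step)
  wseq <- substring(s, win$start + 1L, win$end)
  fl <- tryCatch(
    engine_fold_batch(engine, wseq, config$temperature),
    error = function(e) stop(sprintf(
      "folding engine failed on windows of '%s' (first window %d-%d): %s",
      gene_id, win$start[1L] + 1L, win$end[1L], conditionMessage(e))))
  windows <- data.frame(
    start = win$start, end = win$end, short = win$short,
    sequence = wseq,
    gc_fraction = vapply(wseq, gc_fraction, numeric(1), USE.NAMES = FALSE),
    mfe = fl$mfe, dg = fl$mfe,
    stringsAsFactors = FALSE)
  if (config$compute_null) {
    nw <- nrow(win)
    shuffled <- vector("list", nw)
    for (w in seq_len(nw)) {
      shuffled[[w]] <- with_seed(
        derive_seed(config$seed, win$start[w]),
        replicate(config$num_shuffles, mononucleotide_shuffle(wseq[w])))
    }
    smfe <- engine_mfe_batch(engine, unlist(shuffled), config$temperature)
    smfe <- matrix(smfe, nrow = config$num_shuffles)
    zs <- numeric(nw); degen <- logical(nw)
    for (w in seq_len(nw)) {
      z <- z_score(windows$mfe[w], smfe[, w])
      zs[w] <- as.numeric(z)
      degen[w] <- attr(z, "degenerate")
    }
    windows$shuffled_mean <- colMeans(smfe)
    windows$shuffled_sd <- apply(smfe, 2L, stats::sd)
    windows$z_score <- zs
    windows$p_value <- colMeans(smfe <= rep(windows$mfe, each = config$num_shuffles))
    windows$degenerate <- degen
  }
  windows$ensemble_diversity <- fl$ensemble_diversity
  windows$centroid_dbn <- fl$centroid_dbn
  windows$mfe_dbn <- fl$mfe_dbn
  rownames(windows) <- NULL
  structure(list(windows = windows, config = config,
                 engine = engine_info(engine), gene_id = gene_id,
                 sequence = s, sequence_length = n),
            class = "rna_scan")
}

#' @export
print.rna_scan <- function(x, ...) {
  cat(sprintf("<rna_scan> %s: %d nt, %d window(s) of %d nt (step %d) at %g degC\n",
              x$gene_id, x$sequence_length, nrow(x$windows),
              x$config$window_size, x$config$step, x$config$temperature))
  cat(sprintf("  engine: %s; null: %s\n", x$engine,
              if (x$config$compute_null)
                sprintf("%d mononucleotide shuffles/window (seed %d)",
                        x$config$num_shuffles, x$config$seed)
              else "none (scan-only)"))
  if (x$config$compute_null)
    cat(sprintf("  z-score: min %.2f / mean %.2f;  ED: mean %.2f\n",
                min(x$windows$z_score), mean(x$windows$z_score),
                mean(x$windows$ensemble_diversity)))
  invisible(x)
}

#' @export
summary.rna_scan <- function(object, ...) {
  w <- object$windows
  out <- list(gene_id = object$gene_id, n_windows = nrow(w),
              temperature = object$config$temperature,
              mfe = summary(w$mfe), ed = summary(w$ensemble_diversity))
  if (!is.null(w$z_score)) out$z_score <- summary(w$z_score)
  class(out) <- "summary.rna_scan"
  out
}

#' @export
print.summary.rna_scan <- function(x, ...) {
  cat(sprintf("Scan of %s: %d windows at %g degC\n", x$gene_id,
              x$n_windows, x$temperature))
  cat("MFE (kcal/mol):\n"); print(x$mfe)
  cat("Ensemble diversity:\n"); print(x$ed)
  if (!is.null(x$z_score)) { cat("z-score:\n"); print(x$z_score) }
  invisible(x)
}

#' Plot per-window scan metrics
#'
#' Base-graphics panels of MFE, z-score (full runs) and ensemble diversity
#' along the transcript.
#'
#' @param x an `rna_scan`.
#' @param ... passed to [plot()].
#' @export
plot.rna_scan <- function(x, ...) {
  w <- x$windows
  has_z <- !is.null(w$z_score)
  op <- graphics::par(mfrow = c(if (has_z) 3 else 2, 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(w$start + 1, w$mfe, type = "l", xlab = "",
                 ylab = "MFE (kcal/mol)", ...)
  if (has_z) {
    graphics::plot(w$start + 1, w$z_score, type = "l", xlab = "",
                   ylab = "z-score", ...)
    graphics::abline(h = c(-1, -2), lty = 3)
  }
  graphics::plot(w$start + 1, w$ensemble_diversity, type = "l",
                 xlab = "window start (nt)", ylab = "ED", ...)
  invisible(x)
}

# ---- TSV persistence ---------------------------------------------------

.SCAN_COLS_CORE <- c("start", "end", "short", "sequence", "gc_fraction",
                     "mfe", "dg")
.SCAN_COLS_NULL <- c("shuffled_mean", "shuffled_sd", "z_score", "p_value",
                     "degenerate")
.SCAN_COLS_TAIL <- c("ensemble_diversity", "centroid_dbn", "mfe_dbn")

#' Write / read per-window scan output as TSV
#'
#' One row per window, tab-separated, with run metadata in `#`-prefixed
#' header comments. Coordinates in the file are 1-based inclusive (genome
#' browser convention); they are converted back to the package's internal
#' 0-based half-open convention on reading. Numeric fields round-trip to
#' at least 1e-9.
#'
#' @param scan an `rna_scan` object.
#' @param path file path (conventionally `win_<W>_step_<s>.tsv`).
#' @param timestamp include a generation timestamp comment.
#' @return `write_scan_tsv` returns `path` invisibly; `read_scan_tsv`
#'   returns an `rna_scan`.
#' @export
write_scan_tsv <- function(scan, path, timestamp = TRUE) {
  stopifnot(inherits(scan, "rna_scan"))
  cfg <- scan$config
  meta <- c(
    "# thermoscan window scan",
    if (timestamp) paste0("# generated=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("# engine=", scan$engine),
    paste0("# gene_id=", scan$gene_id),
    paste0("# sequence_length=", scan$sequence_length),
    paste0("# temperature_celsius=", format(cfg$temperature)),
    paste0("# window_size=", cfg$window_size),
    paste0("# step=", cfg$step),
    paste0("# num_shuffles=", cfg$num_shuffles),
    paste0("# seed=", cfg$seed),
    paste0("# compute_null=", cfg$compute_null),
    "# coordinates=1-based inclusive")
  w <- scan$windows
  cols <- c(.SCAN_COLS_CORE, if (cfg$compute_null) .SCAN_COLS_NULL,
            .SCAN_COLS_TAIL)
  w <- w[, cols, drop = FALSE]
  w$start <- w$start + 1L          # 1-based inclusive on disk
  num <- vapply(w, is.double, logical(1))
  for (cn in names(w)[num]) w[[cn]] <- sprintf("%.12g", w[[cn]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(w))
    writeLines(do.call(paste, c(unname(as.list(w)), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  if (!length(body)) stop("no header line found in ", path)
  meta <- list()
  kv <- regmatches(meta_lines, regexec("^# ([a-z_]+)=(.*)$", meta_lines))
  for (m in kv) if (length(m) == 3L) meta[[m[2]]] <- m[3]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need <- c(.SCAN_COLS_CORE, .SCAN_COLS_TAIL)
  if (!all(need %in% header))
    stop("malformed scan TSV header: missing column(s) ",
         paste(setdiff(need, header), collapse = ", "))
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  arity <- lengths(rows)
  bad <- which(arity != length(header))
  if (length(bad)) {
    lineno <- which(!is_meta)[1L + bad[1L]]
    stop(sprintf("malformed scan TSV: line %d has %d fields, expected %d",
                 lineno, arity[bad[1L]], length(header)))
  }
  if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(matrix(character(0), ncol = length(header)),
                        stringsAsFactors = FALSE)
  }
  names(df) <- header
  int_cols <- c("start", "end")
  chr_cols <- c("sequence", "centroid_dbn", "mfe_dbn")
  lgl_cols <- c("short", "degenerate")
  for (cn in header) {
    df[[cn]] <- if (cn %in% int_cols) as.integer(df[[cn]])
                else if (cn %in% chr_cols) df[[cn]]
                else if (cn %in% lgl_cols) as.logical(df[[cn]])
                else as.numeric(df[[cn]])
  }
  if (!nrow(df)) {
    df <- df[0, , drop = FALSE]
  } else {
    df$start <- df$start - 1L        # back to 0-based half-open
  }
  compute_null <- identical(meta$compute_null, "TRUE")
  cfg <- scan_config(
    window_size = as.integer(meta$window_size),
    step = as.integer(meta$step),
    num_shuffles = as.integer(meta$num_shuffles),
    temperature = as.numeric(meta$temperature_celsius),
    seed = as.integer(meta$seed), compute_null = compute_null)
  structure(list(windows = df, config = cfg,
                 engine = meta$engine %||% "unknown",
                 gene_id = meta$gene_id %||% "seq",
                 sequence = NULL,
                 sequence_length = as.integer(meta$sequence_length)),
            class = "rna_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
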