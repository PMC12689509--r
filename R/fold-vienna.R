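#' ViennaRNA RNAfold engine
#'
#' Adapter around the `RNAfold` command-line program (nearest-neighbor
#' thermodynamics). Sequences are folded in batches through a single
#' process invocation; the MFE structure and energy, the centroid structure
#' and the ensemble diversity are parsed from the program output, and base
#' pair probabilities (when requested through [fold()]) from the
#' PostScript dot plot. The engine's reported ensemble diversity is used
#' as-is when scanning with this engine.
#'
#' @param path path to the `RNAfold` executable (found on the PATH by
#'   default).
#' @return an engine object of class `c("vienna_engine", "fold_engine")`.
#' @export
vienna_engine <- function(path = Sys.which("RNAfold")) {
  if (!nzchar(path))
    stop("RNAfold executable not found; install ViennaRNA or use toy_engine()")
  ver <- tryCatch(system2(path, "--version", stdout = TRUE, stderr = TRUE),
                  error = function(e) "unknown")
  ver <- sub("^RNAfold\\s+", "", ver[1])
  structure(list(name = "ViennaRNA RNAfold", version = ver, path = path),
            class = c("vienna_engine", "fold_engine"))
}

# Run RNAfold on a batch of sequences inside a scratch directory.
# Returns the stdout lines.
.run_rnafold <- function(engine, sequences, temperature, args) {
  fa <- paste0(">s", seq_along(sequences), "\n", sequences, collapse = "\n")
  dir <- tempfile("rnafold")
  dir.create(dir)
  owd <- setwd(dir)
  on.exit({ setwd(owd); unlink(dir, recursive = TRUE) })
  out <- suppressWarnings(system2(
    engine$path, c(args, "-T", format(temperature)),
    stdout = TRUE, stderr = FALSE, input = fa))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("RNAfold exited with status %d", status))
  out
}

# Parse "STRUCT ( -5.80)" style lines.
.parse_struct_line <- function(line, open, close) {
  pat <- sprintf("^([.()]+)\\s+\\%s\\s*(-?[0-9.]+)(\\s+d=([0-9.]+))?\\%s",
                 open, close)
  m <- regmatches(line, regexec(pat, line))[[1]]
  if (!length(m)) stop("unexpected RNAfold output line: ", line)
  list(dbn = m[2], energy = as.numeric(m[3]),
       d = if (nchar(m[5])) as.numeric(m[5]) else NA_real_)
}

# Parse batched RNAfold stdout into a per-sequence data frame.
.parse_rnafold <- function(out, n_seq, partition) {
  hdr <- grep("^>", out)
  if (length(hdr) != n_seq)
    stop(sprintf("RNAfold returned %d records for %d sequences",
                 length(hdr), n_seq))
  per <- if (partition) 5L else 2L
  mfe <- numeric(n_seq); mfe_dbn <- character(n_seq)
  ed <- rep(NA_real_, n_seq); cent <- rep(NA_character_, n_seq)
  for (q in seq_len(n_seq)) {
    base <- hdr[q]
    m <- .parse_struct_line(out[base + 2L], "(", ")")
    mfe[q] <- m$energy; mfe_dbn[q] <- m$dbn
    if (partition) {
      cm <- .parse_struct_line(out[base + 4L], "{", "}")
      cent[q] <- cm$dbn
      edl <- regmatches(out[base + 5L],
                        regexec("ensemble diversity\\s+([0-9.]+)",
                                out[base + 5L]))[[1]]
      if (length(edl) < 2L)
        stop("could not parse ensemble diversity from RNAfold output")
      ed[q] <- as.numeric(edl[2])
    }
  }
  data.frame(mfe = mfe, mfe_dbn = mfe_dbn, ensemble_diversity = ed,
             centroid_dbn = cent, stringsAsFactors = FALSE)
}

#' @export
engine_mfe_batch.vienna_engine <- function(engine, sequences, temperature) {
  out <- .run_rnafold(engine, sequences, temperature, c("--noPS"))
  .parse_rnafold(out, length(sequences), partition = FALSE)$mfe
}

#' @export
engine_fold_batch.vienna_engine <- function(engine, sequences, temperature) {
  out <- .run_rnafold(engine, sequences, temperature,
                      c("--noPS", "--noDP", "-p"))
  .parse_rnafold(out, length(sequences), partition = TRUE)
}

#' @export
fold.vienna_engine <- function(sequence, temperature = 37,
                               engine = vienna_engine(),
                               pair_probabilities = TRUE) {
  s <- normalize_rna(sequence)
  ppdf <- NULL
  if (pair_probabilities) {
    # need the dot plot: run in a scratch dir without --noDP
    fa <- paste0(">ts\n", s)
    dir <- tempfile("rnafold")
    dir.create(dir)
    owd <- setwd(dir)
    on.exit({ setwd(owd); unlink(dir, recursive = TRUE) }, add = TRUE)
    out <- suppressWarnings(system2(
      engine$path, c("--noPS", "-p", "-T", format(temperature)),
      stdout = TRUE, stderr = FALSE, input = fa))
    res <- .parse_rnafold(out, 1L, partition = TRUE)
    dp <- readLines("ts_dp.ps", warn = FALSE)
    ub <- grep("ubox$", dp, value = TRUE)
    ub <- ub[grepl("^[0-9]+\\s+[0-9]+\\s+[0-9.eE+-]+\\s+ubox$", ub)]
    if (length(ub)) {
      f <- do.call(rbind, strsplit(ub, "\\s+"))
      ppdf <- data.frame(i = as.integer(f[, 1]) - 1L,
                         j = as.integer(f[, 2]) - 1L,
                         prob = as.numeric(f[, 3])^2)
      ppdf <- ppdf[order(ppdf$i, ppdf$j), , drop = FALSE]
      rownames(ppdf) <- NULL
    } else {
      ppdf <- data.frame(i = integer(0), j = integer(0), prob = numeric(0))
    }
    setwd(owd)
  } else {
    res <- engine_fold_batch(engine, s, temperature)
  }
  new_fold_result(
    sequence = s, temperature = temperature,
    mfe = res$mfe, mfe_pairs = dbn_to_pairs(res$mfe_dbn),
    pair_probabilities = ppdf,
    ensemble_diversity = res$ensemble_diversity,
    centroid_pairs = dbn_to_pairs(res$centroid_dbn),
    engine = engine,
    centroid_dbn = res$centroid_dbn, mfe_dbn = res$mfe_dbn)
}
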