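#' Folding engines
#'
#' A folding engine is the pluggable thermodynamic back end behind
#' [fold()] and [scan_sequence()]. Two engines ship with the package:
#'
#' * `toy_engine()` -- the bundled additive pair-energy model, computed by
#'   exact dynamic programming (Nussinov-style minimum energy with
#'   traceback; McCaskill-style inside/outside recursions for pair
#'   probabilities). Fully deterministic, no external software, fast enough
#'   for large simulation studies.
#' * `vienna_engine()` -- ViennaRNA's `RNAfold` program (nearest-neighbor
#'   Turner energies, partition function, centroid and ensemble diversity),
#'   the engine used for production transcript scans.
#'
#' @param params a [toy_energy_params()] object.
#' @return an engine object (classes `toy_engine`/`vienna_engine` +
#'   `fold_engine`).
#' @export
toy_engine <- function(params = toy_energy_params()) {
  stopifnot(inherits(params, "toy_energy_params"))
  structure(list(name = "thermoscan-toy", version = "1.0", params = params),
            class = c("toy_engine", "fold_engine"))
}

#' @export
print.fold_engine <- function(x, ...) {
  cat(sprintf("<fold_engine> %s %s\n", x$name, x$version))
  invisible(x)
}

engine_info <- function(engine) {
  paste(engine$name, engine$version)
}

#' Fold a single RNA sequence
#'
#' Predicts the minimum-free-energy (MFE) structure and Boltzmann-ensemble
#' statistics of one sequence at a fixed temperature.
#'
#' @param sequence RNA string (`T` is read as `U`; lowercase accepted;
#'   IUPAC ambiguity codes allowed but never paired by the toy engine).
#' @param temperature degrees Celsius, in `[0, 100]`.
#' @param engine a folding engine; see [toy_engine()] and [vienna_engine()].
#' @param pair_probabilities if `FALSE`, skip the (slower) base-pair
#'   probability computation; `ensemble_diversity` and the centroid are
#'   still returned.
#' @return an object of class `fold_result`: a list with elements
#'   `sequence`, `temperature_celsius`, `mfe_kcal_mol`, `mfe_pairs`,
#'   `mfe_dbn`, `pair_probabilities` (data frame `i`, `j`, `prob`; 0-based),
#'   `ensemble_diversity`, `centroid_pairs`, `centroid_dbn`, `engine`.
#' @examples
#' fold("GGGAAACCC", 37, engine = toy_engine())
#' @export
fold <- function(sequence, temperature = 37, engine = default_engine(),
                 pair_probabilities = TRUE) {
  s <- normalize_rna(sequence)
  if (!is.numeric(temperature) || temperature < 0 || temperature > 100)
    stop("temperature must be in [0, 100] degrees Celsius")
  UseMethod("fold", engine)
}

#' @export
fold.toy_engine <- function(sequence, temperature = 37,
                            engine = toy_engine(),
                            pair_probabilities = TRUE) {
  s <- normalize_rna(sequence)
  p <- engine$params
  mfe <- toy_mfe_cpp(s, p$energy_matrix, p$min_loop, p$stack)
  ens <- toy_ensemble_cpp(s, p$energy_matrix, p$min_loop, p$stack,
                          .RT(temperature), mfe$mfe)
  pp <- ens$pair_prob
  idx <- which(pp > 1e-12, arr.ind = TRUE)
  ppdf <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                     prob = pp[idx])
  ppdf <- ppdf[order(ppdf$i, ppdf$j), , drop = FALSE]
  rownames(ppdf) <- NULL
  mfe_pairs <- as_pair_table(cbind(mfe$i, mfe$j))
  centroid <- as_pair_table(cbind(ens$centroid_i, ens$centroid_j))
  new_fold_result(
    sequence = s, temperature = temperature,
    mfe = mfe$mfe, mfe_pairs = mfe_pairs,
    pair_probabilities = if (pair_probabilities) ppdf else NULL,
    ensemble_diversity = ens$ensemble_diversity,
    centroid_pairs = centroid, engine = engine)
}

new_fold_result <- function(sequence, temperature, mfe, mfe_pairs,
                            pair_probabilities, ensemble_diversity,
                            centroid_pairs, engine,
                            centroid_dbn = NULL, mfe_dbn = NULL) {
  n <- nchar(sequence)
  structure(list(
    sequence = sequence,
    temperature_celsius = temperature,
    mfe_kcal_mol = mfe,
    mfe_pairs = mfe_pairs,
    mfe_dbn = if (is.null(mfe_dbn)) pairs_to_dbn(mfe_pairs, n) else mfe_dbn,
    pair_probabilities = pair_probabilities,
    ensemble_diversity = ensemble_diversity,
    centroid_pairs = centroid_pairs,
    centroid_dbn = if (is.null(centroid_dbn)) pairs_to_dbn(centroid_pairs, n)
                   else centroid_dbn,
    engine = engine_info(engine)), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d nt at %g degC [%s]\n",
              nchar(x$sequence), x$temperature_celsius, x$engine))
  cat(sprintf("  MFE   %8.2f kcal/mol  %s\n", x$mfe_kcal_mol, x$mfe_dbn))
  cat(sprintf("  cent. %8s           %s\n", "", x$centroid_dbn))
  cat(sprintf("  ensemble diversity %.3f\n", x$ensemble_diversity))
  invisible(x)
}

#' Pick the default folding engine
#'
#' `vienna_engine()` when `RNAfold` is on the PATH, otherwise the bundled
#' reference engine.
#'
#' @return a `fold_engine` object.
#' @export
default_engine <- function() {
  if (nzchar(Sys.which("RNAfold"))) vienna_engine() else toy_engine()
}

# ---- internal batched interface used by the scanner --------------------

# MFE values only, one per sequence.
engine_mfe_batch <- function(engine, sequences, temperature) {
  UseMethod("engine_mfe_batch")
}

# Full per-window metrics: data.frame(mfe, mfe_dbn, ensemble_diversity,
# centroid_dbn), one row per sequence.
engine_fold_batch <- function(engine, sequences, temperature) {
  UseMethod("engine_fold_batch")
}

#' @export
engine_mfe_batch.toy_engine <- function(engine, sequences, temperature) {
  p <- engine$params
  toy_mfe_batch_cpp(sequences, p$energy_matrix, p$min_loop, p$stack)
}

#' @export
engine_fold_batch.toy_engine <- function(engine, sequences, temperature) {
  p <- engine$params
  rt <- .RT(temperature)
  out <- lapply(sequences, function(s) {
    mfe <- toy_mfe_cpp(s, p$energy_matrix, p$min_loop, p$stack)
    ens <- toy_ensemble_cpp(s, p$energy_matrix, p$min_loop, p$stack, rt,
                            mfe$mfe)
    n <- nchar(s)
    list(mfe = mfe$mfe,
         mfe_dbn = pairs_to_dbn(as_pair_table(cbind(mfe$i, mfe$j)), n),
         ed = ens$ensemble_diversity,
         centroid_dbn = pairs_to_dbn(
           as_pair_table(cbind(ens$centroid_i, ens$centroid_j)), n))
  })
  data.frame(mfe = vapply(out, `[[`, numeric(1), "mfe"),
             mfe_dbn = vapply(out, `[[`, character(1), "mfe_dbn"),
             ensemble_diversity = vapply(out, `[[`, numeric(1), "ed"),
             centroid_dbn = vapply(out, `[[`, character(1), "centroid_dbn"),
             stringsAsFactors = FALSE)
}
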