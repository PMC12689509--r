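#' Additive pair-energy model parameters
#'
#' The reference folding engine uses a deliberately simple thermodynamic
#' model: each base pair contributes a fixed, composition-dependent energy
#' (kcal/mol) and hairpin loops must contain at least `min_loop` unpaired
#' nucleotides. The model supports exact exhaustive enumeration for short
#' sequences, which makes it usable as an oracle for the dynamic-programming
#' engine and as a fast stand-alone engine for simulation studies.
#'
#' @param gc,au,gu energies (kcal/mol, all `<= 0`) for GC/CG, AU/UA and
#'   GU/UG pairs.
#' @param stack additional energy (kcal/mol, `<= 0`) for every pair whose
#'   immediate interior neighbour is also paired. The default 0 gives the
#'   plain additive model; a negative value makes contiguous helices
#'   strictly preferable to scattered pairings with the same composition,
#'   emulating the helix cooperativity of nearest-neighbor models.
#' @param min_loop minimum number of unpaired nucleotides in a hairpin loop.
#' @return an object of class `toy_energy_params`.
#' @export
toy_energy_params <- function(gc = -3.0, au = -2.0, gu = -1.0, stack = 0,
                              min_loop = 3L) {
  if (any(c(gc, au, gu, stack) > 0))
    stop("pair and stacking energies must be <= 0")
  if (min_loop < 0) stop("min_loop must be >= 0")
  E <- matrix(NA_real_, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                              c("A", "C", "G", "U")))
  E["G", "C"] <- E["C", "G"] <- gc
  E["A", "U"] <- E["U", "A"] <- au
  E["G", "U"] <- E["U", "G"] <- gu
  structure(list(pair_energies = c(GC = gc, AU = au, GU = gu),
                 stack = stack, energy_matrix = E,
                 min_loop = as.integer(min_loop)),
            class = "toy_energy_params")
}

# Energy of an explicit pair set under the toy model: additive pair terms
# plus the stacking bonus for adjacent pairs.
toy_structure_energy <- function(pairs, sequence, params) {
  m <- as_pair_table(pairs)
  if (!nrow(m)) return(0)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  e <- sum(vapply(seq_len(nrow(m)), function(r)
    .pair_energy(params, ch[m[r, 1L] + 1L], ch[m[r, 2L] + 1L]),
    numeric(1)))
  key <- paste(m[, 1L], m[, 2L])
  stacks <- sum(paste(m[, 1L] + 1L, m[, 2L] - 1L) %in% key)
  e + params$stack * stacks
}

.pair_energy <- function(params, a, b) {
  codes <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  ia <- codes[a]; ib <- codes[b]
  if (is.na(ia) || is.na(ib)) return(NA_real_)
  params$energy_matrix[ia, ib]
}

#' Exhaustively enumerate all nested secondary structures
#'
#' Generates every non-crossing structure of a short sequence under the
#' additive pair model, including the empty structure. Serves as the
#' independent oracle for the dynamic-programming engine; the interval
#' recursion (position i unpaired, or paired with each admissible k)
#' visits each structure exactly once.
#'
#' @param sequence RNA string.
#' @param params a [toy_energy_params()] object.
#' @param max_length guard on sequence length (enumeration is exponential).
#' @return a list of `list(pairs = <two-column matrix>, energy = <kcal/mol>)`.
#' @export
enumerate_structures <- function(sequence, params = toy_energy_params(),
                                 max_length = 18L) {
  s <- normalize_rna(sequence)
  n <- nchar(s)
  if (n > max_length)
    stop(sprintf(
      "sequence length %d exceeds the enumeration guard (%d); %s",
      n, max_length, "use the dynamic-programming engine instead"))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  minloop <- params$min_loop
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {  # closed interval, 0-based
    if (i > j) return(list(list(pairs = NULL)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    for (str in rec(i + 1L, j))  # i unpaired
      out[[length(out) + 1L]] <- str
    for (k in seq_len(max(0L, j - (i + minloop)))) {
      k <- i + minloop + k
      e <- .pair_energy(params, ch[i + 1L], ch[k + 1L])
      if (is.na(e)) next
      inner <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (a in inner) for (b in right)
        out[[length(out) + 1L]] <- list(pairs = rbind(c(i, k), a$pairs,
                                                      b$pairs))
    }
    memo[[key]] <- out
    out
  }
  res <- rec(0L, n - 1L)
  lapply(res, function(x) {
    p <- as_pair_table(x$pairs)
    list(pairs = p, energy = toy_structure_energy(p, s, params))
  })
}

#' Boltzmann ensemble statistics from an enumerated structure list
#'
#' Weights every structure by `exp(-E/RT)`, with
#' `RT = 0.0019872 kcal/(mol K) * (temperature + 273.15)`, and derives base
#' pair probabilities, ensemble diversity (the expected base-pair distance
#' between two independent draws, `sum 2 p (1 - p)`), and the centroid
#' structure (all pairs with probability above one half).
#'
#' @param structures list as returned by [enumerate_structures()].
#' @param temperature degrees Celsius.
#' @return `list(pair_probabilities, ensemble_diversity, centroid_pairs)`;
#'   `pair_probabilities` is a data frame with columns `i`, `j`, `prob`.
#' @export
ensemble_from_enumeration <- function(structures, temperature = 37) {
  if (!length(structures)) stop("empty structure list")
  rt <- .RT(temperature)
  en <- vapply(structures, `[[`, numeric(1), "energy")
  w <- exp(-(en - min(en)) / rt)
  w <- w / sum(w)
  acc <- new.env(parent = emptyenv())
  for (s in seq_along(structures)) {
    p <- structures[[s]]$pairs
    if (!NROW(p)) next
    for (r in seq_len(nrow(p))) {
      key <- paste(p[r, 1L], p[r, 2L])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w[s]
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    pp <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                     prob = vapply(keys, function(k) acc[[k]], numeric(1)),
                     row.names = NULL)
    pp <- pp[order(pp$i, pp$j), , drop = FALSE]
    rownames(pp) <- NULL
  } else {
    pp <- data.frame(i = integer(0), j = integer(0), prob = numeric(0))
  }
  ed <- sum(2 * pp$prob * (1 - pp$prob))
  centroid <- as_pair_table(pp[pp$prob > 0.5, c("i", "j"), drop = FALSE])
  list(pair_probabilities = pp, ensemble_diversity = ed,
       centroid_pairs = centroid)
}
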