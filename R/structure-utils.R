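#' Sequence and secondary-structure utilities
#'
#' Helpers shared across the scanning, consensus and track-writing layers:
#' validation/normalisation of RNA strings, conversion between dot-bracket
#' notation and base-pair tables, crossing (pseudoknot-like) detection and
#' GC content.
#'
#' All base-pair tables in this package are two-column integer matrices or
#' data frames with columns `i` and `j`, 0-based transcript positions with
#' `i < j`.
#'
#' @name structure-utils
NULL

.IUPAC <- c("A", "C", "G", "U", "T", "N",
            "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalise an RNA/DNA string
#'
#' Uppercases, maps T to U and validates against the IUPAC nucleotide
#' alphabet. Ambiguity codes are kept (they are simply never paired by the
#' reference engine).
#'
#' @param sequence a single character string.
#' @return the normalised RNA string.
#' @export
normalize_rna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  if (nchar(sequence) == 0L) stop("empty sequence")
  s <- chartr("t", "u", sequence)
  s <- toupper(s)
  s <- chartr("T", "U", s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(ch %in% .IUPAC))
  if (length(bad))
    stop(sprintf("invalid nucleotide character '%s' at position %d",
                 ch[bad[1L]], bad[1L]))
  s
}

# Canonical pair table: integer matrix, columns i, j (0-based, i < j),
# rows sorted by (i, j).
as_pair_table <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  m <- cbind(i = as.integer(pairs[, 1L]), j = as.integer(pairs[, 2L]))
  flip <- m[, 1L] > m[, 2L]
  if (any(flip)) m[flip, ] <- m[flip, c(2L, 1L)]
  if (any(m[, 1L] == m[, 2L])) stop("a position cannot pair with itself")
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  if (anyDuplicated(m)) m <- unique(m)
  pos <- c(m[, 1L], m[, 2L])
  if (anyDuplicated(pos))
    stop("invalid pair set: a position participates in more than one pair")
  m
}

#' Base-pair distance between two structures
#'
#' The size of the symmetric difference of two base-pair sets -- the metric
#' underlying ensemble diversity and centroid comparison.
#'
#' @param pairs_a,pairs_b two-column matrices/data frames of 0-based pairs.
#' @return integer count.
#' @export
base_pair_distance <- function(pairs_a, pairs_b) {
  a <- as_pair_table(pairs_a)
  b <- as_pair_table(pairs_b)
  ka <- paste(a[, 1L], a[, 2L])
  kb <- paste(b[, 1L], b[, 2L])
  sum(!(ka %in% kb)) + sum(!(kb %in% ka))
}

# Do any two pairs in the table cross (i < k < j < l)?
pairs_cross <- function(pairs) {
  m <- as_pair_table(pairs)
  n <- nrow(m)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    crossing <- m[(a + 1L):n, 1L] < m[a, 2L] & m[(a + 1L):n, 2L] > m[a, 2L]
    if (any(crossing)) return(TRUE)
  }
  FALSE
}

# Remove crossing pairs greedily, keeping higher-weight pairs first.
# `weight` must align with the rows of `pairs`; pairs must already have
# i < j in each row.  Returns list(kept, dropped).
remove_crossings <- function(pairs, weight = NULL) {
  m <- cbind(i = as.integer(pairs[, 1L]), j = as.integer(pairs[, 2L]))
  if (is.null(weight)) weight <- rep(0, nrow(m))
  stopifnot(length(weight) == nrow(m), all(m[, 1L] < m[, 2L]))
  ord <- order(-weight, m[, 1L], m[, 2L])
  kept <- matrix(integer(0), ncol = 2L)
  kept_rows <- integer(0)
  for (r in ord) {
    cand <- m[r, , drop = FALSE]
    ok <- TRUE
    if (nrow(kept)) {
      cross <- (kept[, 1L] < cand[1L] & cand[1L] < kept[, 2L] &
                  kept[, 2L] < cand[2L]) |
               (cand[1L] < kept[, 1L] & kept[, 1L] < cand[2L] &
                  cand[2L] < kept[, 2L])
      ok <- !any(cross)
    }
    if (ok) { kept <- rbind(kept, cand); kept_rows <- c(kept_rows, r) }
  }
  dropped <- setdiff(seq_len(nrow(m)), kept_rows)
  list(kept = as_pair_table(m[kept_rows, , drop = FALSE]),
       dropped = m[dropped, , drop = FALSE])
}

#' Convert a pair table to dot-bracket notation
#'
#' @param pairs two-column matrix of 0-based pairs (must be nested).
#' @param length structure length in nucleotides.
#' @param offset subtracted from coordinates before writing (for motifs in
#'   transcript coordinates).
#' @return a dot-bracket string.
#' @export
pairs_to_dbn <- function(pairs, length, offset = 0L) {
  m <- as_pair_table(pairs)
  if (nrow(m)) {
    m[, 1L] <- m[, 1L] - as.integer(offset)
    m[, 2L] <- m[, 2L] - as.integer(offset)
    if (any(m < 0L) || any(m >= length))
      stop("pair coordinates outside [offset, offset + length)")
    if (pairs_cross(m))
      stop("crossing pairs cannot be written as dot-bracket; resolve first")
  }
  ch <- rep(".", length)
  ch[m[, 1L] + 1L] <- "("
  ch[m[, 2L] + 1L] <- ")"
  paste(ch, collapse = "")
}

#' Parse dot-bracket notation into a pair table
#'
#' @param dbn a dot-bracket string using `(`, `)` and `.`.
#' @return two-column integer matrix of 0-based pairs.
#' @export
dbn_to_pairs <- function(dbn) {
  ch <- strsplit(dbn, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket string may only contain '(', ')' and '.'")
  stack <- integer(0)
  out_i <- integer(0); out_j <- integer(0)
  for (p in seq_along(ch)) {
    if (ch[p] == "(") stack <- c(stack, p - 1L)
    else if (ch[p] == ")") {
      if (!length(stack)) stop(sprintf("unbalanced ')' at position %d", p))
      out_i <- c(out_i, stack[length(stack)])
      out_j <- c(out_j, p - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced '(' in dot-bracket string")
  as_pair_table(cbind(out_i, out_j))
}

#' GC fraction of a sequence
#'
#' @param sequence RNA/DNA string.
#' @return fraction of G or C characters in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  mean(ch %in% c("G", "C", "S"))
}
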