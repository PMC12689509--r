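# z-weighted consensus pairing, competition resolution and motif extraction.

# Minimal windows for crafted-structure tests.  dbn strings are placed at
# the given transcript starts.
windows_from_dbn <- function(starts, dbns, zs) {
  n <- nchar(dbns[1])
  data.frame(start = starts, end = starts + n, short = FALSE,
             sequence = strrep("N", n), gc_fraction = 0.5,
             mfe = -1, dg = -1, shuffled_mean = 0, shuffled_sd = 1,
             z_score = zs, p_value = 0.5, degenerate = FALSE,
             ensemble_diversity = 1, centroid_dbn = dbns, mfe_dbn = dbns,
             stringsAsFactors = FALSE)
}

test_that("pair evidence accumulates window structures in transcript coordinates", {
  # one window, one hairpin
  sc <- fake_scan(windows_from_dbn(0L, "((((...))))", -2))
  ev <- accumulate_pair_evidence(sc)
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$mean_z, rep(-2, 4))
  expect_equal(ev$count, rep(1L, 4))

  # two overlapping windows sharing transcript pair (5, 20)
  d1 <- paste0(strrep(".", 5), "(", strrep(".", 14), ")", strrep(".", 4))
  d2 <- paste0(strrep(".", 3), "(", strrep(".", 14), ")", strrep(".", 6))
  sc <- fake_scan(windows_from_dbn(c(0L, 2L), c(d1, d2), c(-2, -1)),
                  sequence_length = 27L)
  ev <- accumulate_pair_evidence(sc)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$i, 5L); expect_equal(ev$j, 20L)
  expect_equal(ev$count, 2L)
  expect_equal(ev$mean_z, -1.5)
  expect_equal(ev$min_window_z, -2)
  expect_equal(ev$z_values[[1]], c(-2, -1))

  # disjoint pairs stay separate
  sc <- fake_scan(windows_from_dbn(c(0L, 30L),
                                   c("((((...))))", "(((.....)))"),
                                   c(-1, -3)), sequence_length = 41L)
  ev <- accumulate_pair_evidence(sc)
  expect_equal(nrow(ev), 7L)
  expect_true(all(ev$count == 1L))

  # scan-only runs cannot feed the consensus
  sc <- fake_scan(windows_from_dbn(0L, "((((...))))", -2)[
    , !names(windows_from_dbn(0L, "((((...))))", -2)) %in%
      c("z_score", "p_value", "shuffled_mean", "shuffled_sd",
        "degenerate")], compute_null = FALSE)
  expect_error(accumulate_pair_evidence(sc), "full run")
})

make_evidence <- function(i, j, mean_z, count = rep(1L, length(i)),
                          min_z = mean_z, length = 30L) {
  ev <- data.frame(i = as.integer(i), j = as.integer(j),
                   count = as.integer(count), mean_z = mean_z,
                   min_window_z = min_z)
  ev$z_values <- as.list(mean_z)
  attr(ev, "length") <- length
  attr(ev, "gene_id") <- "ev"
  class(ev) <- c("pair_evidence", "data.frame")
  ev
}

test_that("competition resolution selects mutual best pairs deterministically", {
  # position 5 prefers (5,20) over (5,22); 20's only candidate is (5,20)
  ev <- make_evidence(c(5, 5), c(20, 22), c(-2, 1))
  m <- resolve_competition(ev)
  expect_equal(m$pairs$i, 5L); expect_equal(m$pairs$j, 20L)
  expect_equal(m$partner[5 + 1], 20L)
  expect_equal(m$partner[20 + 1], 5L)
  expect_true(is.na(m$partner[22 + 1]))
  # partner map is symmetric
  paired <- which(!is.na(m$partner)) - 1L
  expect_true(all(m$partner[m$partner[paired + 1L] + 1L] == paired))

  # equal mean_z and count: shorter span wins
  ev <- make_evidence(c(5, 5), c(24, 20), c(-1, -1))
  m <- resolve_competition(ev)
  expect_equal(m$pairs$j, 20L)

  # higher count beats span at equal mean_z
  ev <- make_evidence(c(5, 5), c(24, 20), c(-1, -1), count = c(3L, 1L))
  m <- resolve_competition(ev)
  expect_equal(m$pairs$j, 24L)

  # a non-mutual nomination never enters: 5 prefers 20, but 20 prefers 3
  ev <- make_evidence(c(5, 3), c(20, 20), c(-2, -4))
  m <- resolve_competition(ev)
  expect_equal(m$pairs$i, 3L)
  expect_true(is.na(m$partner[5 + 1]))
})

test_that("a single-window consensus equals that window's MFE structure", {
  dbn <- "..(((((....)))))...."
  sc <- fake_scan(windows_from_dbn(0L, dbn, -2.5))
  m <- consensus_structure(sc)
  expect_equal(m$pairs[, c("i", "j")],
               as.data.frame(dbn_to_pairs(dbn)), ignore_attr = TRUE)
})

test_that("threshold filtering is nested and respects the pair z-values", {
  ev <- make_evidence(c(2, 10, 16), c(8, 15, 22), c(-2.5, -1.2, -0.3))
  m <- resolve_competition(ev)
  all_p <- filter_by_threshold(m, NULL)
  p1 <- filter_by_threshold(m, -1)
  p2 <- filter_by_threshold(m, -2)
  expect_equal(nrow(all_p), 3L)
  expect_equal(nrow(p1), 2L)
  expect_equal(nrow(p2), 1L)
  k <- function(d) paste(d$i, d$j)
  expect_true(all(k(p2) %in% k(p1)))
  expect_true(all(k(p1) %in% k(all_p)))

  empty <- resolve_competition(make_evidence(integer(0), integer(0),
                                             numeric(0)))
  for (th in list(NULL, -1, -2))
    expect_equal(nrow(filter_by_threshold(empty, th)), 0L)
})

test_that("motif extraction groups pairs by gap and trims flanks", {
  # one isolated hairpin -> one motif
  sc <- fake_scan(windows_from_dbn(0L, "...((((....))))...", -3))
  m <- consensus_structure(sc)
  ms <- extract_motifs(m, threshold = -2)
  expect_length(ms, 1L)
  expect_equal(ms[[1]]$dbn, "((((....))))")
  expect_equal(ms[[1]]$start, 3L)
  expect_equal(ms[[1]]$min_window_z, -3)

  # two hairpins far apart -> two motifs; close together -> merged
  far <- make_evidence(c(0, 1, 200, 201), c(10, 9, 210, 209),
                       rep(-3, 4), length = 230L)
  ms <- extract_motifs(resolve_competition(far), threshold = -2)
  expect_length(ms, 2L)
  expect_equal(vapply(ms, `[[`, numeric(1), "start"), c(0, 200))

  near <- make_evidence(c(0, 1, 16, 17), c(10, 9, 26, 25),
                        rep(-3, 4), length = 40L)
  expect_length(extract_motifs(resolve_competition(near),
                               threshold = -2, min_gap = 10), 1L)
  expect_length(extract_motifs(resolve_competition(near),
                               threshold = -2, min_gap = 3), 2L)
})

test_that("trim_motif tightens coordinates and is idempotent", {
  # a motif with unpaired flanks (as a user might construct one)
  m <- structure(list(start = 0L, end = 12L, dbn = "..((....))..",
                      pairs = data.frame(i = c(2L, 3L), j = c(9L, 8L),
                                         mean_z = c(-2, -2),
                                         count = c(1L, 1L),
                                         min_window_z = c(-2, -2)),
                      min_window_z = -2, mean_z = -2,
                      region_label = NA_character_, gene_id = "g"),
                 class = "motif")
  t1 <- trim_motif(m)
  expect_equal(t1$start, 2L)
  expect_equal(t1$end, 10L)
  expect_equal(t1$dbn, "((....))")
  expect_identical(trim_motif(t1), t1)
  # already-flush motifs pass through unchanged
  ev <- make_evidence(c(2, 3), c(9, 8), c(-2, -2))
  flush <- extract_motifs(resolve_competition(ev), threshold = -1)[[1]]
  expect_identical(trim_motif(flush)$dbn, flush$dbn)
  # zero-pair motif refuses
  m0 <- m; m0$pairs <- m$pairs[0, ]
  expect_error(trim_motif(m0), "zero pairs")
})

test_that("every consensus pair traces back to a window MFE structure", {
  sc <- scan_sequence(planted_gene(7), scan_config(40, 2, 30, 37, 7), TOY)
  m <- consensus_structure(sc)
  expect_true(all(m$pairs$count >= 1))
  ev <- m$evidence
  k <- function(d) paste(d$i, d$j)
  expect_true(all(k(m$pairs) %in% k(ev)))
  # provenance: recompute one pair's window membership from the scan
  if (nrow(m$pairs)) {
    pr <- m$pairs[1, ]
    hit <- FALSE
    for (r in seq_len(nrow(sc$windows))) {
      p <- dbn_to_pairs(sc$windows$mfe_dbn[r])
      if (nrow(p) &&
          any(p[, 1] + sc$windows$start[r] == pr$i &
              p[, 2] + sc$windows$start[r] == pr$j)) hit <- TRUE
    }
    expect_true(hit)
  }
})

test_that("a planted ordered hairpin is recovered by the z <= -1 consensus", {
  g <- planted_gene(31)
  planted <- attr(g, "element")$pairs
  sc <- scan_sequence(as.character(g), scan_config(40, 1, 50, 37, 31),
                      TOY_STACK)
  m <- consensus_structure(sc)
  surv <- filter_by_threshold(m, -1)
  recovered <- sum(paste(planted[, 1], planted[, 2]) %in%
                     paste(surv$i, surv$j))
  expect_gte(recovered / nrow(planted), 0.9)
})
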