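# Temperature-differential ensemble-diversity screen.

ed_scan <- function(eds, temperature, starts = seq_along(eds) - 1L,
                    short = FALSE, centroids = NULL) {
  n <- length(eds)
  if (is.null(centroids)) centroids <- rep(strrep(".", 12), n)
  fake_scan(data.frame(start = starts, end = starts + 12L,
                       short = rep_len(short, n), sequence = strrep("N", 12),
                       gc_fraction = 0.5, mfe = -1, dg = -1,
                       ensemble_diversity = eds, centroid_dbn = centroids,
                       mfe_dbn = centroids, stringsAsFactors = FALSE),
            temperature = temperature, window_size = 12L,
            compute_null = FALSE)
}

test_that("delta_ed subtracts aligned windows with the high-minus-low convention", {
  lo <- ed_scan(c(5, 2, 1), 28); hi <- ed_scan(c(9.2, 2, 0.5), 42)
  d <- delta_ed(lo, hi)
  expect_equal(d$delta_ed, c(4.2, 0, -0.5))
  expect_equal(d$delta_ed, d$ed_high - d$ed_low)
  # identical scans: all zero
  expect_true(all(delta_ed(lo, lo)$delta_ed == 0))
  # antisymmetry under swapping the arguments
  expect_equal(delta_ed(hi, lo)$delta_ed, -d$delta_ed)
  # mismatched window sets are refused with the offending coordinate
  hi2 <- ed_scan(c(9.2, 2, 0.5), 42, starts = c(0L, 1L, 5L))
  expect_error(delta_ed(lo, hi2), "mismatch")
  expect_error(delta_ed(lo, ed_scan(c(1, 2), 42)), "differ")
})

test_that("short-flagged windows are excluded and counted", {
  lo <- ed_scan(c(5, 2, 1), 28, short = c(FALSE, TRUE, FALSE))
  hi <- ed_scan(c(6, 9, 2), 42, short = c(FALSE, TRUE, FALSE))
  d <- delta_ed(lo, hi)
  expect_equal(nrow(d), 2L)
  expect_equal(attr(d, "n_excluded"), 1L)
})

test_that("gene summaries report mean, spread and extreme windows", {
  d <- delta_ed(ed_scan(c(0, 0, 0), 28), ed_scan(c(1, 2, 3), 42))
  g <- gene_summary("g1", d)
  expect_equal(g$mean_delta_ed, 2)
  expect_equal(unname(g$max_window), c(2, 3))
  expect_equal(unname(g$min_window), c(0, 1))
  expect_equal(g$n_windows, 3L)

  # single window: sd undefined and flagged
  d1 <- delta_ed(ed_scan(1, 28), ed_scan(3, 42))
  g1 <- gene_summary("g2", d1)
  expect_true(is.na(g1$sd_delta_ed))
  expect_true(g1$sd_undefined)

  # symmetric deltas average to zero
  d2 <- delta_ed(ed_scan(c(3, 1), 28), ed_scan(c(1, 3), 42))
  expect_equal(gene_summary("g3", d2)$mean_delta_ed, 0)

  expect_error(gene_summary("g4", d2[0, ]), "no delta-ED")
})

fake_summary <- function(id, m)
  structure(list(gene_id = id, n_windows = 10L, mean_delta_ed = m,
                 sd_delta_ed = 1, sd_undefined = FALSE,
                 max_window = c(0, m), min_window = c(0, m),
                 n_excluded = 0L), class = "gene_thermo_summary")

test_that("population statistics use sample sd and interpolated quartiles", {
  pop <- population_stats(lapply(1:5, function(i)
    fake_summary(paste0("g", i), i)))
  expect_equal(pop$n_genes, 5L)
  expect_equal(pop$mean, 3); expect_equal(pop$median, 3)
  expect_equal(pop$q1, 2); expect_equal(pop$q3, 4)
  expect_equal(pop$sd, sd(1:5))

  # even n: median interpolates
  pop4 <- population_stats(lapply(1:4, function(i)
    fake_summary(paste0("g", i), i)))
  expect_equal(pop4$median, 2.5)

  # constant cohort
  popc <- population_stats(lapply(1:3, function(i)
    fake_summary(paste0("g", i), 2)))
  expect_equal(popc$sd, 0)
  expect_equal(popc$q1, popc$median)
  expect_equal(popc$q3, popc$median)

  expect_error(population_stats(list(fake_summary("g", 1))), "at least 2")
})

test_that("standard scores are centered population z-values", {
  pop <- population_stats(lapply(1:5, function(i)
    fake_summary(paste0("g", i), i)))
  expect_equal(standard_score(fake_summary("x", 3), pop), 0)
  expect_equal(standard_score(fake_summary("x", 3 + pop$sd), pop), 1)
  expect_equal(standard_score(fake_summary("x", 5), pop), 1.2649,
               tolerance = 1e-4)
  # scores of the cohort's own genes average to zero
  scores <- vapply(1:5, function(i)
    standard_score(fake_summary(paste0("g", i), i), pop), numeric(1))
  expect_equal(mean(scores), 0, tolerance = 1e-9)

  popc <- population_stats(lapply(1:3, function(i)
    fake_summary(paste0("g", i), 2)))
  expect_error(standard_score(fake_summary("x", 2), popc), "sd")
})

test_that("one-sample t-test matches the closed-form statistic", {
  # centered family: t = 0, p = 1
  tt <- one_sample_t_test(c(2, 3, 4), 3)
  expect_equal(tt$t_statistic, 0)
  expect_equal(tt$p_value, 1)

  # textbook case, verified against the t distribution directly
  x <- c(1, 2, 3, 4)
  tt <- one_sample_t_test(x, 2)
  se <- sd(x) / sqrt(4)
  tman <- (mean(x) - 2) / se
  expect_equal(tt$standard_error, se)
  expect_equal(tt$t_statistic, tman, tolerance = 1e-12)
  expect_equal(tt$t_statistic, 0.7746, tolerance = 1e-4)
  expect_equal(tt$degrees_freedom, 3L)
  expect_equal(tt$p_value, 2 * stats::pt(-abs(tman), df = 3),
               tolerance = 1e-12)
  expect_equal(tt$p_value, 0.495, tolerance = 1e-3)

  # shifting the reference by c shifts t by -c/SE
  t2 <- one_sample_t_test(x, 2.5)
  expect_equal(t2$t_statistic, tt$t_statistic - 0.5 / se,
               tolerance = 1e-12)

  expect_error(one_sample_t_test(3, 0), "n >= 2")
  expect_error(one_sample_t_test(c(2, 2, 2), 0), "constant")
})

test_that("extreme-window selection ranks by the requested mode", {
  d <- delta_ed(ed_scan(c(0, 0, 0), 28), ed_scan(c(0, 5, -7), 42))
  expect_equal(top_delta_windows(d, 1, "absolute")$delta_ed, -7)
  expect_equal(top_delta_windows(d, 1, "positive")$delta_ed, 5)
  expect_equal(top_delta_windows(d, 1, "negative")$delta_ed, -7)
  expect_equal(nrow(top_delta_windows(d, 10)), 3L)   # k clipped
  # ties resolve in ascending coordinate order
  dt <- delta_ed(ed_scan(c(0, 0), 28), ed_scan(c(3, 3), 42))
  expect_equal(top_delta_windows(dt, 2, "positive")$window_start, c(0, 1))
})

test_that("centroid comparison reports melted and formed pairs", {
  lo <- ed_scan(c(1, 1), 28, centroids = c("((......))..", "(((....))).."))
  hi <- ed_scan(c(2, 2), 42, centroids = c("............", "((......)).."))
  # total melt: everything lost
  cs <- centroid_shift(lo, hi, 0L)
  expect_equal(cs$distance, 2L)
  expect_equal(nrow(cs$gained), 0L)
  expect_equal(cs$lost, rbind(c(0L, 9L), c(1L, 8L)), ignore_attr = TRUE)
  # rearrangement: symmetric difference counts both sides
  cs2 <- centroid_shift(lo, hi, 1L)
  expect_equal(cs2$distance, base_pair_distance(
    dbn_to_pairs("(((....)))"), dbn_to_pairs("((......))")))
  expect_equal(nrow(cs2$gained) + nrow(cs2$lost), cs2$distance)
  # identical centroids
  cs3 <- centroid_shift(lo, lo, 0L)
  expect_equal(cs3$distance, 0L)
  expect_error(centroid_shift(lo, hi, 99L), "not present")
})

test_that("toy-engine delta-ED is antisymmetric on real scans", {
  s <- random_sequence(70, seed = 55)
  lo <- scan_sequence(s, scan_config(40, 3, 0, 28, compute_null = FALSE),
                      TOY)
  hi <- scan_sequence(s, scan_config(40, 3, 0, 42, compute_null = FALSE),
                      TOY)
  d <- delta_ed(lo, hi)
  expect_equal(delta_ed(hi, lo)$delta_ed, -d$delta_ed)
  expect_equal(attr(d, "temperature_low"), 28)
  expect_equal(attr(d, "temperature_high"), 42)
})
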