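# Synthetic transcript and cohort generators.

test_that("random sequences honor length, composition and seeding", {
  s <- random_sequence(500, 1.0, seed = 1)
  expect_equal(nchar(s), 500L)
  expect_true(all(strsplit(s, "")[[1]] %in% c("G", "C")))
  expect_true(all(strsplit(random_sequence(200, 0, seed = 1), "")[[1]]
                  %in% c("A", "U")))
  expect_identical(random_sequence(100, 0.5, seed = 7),
                   random_sequence(100, 0.5, seed = 7))
  expect_false(identical(random_sequence(100, 0.5, seed = 7),
                         random_sequence(100, 0.5, seed = 8)))
  expect_error(random_sequence(0), "length")
  expect_error(random_sequence(10, 1.2), "gc_fraction")
})

test_that("realized GC tracks the requested fraction for long sequences", {
  for (seed in 1:5) for (gc in c(0.3, 0.5, 0.7)) {
    s <- random_sequence(500, gc, seed = seed)
    expect_lt(abs(gc_fraction(s) - gc), 0.03 + 3 * sqrt(gc * (1 - gc) / 500))
  }
})

test_that("planted hairpins are perfect inverted repeats at the stated site", {
  bg <- strrep("A", 100)
  s <- plant_hairpin(bg, 50, 6, 4, composition = "GC", seed = 2)
  el <- attr(s, "element")
  expect_equal(el$start, 50L)
  expect_equal(el$end, 66L)
  ch <- strsplit(as.character(s), "")[[1]]
  rc <- c(A = "U", C = "G", G = "C", U = "A")
  for (t in 0:5)
    expect_equal(ch[50 + t + 1], unname(rc[ch[66 - t]]))
  # background untouched outside the element
  expect_equal(substr(as.character(s), 1, 50), strrep("A", 50))
  expect_equal(substr(as.character(s), 67, 100), strrep("A", 34))

  expect_error(plant_hairpin(bg, 95, 6, 4), "does not fit")
  expect_error(plant_hairpin(bg, -1, 6, 4), "does not fit")
  expect_error(plant_hairpin(bg, 10, 6, 2), "loop_length")
})

test_that("a planted GC stem is the toy-model MFE of its local window", {
  s <- plant_hairpin(strrep("A", 40), 12, 6, 4, composition = "GC",
                     seed = 9)
  el <- attr(s, "element")
  f <- fold(substr(s, el$start + 1, el$end), 37, engine = TOY)
  local_pairs <- cbind(el$pairs[, 1] - el$start, el$pairs[, 2] - el$start)
  expect_equal(f$mfe_pairs, local_pairs, ignore_attr = TRUE)
  expect_equal(f$mfe_kcal_mol, -18)   # 6 GC pairs
})

test_that("cohorts are reproducible with labeled families and thermometers", {
  co <- make_cohort(10, families = c(Hsf = 3, other = 7),
                    thermometer_fraction = 0.2, seed = 4)
  genes <- co$manifest[!duplicated(co$manifest$gene_id), ]
  expect_equal(nrow(genes), 10L)
  expect_equal(sum(genes$family == "Hsf"), 3L)
  expect_equal(sum(genes$thermometer), 2L)
  expect_length(co$sequences, 10L)
  expect_true(all(nchar(co$sequences) == 200L))

  co2 <- make_cohort(10, families = c(Hsf = 3, other = 7),
                     thermometer_fraction = 0.2, seed = 4)
  expect_identical(co$sequences, co2$sequences)
  expect_identical(co$manifest, co2$manifest)

  # null cohort has no elements
  null <- make_cohort(5, seed = 1)
  expect_true(all(!null$manifest$thermometer))
  expect_true(all(is.na(null$manifest$element_start)))

  expect_error(make_cohort(1), "at least 2")
  expect_error(make_cohort(5, families = c(a = 2)), "sum")
})

test_that("planted thermometer elements fit and never overlap", {
  co <- make_cohort(6, thermometer_fraction = 0.5, seed = 2, length = 300)
  for (id in unique(co$manifest$gene_id)) {
    mf <- co$manifest[co$manifest$gene_id == id &
                        !is.na(co$manifest$element_start), ]
    if (!nrow(mf)) next
    expect_true(all(mf$element_end <= 300L))
    o <- order(mf$element_start)
    if (nrow(mf) > 1L)
      expect_true(all(mf$element_start[o][-1] >= mf$element_end[o][-nrow(mf)]))
  }
  # the first thermometer gene has an element at its 5'UTR-intron junction
  m1 <- co$models[[1]]
  junction <- m1$features$end[m1$features$type == "five_prime_UTR"][1]
  mf1 <- co$manifest[co$manifest$gene_id == names(co$models)[1], ]
  expect_true(any(mf1$element_start <= junction &
                    junction <= mf1$element_end))
})

test_that("cohort fixtures are written as FASTA, GFF3 and manifest", {
  dir <- tempfile("cohort")
  co <- make_cohort(4, seed = 6, dir = dir, thermometer_fraction = 0.25)
  fastas <- list.files(dir, pattern = "\\.fasta$")
  expect_length(fastas, 4L)
  onDisk <- read_fasta(file.path(dir, fastas[1]))
  expect_equal(chartr("T", "U", unname(onDisk)),
               unname(co$sequences[names(onDisk)]))
  expect_true(file.exists(file.path(dir, "cohort.gff3")))
  mf <- utils::read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(sort(unique(mf$gene_id)), sort(names(co$sequences)))
  m <- read_gene_model(file.path(dir, "cohort.gff3"),
                       names(co$sequences)[2])
  expect_equal(m$length, 200L)
})

test_that("null cohorts give approximately standard-normal gene scores", {
  # split-half design: population statistics from one half of a null
  # cohort, standard scores for the held-out half (toy engine, scan-only)
  co <- make_cohort(60, seed = 13, length = 150)
  summ <- lapply(seq_along(co$sequences), function(g) {
    s <- co$sequences[[g]]
    lo <- scan_sequence(s, scan_config(40, 5, 0, 28, 1, FALSE), TOY)
    hi <- scan_sequence(s, scan_config(40, 5, 0, 42, 1, FALSE), TOY)
    gene_summary(names(co$sequences)[g], delta_ed(lo, hi))
  })
  pop <- population_stats(summ[1:30])
  scores <- vapply(summ[31:60], standard_score, numeric(1), pop = pop)
  expect_lt(abs(mean(scores)), 0.45)      # ~3 SE for n = 30
  expect_gt(sd(scores), 0.6)
  expect_lt(sd(scores), 1.5)
})

test_that("thermometer genes rank above null genes in delta-ED", {
  skip_if(!has_rnafold, "RNAfold not available")
  co <- make_cohort(24, thermometer_fraction = 0.25, seed = 11,
                    length = 300)
  summ <- lapply(seq_along(co$sequences), function(g) {
    s <- co$sequences[[g]]
    lo <- scan_sequence(s, scan_config(40, 6, 0, 28, 1, FALSE), VIENNA)
    hi <- scan_sequence(s, scan_config(40, 6, 0, 42, 1, FALSE), VIENNA)
    gene_summary(names(co$sequences)[g], delta_ed(lo, hi))
  })
  pop <- population_stats(summ)
  scores <- vapply(summ, standard_score, numeric(1), pop = pop)
  thermo <- co$manifest$thermometer[!duplicated(co$manifest$gene_id)]
  expect_gt(median(scores[thermo]),
            quantile(scores[!thermo], 0.95, names = FALSE))
})
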