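test_that("segment parsing converts 1-based inclusive files to half-open coordinates", {
  path <- write_segment_file(tibble::tibble(
    chrom = "chr17", start = 100L, end = 200L, mean_log2 = 0.30, probes = 10L
  ))
  seg <- read_cna_segments(path, "S1", "pre")
  expect_equal(seg$start, 99L)
  expect_equal(seg$end, 200L)
  expect_equal(seg$mean_log2, 0.30)
  expect_equal(seg$probe_count, 10L)
  expect_equal(seg$direction, "neutral")

  empty <- write_segment_file(tibble::tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    mean_log2 = numeric(0), probes = integer(0)
  ))
  expect_equal(nrow(read_cna_segments(empty, "S1", "pre")), 0L)
})

test_that("segment parsing reports precise format and row errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmean_log2", "chr1\t1\t2\t0.1"), f)
  expect_error(read_cna_segments(f, "S1", "pre"), "probes")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmean_log2\tprobes",
               "chr1\t1\t100\t0.1\tabc"), f2)
  expect_error(read_cna_segments(f2, "S1", "pre"), "line 2")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmean_log2\tprobes",
               "chr1\t1\t100\t0.1\t5",
               "chr1\t500\t100\t0.1\t5"), f3)
  expect_error(read_cna_segments(f3, "S1", "pre"), "line 3")

  expect_error(read_cna_segments(f3, "S1", "mid"), "pre")
})

test_that("gain/loss calling applies strict thresholds and the probe filter", {
  cases <- tibble::tribble(
    ~mean_log2, ~probe_count, ~expected,
    0.30, 10L, "gain",
    0.30, 3L, "filtered",
    0.25, 10L, "neutral",
    -0.25, 10L, "neutral",
    -0.26, 4L, "loss",
    -0.80, 2L, "filtered",
    0.00, 40L, "neutral"
  )
  segs <- classify_cna(make_segments(cases$mean_log2, cases$probe_count))
  expect_equal(segs$direction, cases$expected)
  # idempotent, and a function of (mean_log2, probe_count, thresholds) only
  expect_equal(classify_cna(segs), segs)
  relaxed <- classify_cna(make_segments(0.30, 3L), min_probes = 2L)
  expect_equal(relaxed$direction, "gain")
  expect_error(classify_cna(segs, gain_threshold = -0.1), "loss_threshold")
})

test_that("call counting tallies gains and losses per sample and condition", {
  segs <- bind <- dplyr::bind_rows(
    make_segments(rep(0.5, 5), rep(10L, 5)),
    make_segments(rep(-0.5, 2), rep(10L, 2)),
    make_segments(rep(0.0, 3), rep(10L, 3)),
    make_segments(0.9, 2L)
  )
  counts <- count_cna_calls(classify_cna(segs))
  expect_equal(counts$n_calls, 7L)
  expect_equal(counts$n_gains, 5L)
  expect_equal(counts$n_losses, 2L)

  neutral <- count_cna_calls(classify_cna(make_segments(rep(0, 4), rep(10L, 4))))
  expect_equal(neutral$n_calls, 0L)

  mixed <- dplyr::bind_rows(
    make_segments(0.5, 10L, sample_id = "A", condition = "pre"),
    make_segments(0.5, 10L, sample_id = "A", condition = "post"),
    make_segments(-0.5, 10L, sample_id = "B", condition = "pre")
  ) |> classify_cna()
  cm <- count_cna_calls(mixed)
  expect_equal(nrow(cm), 3L)
  expect_true(all(cm$n_calls == 1L))
  # invariant under row order
  shuffled <- count_cna_calls(mixed[c(3, 1, 2), ])
  expect_equal(shuffled, cm)
})

test_that("cytoband mapping follows the any-overlap rule and flags discordance", {
  cb <- tiny_cytobands()
  spanning <- classify_cna(make_segments(0.5, 10L, start = 900L, end = 1100L))
  alt <- map_cytoband_alterations(spanning, cb)
  expect_equal(sort(alt$cytoband), c("1p11", "1q11"))
  expect_true(all(alt$direction == "gain"))

  neutral <- classify_cna(make_segments(0.1, 10L, start = 10L, end = 50L))
  expect_equal(nrow(map_cytoband_alterations(neutral, cb)), 0L)

  both <- classify_cna(dplyr::bind_rows(
    make_segments(0.5, 10L, start = 10L, end = 400L),
    make_segments(-0.5, 10L, start = 500L, end = 900L)
  ))
  alt2 <- map_cytoband_alterations(both, cb)
  expect_equal(nrow(alt2), 2L)
  expect_setequal(alt2$direction, c("gain", "loss"))
  expect_true(all(alt2$discordant))

  offmap <- classify_cna(make_segments(0.5, 10L, chrom = "chrX"))
  expect_warning(res <- map_cytoband_alterations(offmap, cb), "chrX")
  expect_equal(nrow(res), 0L)
})

test_that("every supporting segment overlaps its cytoband interval", {
  cb <- tiny_cytobands()
  withr::with_seed(7, {
    for (rep in 1:20) {
      starts <- sample.int(1900L, 8L)
      segs <- classify_cna(make_segments(
        runif(8, -1, 1), sample(1:20, 8, replace = TRUE),
        start = starts, end = starts + sample.int(300L, 8L)
      ))
      alt <- map_cytoband_alterations(segs, cb)
      for (i in seq_len(nrow(alt))) {
        band <- cb[cb$name == alt$cytoband[i], ]
        sup <- alt$segments[[i]]
        expect_true(all(sup$start < band$end & band$start < sup$end))
      }
    }
  })
})

test_that("recurrence selection counts distinct samples and annotates concordance", {
  cb <- tiny_cytobands()
  segs <- classify_cna(dplyr::bind_rows(
    make_segments(0.5, 10L, sample_id = "P1", start = 10L, end = 500L),
    make_segments(0.5, 10L, sample_id = "P2", start = 20L, end = 400L),
    make_segments(0.5, 10L, sample_id = "P3", start = 1200L, end = 1600L)
  ))
  alt <- map_cytoband_alterations(segs, cb)
  rec <- recurrent_cytobands(alt, min_samples = 2L)
  expect_equal(rec$cytoband, "1p11")
  expect_equal(rec$n_samples, 2L)
  expect_true(rec$concordant)

  # min_samples = 1 returns every altered cytoband
  rec1 <- recurrent_cytobands(alt, min_samples = 1L)
  expect_setequal(rec1$cytoband, unique(alt$cytoband))

  disc <- classify_cna(dplyr::bind_rows(
    make_segments(0.5, 10L, sample_id = "P1", start = 10L, end = 500L),
    make_segments(-0.5, 10L, sample_id = "P2", start = 20L, end = 400L)
  ))
  rec2 <- recurrent_cytobands(map_cytoband_alterations(disc, cb), 2L)
  expect_equal(rec2$cytoband, "1p11")
  expect_false(rec2$concordant)

  expect_error(recurrent_cytobands(alt, min_samples = 0L), "min_samples")
})
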