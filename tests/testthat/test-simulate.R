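test_that("genome generation is deterministic and respects its parameters", {
  g1 <- simulate_genome(n_chrom = 2, cytobands_per_chrom = 3,
                        genes_per_cytoband = 4, seed = 9)
  g2 <- simulate_genome(n_chrom = 2, cytobands_per_chrom = 3,
                        genes_per_cytoband = 4, seed = 9)
  expect_equal(g1, g2)
  expect_equal(nrow(g1$cytobands), 6L)
  expect_equal(nrow(g1$genes), 24L)

  coding <- simulate_genome(noncoding_fraction = 0, seed = 1)
  expect_true(all(coding$genes$biotype == "protein_coding"))

  expect_error(simulate_genome(gene_length = 2e6, seed = 1), "packing")
  expect_error(simulate_genome(noncoding_fraction = 1, seed = 1), "noncoding_fraction")
})

test_that("planted CNA segments are recovered by the calling rules", {
  genome <- simulate_genome(seed = 3)
  cna <- simulate_cna_profiles(genome, seed = 3)
  segs <- classify_cna(cna$segments)
  called <- dplyr::filter(segs, direction %in% c("gain", "loss"))
  alt <- map_cytoband_alterations(segs, genome$cytobands)
  hit <- dplyr::inner_join(
    cna$truth, alt,
    by = c("sample_id", "condition", "cytoband", "direction")
  )
  expect_gte(nrow(hit) / nrow(cna$truth), 0.95)
  # decoy segments (<= 3 probes) never produce calls
  expect_true(all(called$probe_count > 3))

  # the shared core makes every core band recurrent across all samples
  rec <- recurrent_cytobands(alt, min_samples = 3)
  core <- cna$params$core_cytobands
  expect_true(all(core %in% rec$cytoband[rec$condition == "pre"]))
  expect_true(all(core %in% rec$cytoband[rec$condition == "post"]))
})

test_that("zero segment noise recovers every planted direction exactly", {
  genome <- simulate_genome(seed = 5)
  cna <- simulate_cna_profiles(genome, noise_sd = 0, seed = 5)
  segs <- classify_cna(cna$segments)
  alt <- map_cytoband_alterations(segs, genome$cytobands)
  hit <- dplyr::inner_join(
    cna$truth, alt,
    by = c("sample_id", "condition", "cytoband", "direction")
  )
  expect_equal(nrow(hit), nrow(cna$truth))
})

test_that("CNA profile parameters are validated before any work", {
  genome <- simulate_genome(seed = 1)
  expect_error(simulate_cna_profiles(genome, log2_effect = 0.3, noise_sd = 0.05),
               "margin|exceed")
  expect_error(simulate_cna_profiles(genome, probe_range = c(2L, 10L)),
               "probe")
})

test_that("interaction generation is deterministic and plants top-degree regulators", {
  genome <- simulate_genome(seed = 7)
  p1 <- simulate_ppi(genome$genes, seed = 7)
  p2 <- simulate_ppi(genome$genes, seed = 7)
  expect_equal(p1$edges, p2$edges)

  f <- withr::local_tempfile(fileext = ".txt")
  readr::write_delim(p1$edges, f, delim = " ", progress = FALSE)
  kept <- read_interactions(f)
  # recompute degrees from the emitted, filtered file
  el <- dplyr::distinct(kept, a = pmin(node_a, node_b), b = pmax(node_a, node_b))
  deg <- sort(table(c(el$a, el$b)), decreasing = TRUE)
  expect_true(all(p1$regulators %in% names(deg)[1:10]))

  # forcing every evidence score below threshold leaves nothing after filtering
  p0 <- simulate_ppi(genome$genes, pass_rate = 0, seed = 7)
  f0 <- withr::local_tempfile(fileext = ".txt")
  readr::write_delim(p0$edges, f0, delim = " ", progress = FALSE)
  expect_equal(nrow(read_interactions(f0)), 0L)

  expect_error(simulate_ppi(genome$genes[1:3, ], n_regulators = 5, seed = 1),
               "regulators|nodes")
})

test_that("annotation generation plants a leaf term that enriches first", {
  genome <- simulate_genome(seed = 13)
  a1 <- simulate_annotations(genome$genes, seed = 13)
  a2 <- simulate_annotations(genome$genes, seed = 13)
  expect_equal(a1$annotations, a2$annotations)
  expect_true(all(a1$depths <= 4))

  prop <- propagate_annotations(a1$annotations, a1$ontology)
  res <- enrich_terms(a1$planted_genes, prop, ontology = a1$ontology)
  expect_equal(res$term_id[1], a1$planted_term)
  expect_lt(res$q[1], 0.05)

  # near-zero background: the planted p approaches the closed form with
  # K = |planted set|
  tiny <- simulate_annotations(genome$genes, background_rate = 1e-9, seed = 13)
  prop2 <- propagate_annotations(tiny$annotations, tiny$ontology)
  res2 <- enrich_terms(tiny$planted_genes, prop2, ontology = tiny$ontology)
  r <- res2[res2$term_id == tiny$planted_term, ]
  N <- r$N
  K <- length(tiny$planted_genes)
  n <- length(tiny$planted_genes)
  expect_equal(r$K, K)
  expect_equal(r$p, oracle_hyper_p(N, K, n, K), tolerance = 1e-12)

  expect_error(simulate_annotations(genome$genes, background_rate = 0, seed = 1),
               "background_rate")
})

test_that("a small study drives the whole pipeline to non-degenerate results", {
  dir <- withr::local_tempdir()
  study <- simulate_study("small", seed = 11, dir = dir)
  res <- run_pipeline(dir)
  sizes <- purrr::map_int(res$hbs, ~ length(hbs_members(.x)))
  expect_length(sizes, 6L)
  expect_true(all(sizes > 0L))
  expect_true(all(res$call_counts$n_calls > 0L))

  out1 <- file.path(dir, "out1")
  out2 <- file.path(dir, "out2")
  write_pipeline(res, out1)
  write_pipeline(run_pipeline(dir), out2)
  f1 <- list.files(out1)
  expect_true(length(f1) > 5)
  expect_equal(f1, list.files(out2))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(out1, f))),
                 unname(tools::md5sum(file.path(out2, f))),
                 label = f)
  }
})

test_that("study truth is serialized and regulators sit inside core cytobands", {
  dir <- withr::local_tempdir()
  study <- simulate_study("small", seed = 19, dir = dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 19L)
  expect_equal(truth$rng$kind, "Mersenne-Twister")
  expect_setequal(unlist(truth$planted_regulators), study$truth$planted_regulators)
  core_iv <- study$genome$cytobands[
    study$genome$cytobands$name %in% study$truth$core_cytobands, ]
  regs <- study$genome$genes[
    study$genome$genes$symbol %in% study$truth$planted_regulators, ]
  for (i in seq_len(nrow(regs))) {
    expect_true(any(regs$chrom[i] == core_iv$chrom &
                      regs$start[i] < core_iv$end &
                      core_iv$start < regs$end[i]))
  }
})
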