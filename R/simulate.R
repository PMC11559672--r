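#' Simulate a genome annotation (cytobands and genes)
#'
#' Builds a toy genome: each chromosome is tiled by equally sized,
#' non-overlapping cytobands (named in the usual arm/band style, e.g.
#' `1p11`, `1q12`); genes of fixed length are placed uniformly at random
#' inside their cytoband, and a fraction of them is labelled non-coding
#' (`miRNA`) to exercise the protein-coding filter downstream. Deterministic
#' per seed.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param cytobands_per_chrom Cytobands per chromosome (>= 1).
#' @param genes_per_cytoband Genes per cytoband (>= 1).
#' @param noncoding_fraction Fraction of genes labelled non-coding, in [0, 1).
#' @param cytoband_length Cytoband length in bp (default 1e6).
#' @param gene_length Gene length in bp (default 2e4); must fit inside a
#'   cytoband.
#' @param seed Integer seed.
#' @return List with tibbles `cytobands` (`chrom`, `start`, `end`, `name`) and
#'   `genes` (`chrom`, `start`, `end`, `symbol`, `biotype`), plus `params`.
#' @export
simulate_genome <- function(n_chrom = 2L, cytobands_per_chrom = 8L,
                            genes_per_cytoband = 15L, noncoding_fraction = 0.1,
                            cytoband_length = 1e6, gene_length = 2e4,
                            seed = 1L) {
  if (n_chrom < 1 || cytobands_per_chrom < 1 || genes_per_cytoband < 1) {
    abort("All counts must be >= 1.")
  }
  if (noncoding_fraction < 0 || noncoding_fraction >= 1) {
    abort("`noncoding_fraction` must lie in [0, 1).")
  }
  if (gene_length > cytoband_length) {
    abort("Impossible packing: `gene_length` exceeds `cytoband_length`.")
  }
  with_seed(seed, {
    L <- as.integer(cytoband_length)
    n_p <- floor(cytobands_per_chrom / 2)
    bands <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
      idx <- seq_len(cytobands_per_chrom)
      arm <- ifelse(idx <= n_p, "p", "q")
      within_arm <- ifelse(idx <= n_p, idx, idx - n_p)
      tibble(
        chrom = sprintf("chr%d", ci),
        start = (idx - 1L) * L,
        end = idx * L,
        name = sprintf("%d%s%d", ci, arm, 10L + within_arm)
      )
    })
    gl <- as.integer(gene_length)
    genes <- purrr::map_dfr(seq_len(nrow(bands)), function(bi) {
      b <- bands[bi, ]
      starts <- sort(b$start + sample.int(L - gl + 1L, genes_per_cytoband,
                                          replace = TRUE) - 1L)
      tibble(chrom = b$chrom, start = starts, end = starts + gl)
    })
    genes$symbol <- sprintf("GENE%04d", seq_len(nrow(genes)))
    genes$biotype <- ifelse(runif(nrow(genes)) < noncoding_fraction,
                            "miRNA", "protein_coding")
    list(
      cytobands = bands,
      genes = genes,
      params = list(n_chrom = n_chrom, cytobands_per_chrom = cytobands_per_chrom,
                    genes_per_cytoband = genes_per_cytoband,
                    noncoding_fraction = noncoding_fraction,
                    cytoband_length = L, gene_length = gl, seed = seed)
    )
  })
}

#' Simulate paired pre/post-chemotherapy CNA profiles
#'
#' For each simulated patient and condition, a set of planted cytobands
#' receives aberrant segments with mean log2 ratio drawn from
#' `Normal(+/- log2_effect, noise_sd)` and probe counts in `probe_range`; a
#' core of `core_cytobands` is gained in every sample and condition (a
#' recurrent backbone, in the spirit of the recurrent 17q gain of
#' neuroblastoma), so recurrence logic always has material to work on.
#' Background cytobands receive neutral segments (`Normal(0, noise_sd)`), and
#' each sample/condition also gets one high-amplitude decoy segment with at
#' most 3 probes, which the probe filter must remove. The planting margin is
#' parameter-checked up front: `log2_effect` must exceed
#' `gain_threshold + 3 * noise_sd`, so planted calls survive thresholding with
#' high probability by construction.
#'
#' @param genome Output of [simulate_genome()].
#' @param n_samples Number of patients (default 3, each with `pre` and `post`
#'   profiles).
#' @param n_planted_per_condition Planted altered cytobands per
#'   sample/condition (core included; default 6).
#' @param core_cytobands Cytoband names gained in all samples/conditions;
#'   defaults to `n_core` randomly chosen bands.
#' @param n_core Size of the random core when `core_cytobands` is `NULL`.
#' @param log2_effect Absolute planted effect on the log2 scale (default 0.5).
#' @param noise_sd Gaussian noise SD on segment means (default 0.05).
#' @param probe_range Integer range of probe counts for planted/background
#'   segments; the minimum must exceed 3 so planted calls pass the probe
#'   filter.
#' @param gain_threshold Calling threshold the margin check is made against
#'   (default 0.25).
#' @param seed Integer seed.
#' @return List with `segments` (long unclassified segment tibble, internal
#'   coordinates), `truth` (tibble `sample_id`, `condition`, `cytoband`,
#'   `direction` of every planted alteration) and `params`.
#' @export
simulate_cna_profiles <- function(genome, n_samples = 3L,
                                  n_planted_per_condition = 6L,
                                  core_cytobands = NULL, n_core = 2L,
                                  log2_effect = 0.5, noise_sd = 0.05,
                                  probe_range = c(5L, 40L),
                                  gain_threshold = 0.25, seed = 1L) {
  if (log2_effect <= gain_threshold + 3 * noise_sd) {
    abort("`log2_effect` must exceed gain_threshold + 3 * noise_sd so planted calls survive thresholding.")
  }
  if (probe_range[1] <= 3L) {
    abort("`probe_range` minimum must exceed 3 so planted segments pass the probe filter.")
  }
  bands <- genome$cytobands
  with_seed(seed, {
    if (is.null(core_cytobands)) {
      core_cytobands <- sort(sample(bands$name, n_core))
    }
    missing <- setdiff(core_cytobands, bands$name)
    if (length(missing) > 0L) {
      abort(sprintf("Unknown core cytoband(s): %s", paste(missing, collapse = ", ")))
    }
    if (n_planted_per_condition < length(core_cytobands)) {
      abort("`n_planted_per_condition` must be >= the number of core cytobands.")
    }
    if (n_planted_per_condition > nrow(bands)) {
      abort("More planted cytobands requested than cytobands in the genome.")
    }
    samples <- sprintf("P%d", seq_len(n_samples))
    probes_pool <- seq.int(probe_range[1], probe_range[2])
    seg_rows <- list()
    truth_rows <- list()
    for (s in samples) {
      for (cond in c("pre", "post")) {
        extra <- sample(setdiff(bands$name, core_cytobands),
                        n_planted_per_condition - length(core_cytobands))
        planted <- tibble(
          cytoband = c(core_cytobands, extra),
          direction = c(rep("gain", length(core_cytobands)),
                        sample(c("gain", "loss"), length(extra), replace = TRUE))
        )
        b <- bands[match(planted$cytoband, bands$name), ]
        mu <- ifelse(planted$direction == "gain", log2_effect, -log2_effect)
        planted_seg <- tibble(
          sample_id = s, condition = cond, chrom = b$chrom,
          start = b$start, end = b$end,
          mean_log2 = rnorm(nrow(b), mu, noise_sd),
          probe_count = sample(probes_pool, nrow(b), replace = TRUE),
          direction = "neutral"
        )
        bg_bands <- setdiff(bands$name, planted$cytoband)
        bg_pick <- bg_bands[runif(length(bg_bands)) < 0.5]
        bb <- bands[match(bg_pick, bands$name), ]
        quarter <- as.integer((bb$end - bb$start) / 4)
        bg_seg <- tibble(
          sample_id = s, condition = cond, chrom = bb$chrom,
          start = bb$start + quarter, end = bb$end - quarter,
          mean_log2 = rnorm(nrow(bb), 0, noise_sd),
          probe_count = sample(probes_pool, nrow(bb), replace = TRUE),
          direction = "neutral"
        )
        decoy_band <- bands[match(sample(bg_bands, 1L), bands$name), ]
        decoy <- tibble(
          sample_id = s, condition = cond, chrom = decoy_band$chrom,
          start = decoy_band$start, end = decoy_band$end,
          mean_log2 = sample(c(-1, 1), 1L) * log2_effect,
          probe_count = sample(1:3, 1L),
          direction = "neutral"
        )
        seg_rows[[paste(s, cond)]] <- bind_rows(planted_seg, bg_seg, decoy)
        truth_rows[[paste(s, cond)]] <- mutate(planted, sample_id = s,
                                               condition = cond, .before = 1)
      }
    }
    list(
      segments = bind_rows(seg_rows),
      truth = bind_rows(truth_rows),
      params = list(n_samples = n_samples,
                    n_planted_per_condition = n_planted_per_condition,
                    core_cytobands = core_cytobands,
                    log2_effect = log2_effect, noise_sd = noise_sd,
                    probe_range = probe_range, seed = seed)
    )
  })
}

#' Simulate a multi-channel protein interaction table with planted regulators
#'
#' Grows a network over the protein-coding genes by sequential attachment:
#' planted regulators join first (wired in a ring) and receive a
#' degree-proportional attachment weight `attachment_bias * (degree + 1)`,
#' while background nodes attach with uniform weight 1. The result is a
#' heavy-tailed degree distribution whose extreme tail is carried by the
#' regulators — they end up with degrees an order of magnitude above the mean,
#' while background degrees concentrate tightly below it, so mean-threshold
#' hub detection recovers the planted set by construction. Each edge gets
#' integer channel scores on the STRING 0-1000 scale: all channels draw low
#' baseline scores, text-mining channels draw freely over the whole scale
#' (they must never rescue an edge under the default channel selection), and
#' with probability `pass_rate` one randomly chosen evidence channel is pushed
#' above 400 so the edge survives the default filter. A few reciprocal
#' duplicate rows are appended to exercise edge simplification.
#'
#' @param genes Gene annotation tibble (only `protein_coding` rows become
#'   nodes).
#' @param n_edges Total number of generated edges (default 1200).
#' @param regulators Symbols to plant as regulators; defaults to
#'   `n_regulators` random coding genes.
#' @param n_regulators Number of planted regulators (default 5).
#' @param attachment_bias Attachment weight multiplier for regulators
#'   (default 5).
#' @param pass_rate Probability that an edge is given at least one evidence
#'   channel score >= 400 (default 0.9).
#' @param seed Integer seed.
#' @return List with `edges` (tibble `protein1`, `protein2`, the eleven
#'   channel columns, `combined_score`), `regulators`, `params`.
#' @export
simulate_ppi <- function(genes, n_edges = 1200L, regulators = NULL,
                         n_regulators = 5L, attachment_bias = 5,
                         pass_rate = 0.9, seed = 1L) {
  nodes_all <- genes$symbol[genes$biotype == "protein_coding"]
  n_nodes <- length(nodes_all)
  if (n_nodes < (if (is.null(regulators)) n_regulators else length(regulators))) {
    abort("Fewer nodes than planted regulators.")
  }
  if (n_edges < n_nodes - 1L) {
    abort("`n_edges` must be at least n_nodes - 1 for a connectable graph.")
  }
  with_seed(seed, {
    if (is.null(regulators)) {
      regulators <- sort(sample(nodes_all, n_regulators))
    }
    if (!all(regulators %in% nodes_all)) {
      abort("All planted regulators must be protein-coding genes.")
    }
    n_reg <- length(regulators)
    others <- sample(setdiff(nodes_all, regulators))
    order_nodes <- c(regulators, others)
    is_reg <- c(rep(TRUE, n_reg), rep(FALSE, length(others)))
    deg <- integer(n_nodes)
    ea <- integer(n_edges)
    eb <- integer(n_edges)
    ne <- 0L
    add_edge <- function(a, b) {
      ne <<- ne + 1L
      ea[ne] <<- a
      eb[ne] <<- b
      deg[a] <<- deg[a] + 1L
      deg[b] <<- deg[b] + 1L
    }
    # seed ring among the regulators (or first two nodes)
    seed_n <- max(2L, n_reg)
    for (i in seq_len(seed_n)) add_edge(i, if (i == seed_n) 1L else i + 1L)
    n_rem <- n_nodes - seed_n
    budget <- n_edges - ne
    m_base <- budget %/% n_rem
    extra <- budget - m_base * n_rem
    for (j in seq_len(n_rem)) {
      v <- seed_n + j
      m <- m_base + as.integer(j <= extra)
      m <- min(m, v - 1L)
      w <- ifelse(is_reg[seq_len(v - 1L)],
                  attachment_bias * (deg[seq_len(v - 1L)] + 1), 1)
      targets <- sample.int(v - 1L, m, prob = w)
      for (t in targets) add_edge(v, t)
    }
    ea <- ea[seq_len(ne)]
    eb <- eb[seq_len(ne)]
    channels <- all_interaction_channels()
    selected <- string_evidence_channels()
    smat <- matrix(as.integer(round(runif(ne * length(channels), 0, 350))),
                   nrow = ne, dimnames = list(NULL, channels))
    smat[, "textmining"] <- as.integer(round(runif(ne, 0, 1000)))
    smat[, "textmining_transferred"] <- as.integer(round(runif(ne, 0, 1000)))
    passes <- runif(ne) < pass_rate
    boost_ch <- sample(selected, ne, replace = TRUE)
    boost_val <- as.integer(round(runif(ne, 450, 990)))
    for (i in which(passes)) smat[i, boost_ch[i]] <- boost_val[i]
    edges <- tibble(protein1 = order_nodes[ea], protein2 = order_nodes[eb])
    for (ch in channels) edges[[ch]] <- smat[, ch]
    edges$combined_score <- as.integer(apply(smat, 1, max))
    # reciprocal duplicates: readers must merge them into single edges
    n_dup <- min(5L, nrow(edges))
    dup <- edges[seq_len(n_dup), ]
    tmp <- dup$protein1
    dup$protein1 <- dup$protein2
    dup$protein2 <- tmp
    edges <- bind_rows(edges, dup)
    list(
      edges = edges,
      regulators = sort(regulators),
      params = list(n_edges = n_edges, n_regulators = n_reg,
                    attachment_bias = attachment_bias, pass_rate = pass_rate,
                    seed = seed)
    )
  })
}

#' Simulate an ontology and gene annotations with one planted enriched term
#'
#' Builds a random tree-shaped DAG of at most `dag_depth` levels below a
#' single root. The root is named "biological process" and its first child
#' "regulation of biological processes" — deliberately generic terms that the
#' default blocklist of [filter_generic_terms()] removes. One planted term (at
#' depth >= 2) is annotated to every gene of `planted_genes`; all non-root
#' terms additionally annotate each coding gene independently with probability
#' `background_rate`. Deterministic per seed.
#'
#' @param genes Gene annotation tibble (coding genes are annotated).
#' @param n_terms Number of ontology terms (default 50).
#' @param dag_depth Maximum term depth below the root (default 4).
#' @param planted_term Term id to plant; defaults to a random term at
#'   depth >= 2.
#' @param planted_genes Genes annotated to the planted term; defaults to
#'   `n_planted_genes` random coding genes.
#' @param n_planted_genes Size of the default planted gene set (default 25).
#' @param background_rate Per-(gene, term) background annotation probability,
#'   in (0, 1).
#' @param seed Integer seed.
#' @return List with `ontology` (an `ontology` object), `annotations` (direct,
#'   unpropagated tibble `gene`, `term_id`), `term_names` tibble,
#'   `planted_term`, `planted_genes`, `depths`, `params`.
#' @export
simulate_annotations <- function(genes, n_terms = 50L, dag_depth = 4L,
                                 planted_term = NULL, planted_genes = NULL,
                                 n_planted_genes = 25L, background_rate = 0.05,
                                 seed = 1L) {
  if (background_rate <= 0 || background_rate >= 1) {
    abort("`background_rate` must lie in (0, 1).")
  }
  if (n_terms < 3L) abort("`n_terms` must be >= 3.")
  coding <- genes$symbol[genes$biotype == "protein_coding"]
  with_seed(seed, {
    if (is.null(planted_genes)) {
      planted_genes <- sort(sample(coding, n_planted_genes))
    }
    if (length(planted_genes) == 0L) abort("`planted_genes` must be non-empty.")
    ids <- sprintf("SYN:%04d", seq_len(n_terms))
    depth <- integer(n_terms)
    parent <- rep(NA_character_, n_terms)
    parent[2] <- ids[1]
    depth[2] <- 1L
    for (i in seq(3L, n_terms)) {
      eligible <- which(depth[seq_len(i - 1L)] < dag_depth)
      p <- eligible[sample.int(length(eligible), 1L)]
      parent[i] <- ids[p]
      depth[i] <- depth[p] + 1L
    }
    if (is.null(planted_term)) {
      # plant in a leaf: annotations propagate upward, so only a childless
      # term keeps a specific (small-K) annotation set after propagation
      is_leaf <- !(ids %in% parent)
      cand <- which(depth >= 2L & is_leaf)
      if (length(cand) == 0L) abort("`dag_depth` leaves no leaf term at depth >= 2 to plant.")
      planted_term <- ids[cand[sample.int(length(cand), 1L)]]
    }
    if (!planted_term %in% ids) {
      abort(sprintf("Planted term '%s' is not among the generated terms.", planted_term))
    }
    nm <- c("biological process", "regulation of biological processes",
            sprintf("synthetic process %02d", seq(3L, n_terms)))
    names_map <- setNames(nm, ids)
    parents_list <- split(parent[-1], ids[-1])
    ont <- new_ontology(parents_list, names_map)
    bg_terms <- ids[-1]
    draws <- matrix(runif(length(coding) * length(bg_terms)),
                    nrow = length(coding))
    hit <- which(draws < background_rate, arr.ind = TRUE)
    background <- tibble(gene = coding[hit[, 1]], term_id = bg_terms[hit[, 2]])
    annotations <- bind_rows(
      tibble(gene = planted_genes, term_id = planted_term),
      background
    ) |>
      distinct(.data$gene, .data$term_id) |>
      arrange(.data$gene, .data$term_id)
    list(
      ontology = ont,
      annotations = annotations,
      term_names = tibble(term_id = ids, name = nm),
      planted_term = planted_term,
      planted_genes = planted_genes,
      depths = setNames(depth, ids),
      params = list(n_terms = n_terms, dag_depth = dag_depth,
                    background_rate = background_rate, seed = seed)
    )
  })
}

study_profiles <- function() {
  list(
    small = list(n_chrom = 2L, cytobands_per_chrom = 8L,
                 genes_per_cytoband = 15L, noncoding_fraction = 0.1,
                 n_samples = 3L, n_planted_per_condition = 6L, n_core = 2L,
                 n_edges = 1200L, n_regulators = 5L, attachment_bias = 5,
                 pass_rate = 0.9, n_terms = 50L, dag_depth = 4L,
                 n_planted_genes = 25L, background_rate = 0.05),
    default = list(n_chrom = 4L, cytobands_per_chrom = 10L,
                   genes_per_cytoband = 25L, noncoding_fraction = 0.1,
                   n_samples = 3L, n_planted_per_condition = 8L, n_core = 3L,
                   n_edges = 6000L, n_regulators = 8L, attachment_bias = 5,
                   pass_rate = 0.9, n_terms = 120L, dag_depth = 5L,
                   n_planted_genes = 40L, background_rate = 0.05)
  )
}

#' Simulate a complete study with known ground truth
#'
#' Orchestrates all generators into one coherent study: a genome; paired
#' pre/post CNA profiles for each patient whose core gained cytobands are
#' shared by every sample and condition; a multi-channel interaction table
#' whose planted regulators live inside those core cytobands (so every induced
#' network contains them); and an ontology whose planted enriched term
#' annotates the regulators plus additional random genes. The ground truth —
#' planted alterations, regulators, enriched term and gene set, generator
#' parameters and the pinned RNG specification — is carried in `$truth` and
#' serialized to `truth.json` when `dir` is given.
#'
#' @param profile `"small"` (runs the full pipeline in seconds) or
#'   `"default"` (a larger study).
#' @param seed Integer seed; all child generator seeds derive from it.
#' @param dir Optional output directory; when given, every input file plus
#'   `truth.json` is written there via [write_study()].
#' @return A `synthetic_study` list: `genome`, `cna`, `ppi`, `annotations`,
#'   `truth`, `profile`, `seed`.
#' @export
simulate_study <- function(profile = c("small", "default"), seed = 1L,
                           dir = NULL) {
  profile <- match.arg(profile)
  p <- study_profiles()[[profile]]
  seeds <- derive_seeds(seed, 5L)
  genome <- simulate_genome(
    n_chrom = p$n_chrom, cytobands_per_chrom = p$cytobands_per_chrom,
    genes_per_cytoband = p$genes_per_cytoband,
    noncoding_fraction = p$noncoding_fraction, seed = seeds[1]
  )
  picks <- with_seed(seeds[2], {
    core <- sort(sample(genome$cytobands$name, p$n_core))
    core_iv <- genome$cytobands[genome$cytobands$name %in% core, ]
    in_core <- purrr::map_lgl(seq_len(nrow(genome$genes)), function(i) {
      g <- genome$genes[i, ]
      any(g$chrom == core_iv$chrom & g$start < core_iv$end & core_iv$start < g$end)
    })
    core_coding <- genome$genes$symbol[in_core &
                                         genome$genes$biotype == "protein_coding"]
    if (length(core_coding) < p$n_regulators) {
      abort("Core cytobands hold too few coding genes to plant the regulators.")
    }
    regulators <- sort(sample(core_coding, p$n_regulators))
    other_coding <- setdiff(
      genome$genes$symbol[genome$genes$biotype == "protein_coding"], regulators
    )
    planted_genes <- sort(c(regulators,
                            sample(other_coding,
                                   p$n_planted_genes - p$n_regulators)))
    list(core = core, regulators = regulators, planted_genes = planted_genes)
  })
  cna <- simulate_cna_profiles(
    genome, n_samples = p$n_samples,
    n_planted_per_condition = p$n_planted_per_condition,
    core_cytobands = picks$core, seed = seeds[3]
  )
  ppi <- simulate_ppi(
    genome$genes, n_edges = p$n_edges, regulators = picks$regulators,
    attachment_bias = p$attachment_bias, pass_rate = p$pass_rate,
    seed = seeds[4]
  )
  ann <- simulate_annotations(
    genome$genes, n_terms = p$n_terms, dag_depth = p$dag_depth,
    planted_genes = picks$planted_genes,
    background_rate = p$background_rate, seed = seeds[5]
  )
  truth <- list(
    seed = seed,
    rng = rng_spec(),
    profile = profile,
    core_cytobands = picks$core,
    planted_alterations = cna$truth,
    planted_regulators = picks$regulators,
    planted_term = ann$planted_term,
    planted_genes = picks$planted_genes,
    params = p
  )
  study <- structure(
    list(genome = genome, cna = cna, ppi = ppi, annotations = ann,
         truth = truth, profile = profile, seed = seed),
    class = "synthetic_study"
  )
  if (!is.null(dir)) {
    write_study(study, dir)
    return(invisible(study))
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> profile '%s', seed %d\n", x$profile, x$seed))
  cat(sprintf("  %d genes, %d cytobands, %d samples x pre/post, %d edges, %d terms\n",
              nrow(x$genome$genes), nrow(x$genome$cytobands),
              x$truth$params$n_samples, x$truth$params$n_edges,
              x$truth$params$n_terms))
  cat(sprintf("  planted: %d regulators, term %s, %d alterations\n",
              length(x$truth$planted_regulators), x$truth$planted_term,
              nrow(x$truth$planted_alterations)))
  invisible(x)
}

fmt_tsv <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
}

#' Write a synthetic study to a directory of pipeline input files
#'
#' Emits every file dialect the pipeline reads: `cytobands.tsv` and
#' `genes.tsv` (BED-like, 0-based half-open), one
#' `segments_<sample>_<condition>.tsv` per profile (1-based inclusive
#' coordinates, mean log2 rounded to 4 decimals at the file boundary),
#' `interactions.tsv` (space-separated STRING protein-links-full layout),
#' `ontology_dag.tsv`, `term_names.tsv`, `annotations.tsv`, and `truth.json`.
#' Output is byte-stable for a fixed study.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_tsv(study$genome$cytobands, file.path(dir, "cytobands.tsv"))
  fmt_tsv(study$genome$genes, file.path(dir, "genes.tsv"))
  segs <- study$cna$segments
  for (s in unique(segs$sample_id)) {
    for (cond in c("pre", "post")) {
      part <- filter(segs, .data$sample_id == s, .data$condition == cond)
      out <- tibble(
        chrom = part$chrom,
        start = part$start + 1L,
        end = part$end,
        mean_log2 = sprintf("%.4f", part$mean_log2),
        probes = part$probe_count
      )
      fmt_tsv(out, file.path(dir, sprintf("segments_%s_%s.tsv", s, cond)))
    }
  }
  readr::write_delim(study$ppi$edges, file.path(dir, "interactions.tsv"),
                     delim = " ", progress = FALSE)
  ont <- study$annotations$ontology
  dag <- tibble(
    child_id = rep(names(ont$parents), lengths(ont$parents)),
    parent_id = unlist(ont$parents, use.names = FALSE)
  ) |>
    arrange(.data$child_id, .data$parent_id)
  fmt_tsv(dag, file.path(dir, "ontology_dag.tsv"))
  fmt_tsv(study$annotations$term_names, file.path(dir, "term_names.tsv"))
  fmt_tsv(study$annotations$annotations, file.path(dir, "annotations.tsv"))
  truth <- study$truth
  truth$planted_alterations <- as.data.frame(truth$planted_alterations)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
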