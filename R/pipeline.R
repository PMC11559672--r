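#' Run the full CNA-to-network-to-enrichment pipeline on a study directory
#'
#' Reads a directory in the layout produced by [write_study()] (or assembled
#' by hand from real exports) and executes every stage: segment parsing and
#' gain/loss calling; call counting; cytoband mapping and recurrence;
#' per-sample/condition protein-coding gene sets; evidence-filtered network
#' induction; centralities and HBS classification; cross-sample and
#' cross-condition HBS intersection; and term over-representation per
#' condition (study set = union of the condition's HBS across samples,
#' restricted to annotated genes), with generic terms removed.
#'
#' @param dir Input directory. Expected files: `cytobands.tsv`, `genes.tsv`,
#'   `segments_<sample>_<pre|post>.tsv`, `interactions.tsv`,
#'   `ontology_dag.tsv`, `term_names.tsv`, `annotations.tsv`.
#' @param gain_threshold,loss_threshold,min_probes CNA calling parameters, see
#'   [classify_cna()].
#' @param min_samples Recurrence threshold, see [recurrent_cytobands()].
#' @param channels,min_score,combine Interaction filter, see
#'   [read_interactions()].
#' @param protein_coding_only Restrict gene sets to coding genes (default
#'   `TRUE`).
#' @param alpha Enrichment significance level (default 0.05).
#' @param blocklist Generic-term blocklist, see [filter_generic_terms()].
#' @return A `cnanet_pipeline` list: `call_counts`, `alterations`,
#'   `recurrent`, `gene_sets`, `networks`, `hbs` (per sample/condition),
#'   `hbs_table`, `intersections` (per condition), `overlap`, `enrichment`
#'   (per condition), `params`.
#' @export
run_pipeline <- function(dir,
                         gain_threshold = 0.25, loss_threshold = -0.25,
                         min_probes = 3L, min_samples = 2L,
                         channels = string_evidence_channels(),
                         min_score = 400L, combine = c("any", "all"),
                         protein_coding_only = TRUE,
                         alpha = 0.05,
                         blocklist = generic_term_blocklist()) {
  combine <- match.arg(combine)
  cytobands <- read_cytobands(file.path(dir, "cytobands.tsv"))
  genes <- read_gene_annotation(file.path(dir, "genes.tsv"))
  seg_files <- sort(list.files(dir, pattern = "^segments_.+_(pre|post)\\.tsv$"))
  if (length(seg_files) == 0L) abort(sprintf("No segment files found in %s", dir))
  meta <- stringr::str_match(seg_files, "^segments_(.+)_(pre|post)\\.tsv$")
  segments <- purrr::pmap_dfr(
    list(seg_files, meta[, 2], meta[, 3]),
    function(f, s, cond) read_cna_segments(file.path(dir, f), s, cond)
  ) |>
    classify_cna(gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold, min_probes = min_probes)
  call_counts <- count_cna_calls(segments)
  alterations <- map_cytoband_alterations(segments, cytobands)
  recurrent <- recurrent_cytobands(alterations, min_samples = min_samples)
  interactions <- read_interactions(file.path(dir, "interactions.tsv"),
                                    channels = channels, min_score = min_score,
                                    combine = combine)
  combos <- distinct(alterations, .data$sample_id, .data$condition) |>
    arrange(.data$sample_id, .data$condition)
  keys <- sprintf("%s_%s", combos$sample_id, combos$condition)
  gene_sets <- purrr::map2(combos$sample_id, combos$condition, function(s, cond) {
    build_gene_set(
      filter(alterations, .data$sample_id == s, .data$condition == cond),
      genes, cytobands, protein_coding_only = protein_coding_only
    )
  })
  names(gene_sets) <- keys
  networks <- purrr::map(gene_sets, ~ induce_ppi_network(.x, interactions))
  hbs <- purrr::map(networks, ~ classify_hbs(node_centralities(.x)))
  hbs_table <- hbs_set_table(hbs)
  intersections <- list()
  for (cond in intersect(c("pre", "post"), unique(hbs_table$condition))) {
    if (n_distinct(hbs_table$sample_id[hbs_table$condition == cond]) >= 2L) {
      intersections[[cond]] <- intersect_hbs(hbs_table, condition = cond)
    }
  }
  overlap <- NULL
  if (setequal(unique(hbs_table$condition), c("pre", "post"))) {
    pre_ids <- unique(hbs_table$sample_id[hbs_table$condition == "pre"])
    post_ids <- unique(hbs_table$sample_id[hbs_table$condition == "post"])
    if (setequal(pre_ids, post_ids)) overlap <- cross_condition_overlap(hbs_table)
  }
  enrichment <- list()
  ann_path <- file.path(dir, "annotations.tsv")
  dag_path <- file.path(dir, "ontology_dag.tsv")
  if (file.exists(ann_path) && file.exists(dag_path)) {
    names_path <- file.path(dir, "term_names.tsv")
    ontology <- read_ontology(dag_path,
                              if (file.exists(names_path)) names_path else NULL)
    annotations <- propagate_annotations(read_term_annotations(ann_path), ontology)
    universe <- unique(annotations$gene)
    for (cond in names(intersections)) {
      study <- intersect(
        unique(hbs_table$node[hbs_table$condition == cond]), universe
      )
      if (length(study) > 0L) {
        enrichment[[cond]] <- enrich_terms(study, annotations,
                                           universe = universe,
                                           ontology = ontology,
                                           alpha = alpha) |>
          filter_generic_terms(blocklist = blocklist)
      }
    }
  }
  structure(
    list(call_counts = call_counts, alterations = alterations,
         recurrent = recurrent, gene_sets = gene_sets, networks = networks,
         hbs = hbs, hbs_table = hbs_table, intersections = intersections,
         overlap = overlap, enrichment = enrichment,
         params = list(gain_threshold = gain_threshold,
                       loss_threshold = loss_threshold,
                       min_probes = min_probes, min_samples = min_samples,
                       channels = channels, min_score = min_score,
                       combine = combine, alpha = alpha)),
    class = "cnanet_pipeline"
  )
}

#' @export
print.cnanet_pipeline <- function(x, ...) {
  cat("<cnanet_pipeline>\n")
  cat("CNA calls per sample/condition:\n")
  print(x$call_counts)
  cat("Networks and HBS:\n")
  print(purrr::map_dfr(x$hbs, glance))
  for (cond in names(x$intersections)) {
    cat(sprintf("%d-way common HBS (%s): %d\n",
                nrow(x$intersections[[cond]]$sizes), cond,
                x$intersections[[cond]]$kway_n))
  }
  if (!is.null(x$overlap)) {
    cat(sprintf("Global pre/post HBS intersection: %d\n", x$overlap$global_n))
  }
  for (cond in names(x$enrichment)) {
    g <- glance(x$enrichment[[cond]])
    cat(sprintf("Enrichment (%s): %d terms tested, %d significant (q < %.2f)\n",
                cond, g$n_terms_tested, g$n_significant, g$alpha))
  }
  invisible(x)
}

# fixed-format numeric columns so that pipeline output files are byte-stable
fmt_num <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)

#' Write pipeline results to a directory of text reports
#'
#' Emits deterministic TSV/JSON reports: per-sample call counts, the cytoband
#' alteration and recurrence tables, per-network edge lists and
#' centrality/HBS tables (`node degree betweenness eigenvector is_hub
#' is_bottleneck is_switch is_hbs`), a machine-readable JSON of all HBS
#' intersections and the pre/post overlap, and per-condition enrichment
#' tables. Running the pipeline twice on the same inputs yields byte-identical
#' reports.
#'
#' @param result A `cnanet_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_tsv(result$call_counts, file.path(dir, "call_counts.tsv"))
  fmt_tsv(select(result$alterations, -"segments"),
          file.path(dir, "cytoband_alterations.tsv"))
  fmt_tsv(select(result$recurrent, -"by_sample"),
          file.path(dir, "recurrent_cytobands.tsv"))
  for (key in names(result$hbs)) {
    h <- result$hbs[[key]]
    out <- tibble(
      node = h$node, degree = h$degree,
      betweenness = fmt_num(h$betweenness, 6),
      eigenvector = fmt_num(h$eigenvector, 8),
      is_hub = h$is_hub, is_bottleneck = h$is_bottleneck,
      is_switch = h$is_switch, is_hbs = h$is_hbs
    )
    fmt_tsv(out, file.path(dir, sprintf("hbs_%s.tsv", key)))
    fmt_tsv(tidy(result$networks[[key]]),
            file.path(dir, sprintf("network_%s.tsv", key)))
  }
  summary <- list(
    intersections = purrr::map(result$intersections, function(ix) {
      list(condition = ix$condition,
           sizes = as.data.frame(ix$sizes),
           pairwise = as.data.frame(select(ix$pairwise, -"members")),
           pairwise_members = purrr::map(
             seq_len(nrow(ix$pairwise)), ~ ix$pairwise$members[[.x]]
           ),
           kway_n = ix$kway_n, kway_members = ix$kway_members)
    }),
    overlap = if (!is.null(result$overlap)) {
      list(per_sample = as.data.frame(select(result$overlap$per_sample, -"members")),
           per_sample_members = result$overlap$per_sample$members,
           global_n = result$overlap$global_n,
           global_members = result$overlap$global_members)
    }
  )
  jsonlite::write_json(summary, file.path(dir, "hbs_intersections.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (cond in names(result$enrichment)) {
    e <- result$enrichment[[cond]]
    out <- tibble(
      term_id = e$term_id, name = e$name, k = e$k, n = e$n, K = e$K, N = e$N,
      p = sprintf("%.6e", e$p), q = sprintf("%.6e", e$q),
      significant = e$significant
    )
    fmt_tsv(out, file.path(dir, sprintf("enrichment_%s.tsv", cond)))
  }
  invisible(dir)
}
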