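#' Read a gene annotation table
#'
#' BED-like TSV with header `chrom start end symbol biotype`, 0-based half-open
#' coordinates. Symbols must be unique across the genome; `biotype` is
#' `protein_coding` for coding genes and any other string (e.g. `miRNA`,
#' `ORF`) for the rest. Nothing is filtered at load time — the coding-only
#' restriction is applied in [build_gene_set()].
#'
#' @param path Path to the gene annotation TSV.
#' @return Tibble `chrom`, `start`, `end`, `symbol`, `biotype`.
#' @export
read_gene_annotation <- function(path) {
  df <- read_table_chr(path, c("chrom", "start", "end", "symbol", "biotype"))
  out <- tibble(
    chrom = df$chrom,
    start = parse_num_col(df$start, "start", path, integer = TRUE),
    end = parse_num_col(df$end, "end", path, integer = TRUE),
    symbol = df$symbol,
    biotype = df$biotype
  )
  if (any(out$start >= out$end)) {
    i <- which(out$start >= out$end)[1]
    abort(sprintf("File %s, line %d: gene start must be < end.", path, i + 1L))
  }
  dup <- out$symbol[duplicated(out$symbol)]
  if (length(dup) > 0L) {
    abort(sprintf("File %s: duplicate gene symbol(s): %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Build the altered gene set for one sample and condition
#'
#' Collects every gene overlapping any altered cytoband of one
#' (sample, condition) — gains and losses pooled into a single set, so that one
#' network is induced per sample per condition. Genes are matched by
#' any-overlap (>= 1 base) of their interval with the cytoband interval; with
#' `unit = "segment"` the supporting segment intervals are used instead of the
#' full cytoband. Non-protein-coding genes (ORFs, miRNAs, ...) are excluded
#' unless `protein_coding_only = FALSE`.
#'
#' @param alterations Rows of [map_cytoband_alterations()] output, all from a
#'   single (sample, condition).
#' @param genes Gene annotation tibble ([read_gene_annotation()]).
#' @param cytobands Cytoband tibble ([read_cytobands()]).
#' @param protein_coding_only Keep only `biotype == "protein_coding"` genes
#'   (default `TRUE`).
#' @param unit Overlap unit: `"cytoband"` (default; the unit of alteration
#'   selection) or `"segment"`.
#' @param directions Which alteration directions feed the set (default both,
#'   pooled).
#' @return Tibble of provenance rows `sample_id`, `condition`, `symbol`,
#'   `cytoband`, `direction` — one row per (gene, supporting cytoband,
#'   direction); the gene set itself is `unique(result$symbol)`.
#' @export
build_gene_set <- function(alterations, genes, cytobands,
                           protein_coding_only = TRUE,
                           unit = c("cytoband", "segment"),
                           directions = c("gain", "loss")) {
  unit <- match.arg(unit)
  empty <- tibble(sample_id = character(0), condition = character(0),
                  symbol = character(0), cytoband = character(0),
                  direction = character(0))
  alterations <- filter(alterations, .data$direction %in% directions)
  if (nrow(alterations) == 0L) {
    warn("No alterations supplied; returning an empty gene set.")
    return(empty)
  }
  combos <- distinct(alterations, .data$sample_id, .data$condition)
  if (nrow(combos) > 1L) {
    abort("`alterations` must all come from a single (sample_id, condition).")
  }
  if (unit == "cytoband") {
    iv <- alterations |>
      inner_join(rename(cytobands, cytoband = "name"),
                 by = c("cytoband", "chrom")) |>
      select("sample_id", "condition", "cytoband", "direction", "chrom",
             "start", "end")
  } else {
    iv <- alterations |>
      select("sample_id", "condition", "cytoband", "direction", "chrom",
             "segments") |>
      tidyr::unnest("segments") |>
      select("sample_id", "condition", "cytoband", "direction", "chrom",
             "start", "end")
  }
  g <- rename(genes, g_start = "start", g_end = "end")
  if (protein_coding_only) g <- filter(g, .data$biotype == "protein_coding")
  hits <- iv |>
    inner_join(g, by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$g_end, .data$g_start < .data$end) |>
    distinct(.data$sample_id, .data$condition, .data$symbol, .data$cytoband,
             .data$direction) |>
    arrange(.data$symbol, .data$cytoband, .data$direction)
  if (nrow(hits) == 0L) {
    warn("Alterations overlap no (matching) genes; returning an empty gene set.")
    return(empty)
  }
  hits
}

#' Extract the unique gene symbols of a gene set
#'
#' @param gene_set Provenance tibble from [build_gene_set()].
#' @return Sorted character vector of symbols.
#' @export
gene_set_symbols <- function(gene_set) {
  sort(unique(gene_set$symbol))
}
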