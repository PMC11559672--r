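#' Read an aCGH aberration segment table
#'
#' Reads a tab-separated segment report (one row per aberration interval) with
#' header columns `chrom`, `start`, `end`, `mean_log2`, `probes`. Coordinates
#' in the file are 1-based inclusive, the convention of vendor aberration
#' interval reports; internally everything is 0-based half-open, and the
#' conversion happens only here (and symmetrically when writing).
#'
#' @param path Path to a TSV segment report.
#' @param sample_id Sample identifier attached to every returned row.
#' @param condition `"pre"` or `"post"` (chemotherapy).
#' @return A tibble with columns `sample_id`, `condition`, `chrom`, `start`,
#'   `end` (0-based half-open), `mean_log2`, `probe_count`, and `direction`
#'   (initialised to `"neutral"`, pending [classify_cna()]). Rows keep file
#'   order.
#' @seealso [classify_cna()], [count_cna_calls()]
#' @export
read_cna_segments <- function(path, sample_id, condition) {
  check_condition(condition)
  required <- c("chrom", "start", "end", "mean_log2", "probes")
  df <- read_table_chr(path, required)
  start1 <- parse_num_col(df$start, "start", path, integer = TRUE)
  end1 <- parse_num_col(df$end, "end", path, integer = TRUE)
  mean_log2 <- parse_num_col(df$mean_log2, "mean_log2", path)
  probes <- parse_num_col(df$probes, "probes", path, integer = TRUE)
  bad <- which(start1 > end1)
  if (length(bad) > 0L) {
    abort(sprintf("File %s, line %d: start (%d) > end (%d).",
                  path, bad[1] + 1L, start1[bad[1]], end1[bad[1]]))
  }
  if (any(probes < 1L)) {
    i <- which(probes < 1L)[1]
    abort(sprintf("File %s, line %d: probes must be >= 1.", path, i + 1L))
  }
  tibble(
    sample_id = as.character(sample_id),
    condition = condition,
    chrom = df$chrom,
    start = start1 - 1L,
    end = end1,
    mean_log2 = mean_log2,
    probe_count = probes,
    direction = if (nrow(df) > 0) "neutral" else character(0)
  )
}

#' Call gains and losses from segment mean log2 ratios
#'
#' Applies the standard aCGH calling rule: a segment is a gain when its mean
#' log2 ratio (Cy5/Cy3) strictly exceeds `gain_threshold`, a loss when it is
#' strictly below `loss_threshold`, and neutral otherwise. Segments that fail
#' the probe filter (probe count must strictly exceed `min_probes`) are marked
#' `filtered` regardless of ratio. All comparisons are strict, so a segment at
#' exactly 0.25 is neutral and one with exactly 3 probes is filtered.
#'
#' Classification is total and idempotent: it depends only on `mean_log2`,
#' `probe_count` and the thresholds.
#'
#' @param segments Tibble of segments as returned by [read_cna_segments()].
#' @param gain_threshold Gain calling threshold on the log2 scale (default
#'   0.25).
#' @param loss_threshold Loss calling threshold (default -0.25).
#' @param min_probes Probe filter: segments with `probe_count <= min_probes`
#'   are excluded from calling (default 3, i.e. at least 4 probes required).
#' @return The input tibble with `direction` set to one of `"gain"`, `"loss"`,
#'   `"neutral"`, `"filtered"`.
#' @export
classify_cna <- function(segments, gain_threshold = 0.25,
                         loss_threshold = -0.25, min_probes = 3L) {
  if (!(loss_threshold < 0 && 0 < gain_threshold)) {
    abort("Thresholds must satisfy loss_threshold < 0 < gain_threshold.")
  }
  dplyr::mutate(segments, direction = dplyr::case_when(
    .data$probe_count <= min_probes ~ "filtered",
    .data$mean_log2 > gain_threshold ~ "gain",
    .data$mean_log2 < loss_threshold ~ "loss",
    TRUE ~ "neutral"
  ))
}

#' Count significant CNA calls per sample and condition
#'
#' A "call" is a segment classified as gain or loss; filtered and neutral
#' segments do not count. Counts are keyed independently per
#' (sample, condition) pair and are invariant under row order.
#'
#' @param segments Classified segments (see [classify_cna()]).
#' @return Tibble `sample_id`, `condition`, `n_calls`, `n_gains`, `n_losses`.
#' @export
count_cna_calls <- function(segments) {
  segments |>
    group_by(.data$sample_id, .data$condition) |>
    summarise(
      n_calls = sum(.data$direction %in% c("gain", "loss")),
      n_gains = sum(.data$direction == "gain"),
      n_losses = sum(.data$direction == "loss"),
      .groups = "drop"
    ) |>
    arrange(.data$sample_id, .data$condition)
}

#' Read a cytoband interval file
#'
#' BED-like TSV with header `chrom start end name`, 0-based half-open
#' coordinates (standard BED). Cytobands are expected to tile each chromosome
#' without overlap.
#'
#' @param path Path to the cytoband TSV.
#' @return Tibble `chrom`, `start`, `end`, `name`.
#' @export
read_cytobands <- function(path) {
  df <- read_table_chr(path, c("chrom", "start", "end", "name"))
  out <- tibble(
    chrom = df$chrom,
    start = parse_num_col(df$start, "start", path, integer = TRUE),
    end = parse_num_col(df$end, "end", path, integer = TRUE),
    name = df$name
  )
  if (any(out$start >= out$end)) {
    i <- which(out$start >= out$end)[1]
    abort(sprintf("File %s, line %d: cytoband start must be < end.", path, i + 1L))
  }
  out
}

#' Map gain/loss segments onto cytobands
#'
#' A cytoband is recorded as altered for a (sample, condition, direction) if at
#' least one segment called in that direction overlaps it by one base or more
#' (any-overlap rule). Neutral and filtered segments never contribute. When the
#' same cytoband carries both a gain and a loss for one sample/condition, both
#' records are kept and flagged `discordant`.
#'
#' @param segments Classified segments.
#' @param cytobands Cytoband tibble from [read_cytobands()].
#' @return Tibble with one row per (sample_id, condition, cytoband, direction):
#'   columns `sample_id`, `condition`, `cytoband`, `chrom`, `direction`,
#'   `n_segments`, `discordant`, and a list-column `segments` holding the
#'   supporting segment rows.
#' @export
map_cytoband_alterations <- function(segments, cytobands) {
  altered <- filter(segments, .data$direction %in% c("gain", "loss"))
  unknown <- setdiff(unique(altered$chrom), unique(cytobands$chrom))
  if (length(unknown) > 0L) {
    warn(sprintf("Skipping %d segment(s) on chromosome(s) absent from the cytoband map: %s",
                 sum(altered$chrom %in% unknown), paste(unknown, collapse = ", ")))
    altered <- filter(altered, !.data$chrom %in% unknown)
  }
  cb <- rename(cytobands, cb_start = "start", cb_end = "end", cytoband = "name")
  hits <- altered |>
    inner_join(cb, by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$cb_end, .data$cb_start < .data$end)
  out <- hits |>
    group_by(.data$sample_id, .data$condition, .data$cytoband, .data$chrom,
             .data$direction) |>
    tidyr::nest(segments = c("start", "end", "mean_log2", "probe_count")) |>
    ungroup() |>
    mutate(n_segments = purrr::map_int(.data$segments, nrow)) |>
    group_by(.data$sample_id, .data$condition, .data$cytoband) |>
    mutate(discordant = dplyr::n_distinct(.data$direction) > 1L) |>
    ungroup() |>
    select("sample_id", "condition", "cytoband", "chrom", "direction",
           "n_segments", "discordant", "segments") |>
    arrange(.data$sample_id, .data$condition, .data$cytoband, .data$direction)
  out
}

#' Select cytobands recurrently altered across samples
#'
#' Keeps, within each condition, the cytobands altered (in either direction) in
#' at least `min_samples` distinct samples. Direction concordance across
#' samples is annotated (`concordant`), not required: a band gained in one
#' sample and lost in another still counts as recurrent, mirroring the
#' opposite-change bands highlighted in cross-patient CNA tables. With
#' `min_samples = 1` every altered cytoband is returned; setting `min_samples`
#' to the number of samples enforces the present-in-all-samples criterion.
#'
#' @param alterations Output of [map_cytoband_alterations()].
#' @param min_samples Minimum number of distinct samples (default 2).
#' @return Tibble `condition`, `cytoband`, `chrom`, `n_samples`, `concordant`,
#'   plus a list-column `by_sample` of per-sample directions.
#' @export
recurrent_cytobands <- function(alterations, min_samples = 2L) {
  if (!is.numeric(min_samples) || length(min_samples) != 1L || min_samples < 1) {
    abort("`min_samples` must be a single integer >= 1.")
  }
  alterations |>
    group_by(.data$condition, .data$cytoband, .data$chrom) |>
    summarise(
      by_sample = list(dplyr::pick("sample_id", "direction", "n_segments")),
      n_samples = n_distinct(.data$sample_id),
      concordant = n_distinct(.data$direction) == 1L,
      .groups = "drop"
    ) |>
    filter(.data$n_samples >= min_samples) |>
    select("condition", "cytoband", "chrom", "n_samples", "concordant",
           "by_sample") |>
    arrange(.data$condition, .data$cytoband)
}
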