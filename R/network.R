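#' Interaction evidence channels
#'
#' `all_interaction_channels()` lists the eleven evidence channels of the
#' STRING protein-links-full layout. `string_evidence_channels()` returns the
#' six channels used by default for edge filtering: co-expression, database and
#' experiments evidence plus their homology-transferred variants. Text-mining
#' channels are deliberately not among the defaults.
#'
#' @return Character vector of channel names.
#' @export
all_interaction_channels <- function() {
  c("neighborhood", "fusion", "cooccurrence",
    "coexpression", "coexpression_transferred",
    "experiments", "experiments_transferred",
    "database", "database_transferred",
    "textmining", "textmining_transferred")
}

#' @rdname all_interaction_channels
#' @export
string_evidence_channels <- function() {
  c("coexpression", "coexpression_transferred",
    "database", "database_transferred",
    "experiments", "experiments_transferred")
}

#' Read and filter a multi-channel interaction table
#'
#' Reads a whitespace-separated edge file in the STRING protein-links-full
#' layout: header `protein1 protein2 <channel...> combined_score`, channel
#' scores as integers on the 0-1000 scale (a confidence of 0.4 is 400).
#' Channel columns may appear in any order; unknown columns are ignored.
#'
#' An edge is retained when, among the *selected* channels, the score filter
#' passes: with `combine = "any"` (default) at least one selected channel must
#' reach `min_score`; with `combine = "all"` every selected channel must.
#' Unselected channels never qualify an edge, so a pure text-mining edge is
#' dropped under the default channel set.
#'
#' @param path Path to the edge file.
#' @param channels Selected channels (default [string_evidence_channels()]).
#' @param min_score Minimum channel score, 0-1000 scale (default 400).
#' @param combine `"any"` (an edge passes if any selected channel reaches
#'   `min_score`) or `"all"` (every selected channel must).
#' @return Tibble `node_a`, `node_b`, one column per selected channel, and
#'   `combined_score` when present in the file.
#' @export
read_interactions <- function(path, channels = string_evidence_channels(),
                              min_score = 400L, combine = c("any", "all")) {
  combine <- match.arg(combine)
  valid <- all_interaction_channels()
  unknown <- setdiff(channels, valid)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown channel(s): %s. Valid channels are: %s",
                  paste(unknown, collapse = ", "),
                  paste(valid, collapse = ", ")))
  }
  if (length(channels) == 0L) abort("At least one channel must be selected.")
  df <- read_table_chr(path, c("protein1", "protein2"), delim = "ws")
  missing <- setdiff(channels, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("File %s is missing selected channel column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  scores <- lapply(channels, function(ch) parse_num_col(df[[ch]], ch, path, integer = TRUE))
  names(scores) <- channels
  smat <- do.call(cbind, scores)
  if (length(smat) > 0 && (min(smat) < 0 || max(smat) > 1000)) {
    abort(sprintf("File %s: channel scores must lie in [0, 1000].", path))
  }
  keep <- if (nrow(df) == 0L) {
    logical(0)
  } else if (combine == "any") {
    rowSums(smat >= min_score) > 0L
  } else {
    rowSums(smat >= min_score) == length(channels)
  }
  out <- tibble(node_a = df$protein1, node_b = df$protein2)
  for (ch in channels) out[[ch]] <- scores[[ch]]
  if ("combined_score" %in% names(df)) {
    out$combined_score <- parse_num_col(df$combined_score, "combined_score", path,
                                        integer = TRUE)
  }
  out[keep, , drop = FALSE]
}

#' Induce the main-component PPI subnetwork of a gene set
#'
#' Keeps the interactions whose two endpoints both belong to the gene set,
#' removes self-loops, merges duplicate and reciprocal records into single
#' undirected edges, and restricts the graph to its largest connected
#' component (ties broken deterministically by the component containing the
#' lexicographically smallest symbol). Nodes left without any retained edge
#' are removed, so the result is always simple and connected.
#'
#' @param gene_set Provenance tibble from [build_gene_set()] or a character
#'   vector of symbols.
#' @param interactions Filtered edge tibble from [read_interactions()].
#' @param sample_id,condition Provenance labels; taken from `gene_set` when it
#'   carries them.
#' @return A `ppi_network` object wrapping an igraph graph plus provenance.
#' @export
induce_ppi_network <- function(gene_set, interactions,
                               sample_id = NULL, condition = NULL) {
  if (is.data.frame(gene_set)) {
    sample_id <- sample_id %||% gene_set$sample_id[1]
    condition <- condition %||% gene_set$condition[1]
    symbols <- unique(gene_set$symbol)
  } else {
    symbols <- unique(as.character(gene_set))
  }
  tag <- sprintf("sample '%s', condition '%s'",
                 sample_id %||% "?", condition %||% "?")
  edges <- interactions |>
    filter(.data$node_a %in% symbols, .data$node_b %in% symbols,
           .data$node_a != .data$node_b) |>
    distinct(pair_min = pmin(.data$node_a, .data$node_b),
             pair_max = pmax(.data$node_a, .data$node_b))
  if (nrow(edges) == 0L) {
    abort(sprintf("No interactions connect the gene set (%s); the induced network is empty.",
                  tag))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    # deterministic tie-break: component holding the smallest symbol
    first_member <- vapply(big, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    big <- big[order(first_member)][1]
  }
  keep <- igraph::V(g)$name[comp$membership == big]
  g <- igraph::induced_subgraph(g, keep)
  structure(
    list(graph = g, sample_id = sample_id, condition = condition),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %s/%s: %d nodes, %d edges (main component)\n",
              x$sample_id %||% "?", x$condition %||% "?",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Nodes of a PPI network
#' @param network A `ppi_network`.
#' @return Sorted character vector of node symbols.
#' @export
network_nodes <- function(network) {
  sort(igraph::V(network$graph)$name)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PPI network into an edge tibble
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return Tibble `node_a`, `node_b` with `node_a < node_b`, sorted.
#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph)
  tibble(node_a = pmin(el[, 1], el[, 2]), node_b = pmax(el[, 1], el[, 2])) |>
    arrange(.data$node_a, .data$node_b)
}

#' One-row summary of a PPI network
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  n <- igraph::vcount(x$graph)
  m <- igraph::ecount(x$graph)
  tibble(sample_id = x$sample_id %||% NA_character_,
         condition = x$condition %||% NA_character_,
         n_nodes = n, n_edges = m,
         density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_)
}
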