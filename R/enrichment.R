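new_ontology <- function(parents, names_map = NULL) {
  terms <- sort(unique(c(names(parents), unlist(parents, use.names = FALSE))))
  parents <- parents[intersect(terms, names(parents))]
  full <- setNames(vector("list", length(terms)), terms)
  full[names(parents)] <- parents
  full <- lapply(full, function(p) sort(unique(p %||% character(0))))
  roots <- terms[lengths(full) == 0L]
  ont <- structure(
    list(terms = terms, parents = full, roots = roots,
         names = names_map %||% setNames(character(0), character(0))),
    class = "ontology"
  )
  check_acyclic(ont)
  ont
}

# Kahn topological sort; on failure, walk parent links to exhibit one cycle.
check_acyclic <- function(ont) {
  indeg <- setNames(lengths(ont$parents), ont$terms)
  children <- split(
    rep(names(ont$parents), lengths(ont$parents)),
    unlist(ont$parents, use.names = FALSE)
  )
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[t]] %||% character(0)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ont$terms)) {
    unresolved <- names(indeg)[indeg > 0L]
    start <- unresolved[1]
    path <- start
    cur <- start
    repeat {
      ps <- ont$parents[[cur]]
      cur <- ps[ps %in% unresolved][1]
      if (cur %in% path) {
        cyc <- c(path[which(path == cur):length(path)], cur)
        abort(sprintf("Ontology contains a cycle: %s", paste(cyc, collapse = " -> ")))
      }
      path <- c(path, cur)
    }
  }
  invisible(ont)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d root(s)\n", length(x$terms), length(x$roots)))
  invisible(x)
}

#' Read an ontology from child-parent edge files
#'
#' The DAG file is a TSV with header `child_id parent_id`, one row per is-a
#' edge; an optional names file is a TSV `term_id name`. Terms appearing only
#' as parents are included as roots. The structure must be acyclic; a cycle is
#' reported explicitly.
#'
#' @param dag_path Path to the child-parent TSV.
#' @param names_path Optional path to the term-name TSV.
#' @return An `ontology` object (terms, parent map, roots, names).
#' @export
read_ontology <- function(dag_path, names_path = NULL) {
  df <- read_table_chr(dag_path, c("child_id", "parent_id"))
  parents <- split(df$parent_id, df$child_id)
  names_map <- NULL
  if (!is.null(names_path)) {
    nm <- read_table_chr(names_path, c("term_id", "name"))
    names_map <- setNames(nm$name, nm$term_id)
  }
  new_ontology(parents, names_map)
}

#' Read a minimal OBO file
#'
#' Supports the subset of OBO used for is-a hierarchies: `[Term]` stanzas with
#' `id:`, `name:` and `is_a:` lines (trailing `! comments` stripped).
#' Evidence codes, qualifiers and obsoletion chains are out of scope.
#'
#' @param path Path to the OBO file.
#' @return An `ontology` object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  id <- NULL
  parents <- list()
  names_map <- character(0)
  flush <- function(id, ps, nm) {
    if (!is.null(id)) {
      parents[[id]] <<- unique(c(parents[[id]], ps))
      if (!is.na(nm)) names_map[[id]] <<- nm
    }
  }
  ps <- character(0); nm <- NA_character_
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") {
      flush(id, ps, nm)
      in_term <- TRUE; id <- NULL; ps <- character(0); nm <- NA_character_
    } else if (grepl("^\\[", ln)) {
      flush(id, ps, nm); in_term <- FALSE; id <- NULL
    } else if (in_term && grepl("^id:", ln)) {
      id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      nm <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      ps <- c(ps, trimws(sub("^is_a:", "", ln)))
    }
  }
  flush(id, ps, nm)
  new_ontology(parents, if (length(names_map)) names_map else NULL)
}

# Ancestor closure (excluding the term itself) for every term, memoised over
# the whole ontology in topological order.
ontology_ancestors <- function(ont) {
  anc <- setNames(vector("list", length(ont$terms)), ont$terms)
  done <- setNames(logical(length(ont$terms)), ont$terms)
  visit <- function(t) {
    if (done[[t]]) return(anc[[t]])
    ps <- ont$parents[[t]]
    out <- ps
    for (p in ps) out <- c(out, visit(p))
    out <- sort(unique(out))
    anc[[t]] <<- out
    done[[t]] <<- TRUE
    out
  }
  for (t in ont$terms) visit(t)
  anc
}

#' Read gene-to-term annotations
#'
#' Two-column TSV with header `gene term_id` (a GAF-like projection).
#'
#' @param path Path to the annotation TSV.
#' @return Tibble `gene`, `term_id`.
#' @export
read_term_annotations <- function(path) {
  df <- read_table_chr(path, c("gene", "term_id"))
  distinct(tibble(gene = df$gene, term_id = df$term_id))
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; this closes each gene's term set under the ancestor relation.
#' The operation is idempotent. Annotated terms missing from the ontology are
#' kept as-is with a warning (they cannot be propagated).
#'
#' @param annotations Tibble `gene`, `term_id`.
#' @param ontology An `ontology` object.
#' @return The propagated annotation tibble, flagged with
#'   `attr(, "propagated") = TRUE`.
#' @export
propagate_annotations <- function(annotations, ontology) {
  unknown <- setdiff(unique(annotations$term_id), ontology$terms)
  if (length(unknown) > 0L) {
    warn(sprintf("%d annotated term(s) absent from the ontology are kept unpropagated: %s",
                 length(unknown), paste(head(unknown, 5), collapse = ", ")))
  }
  anc <- ontology_ancestors(ontology)
  extra <- annotations |>
    filter(.data$term_id %in% ontology$terms) |>
    mutate(term_id = purrr::map(.data$term_id, ~ anc[[.x]])) |>
    tidyr::unnest("term_id")
  out <- bind_rows(annotations, extra) |>
    distinct(.data$gene, .data$term_id) |>
    arrange(.data$gene, .data$term_id)
  attr(out, "propagated") <- TRUE
  out
}

#' Term over-representation by the one-sided hypergeometric test
#'
#' For every term annotated to at least one universe gene, tests whether the
#' study set contains more annotated genes than expected when drawing `n`
#' genes without replacement from the universe. The p-value is the exact
#' upper-tail hypergeometric probability (identical to one-sided Fisher's
#' exact test on the 2x2 table); q-values are Benjamini-Hochberg adjusted over
#' all tested terms (family size = number of tested terms; terms with `K = 0`
#' are never tested).
#'
#' @param study Character vector of study gene symbols (must be a subset of
#'   the universe).
#' @param annotations Annotation tibble; propagated automatically when an
#'   `ontology` is supplied and the tibble is not yet flagged as propagated.
#' @param universe Character vector of universe genes; defaults to every gene
#'   with at least one (propagated) annotation.
#' @param ontology Optional `ontology`, used for propagation and term names.
#' @param alpha Significance level on the q-value scale (default 0.05).
#' @return An `enrichment_result` tibble `term_id`, `name`, `k`, `n`, `K`,
#'   `N`, `p`, `q`, `significant`, sorted by `q` then `p`.
#' @export
enrich_terms <- function(study, annotations, universe = NULL, ontology = NULL,
                         alpha = 0.05) {
  if (!isTRUE(attr(annotations, "propagated", exact = TRUE)) && !is.null(ontology)) {
    annotations <- propagate_annotations(annotations, ontology)
  }
  study <- unique(as.character(study))
  universe <- unique(universe %||% annotations$gene)
  outside <- setdiff(study, universe)
  if (length(outside) > 0L) {
    abort(sprintf("Study gene(s) not in the universe: %s",
                  paste(sort(outside), collapse = ", ")))
  }
  ann <- filter(annotations, .data$gene %in% universe)
  N <- length(universe)
  n <- length(study)
  per_term <- ann |>
    group_by(.data$term_id) |>
    summarise(K = n_distinct(.data$gene),
              k = sum(unique(.data$gene) %in% study), .groups = "drop") |>
    filter(.data$K >= 1L)
  p <- phyper(per_term$k - 1L, per_term$K, N - per_term$K, n, lower.tail = FALSE)
  nm <- if (!is.null(ontology) && length(ontology$names) > 0) {
    unname(ontology$names[per_term$term_id])
  } else {
    NA_character_
  }
  out <- tibble(
    term_id = per_term$term_id,
    name = nm,
    k = per_term$k, n = n, K = per_term$K, N = N,
    p = p,
    q = p.adjust(p, method = "BH")
  ) |>
    mutate(significant = .data$q < alpha) |>
    arrange(.data$q, .data$p, .data$term_id)
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Drop generic, uninformative terms from an enrichment result
#'
#' Removes terms whose id or exact name appears in the blocklist — the
#' standard cleanup that discards catch-all categories such as "regulation of
#' biological processes" which carry no interpretable signal. Order is
#' preserved and the number of removed rows is recorded in
#' `attr(, "n_removed")`.
#'
#' @param results An `enrichment_result`.
#' @param blocklist Character vector of term ids or exact term names; defaults
#'   to [generic_term_blocklist()].
#' @return The filtered `enrichment_result`.
#' @export
filter_generic_terms <- function(results, blocklist = generic_term_blocklist()) {
  drop <- results$term_id %in% blocklist |
    (!is.na(results$name) & results$name %in% blocklist)
  out <- results[!drop, , drop = FALSE]
  attr(out, "alpha") <- attr(results, "alpha", exact = TRUE)
  attr(out, "n_removed") <- sum(drop)
  class(out) <- class(results)
  out
}

#' Default blocklist of generic ontology term names
#'
#' @return Character vector of term names treated as uninformative.
#' @export
generic_term_blocklist <- function() {
  c("biological process", "regulation of biological processes",
    "biochemical processes")
}

#' One-row summary of an enrichment result
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms_tested = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha", exact = TRUE) %||% NA_real_,
         min_q = if (nrow(x) > 0) min(x$q) else NA_real_)
}
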