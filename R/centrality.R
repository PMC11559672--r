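# Betweenness by Brandes' dependency-accumulation algorithm on an unweighted
# undirected graph given as a 1-indexed adjacency list. Conventions fixed for
# mean-threshold classification: unnormalized, each unordered source-target
# pair counted once, endpoints excluded (so every leaf scores 0).
brandes_betweenness <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  if (n == 0L) return(bc)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    visited <- integer(n)
    nv <- 0L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nv <- nv + 1L
      visited[nv] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in seq.int(nv, 1L)) {
      w <- visited[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  bc / 2
}

# Principal-eigenvector centrality by power iteration, scaled so the maximum
# entry is 1. Iterates on A + I: a connected graph makes A + I primitive, so
# the iteration converges even on bipartite graphs, and the principal
# eigenvector is unchanged by the shift.
power_eigenvector <- function(A, tol = 1e-10, max_iter = 1000L) {
  n <- nrow(A)
  if (n == 1L) return(1)
  M <- A + diag(n)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(M %*% x)
    y <- y / max(y)
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  abort(sprintf("Eigenvector power iteration did not converge within %d iterations (tol %g).",
                max_iter, tol))
}

#' Compute node centralities of a PPI network
#'
#' For a simple, connected, undirected, unweighted network, computes per node:
#' * `degree` — number of incident edges;
#' * `betweenness` — shortest-path betweenness by Brandes-style pair-dependency
#'   accumulation: unnormalized, unordered source-target pairs counted once,
#'   endpoints excluded;
#' * `eigenvector` — principal eigenvector of the adjacency matrix by power
#'   iteration (infinity-norm tolerance 1e-10, at most 1000 iterations),
#'   scaled so the maximum entry equals 1.
#'
#' These conventions matter: normalization changes the mean-threshold
#' classification of [classify_hbs()], so they are fixed here rather than left
#' to a library default.
#'
#' @param network A `ppi_network` (or an undirected igraph graph).
#' @return A tibble `node`, `degree`, `betweenness`, `eigenvector`, sorted by
#'   node symbol, carrying sample/condition provenance as attributes.
#' @export
node_centralities <- function(network) {
  if (inherits(network, "ppi_network")) {
    g <- network$graph
    sample_id <- network$sample_id
    condition <- network$condition
  } else if (inherits(network, "igraph")) {
    g <- network
    sample_id <- condition <- NULL
  } else {
    abort("`network` must be a ppi_network or an igraph graph.")
  }
  if (igraph::vcount(g) == 0L) abort("Network is empty.")
  if (igraph::is_directed(g)) abort("Network must be undirected.")
  if (!igraph::is_simple(g)) abort("Network must be simple (no loops or multi-edges).")
  if (!igraph::is_connected(g)) abort("Network must be connected (restrict to the main component first).")
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  out <- tibble(
    node = nodes,
    degree = as.integer(lengths(adj)),
    betweenness = brandes_betweenness(adj),
    eigenvector = power_eigenvector(A)
  ) |>
    arrange(.data$node)
  attr(out, "sample_id") <- sample_id
  attr(out, "condition") <- condition
  out
}

#' Classify hubs, bottlenecks, switches and HBS nodes
#'
#' Labels each node by comparing its centrality scores with the network-wide
#' arithmetic means: a *hub* has strictly above-mean degree, a *bottleneck*
#' strictly above-mean betweenness, a *switch* strictly above-mean eigenvector
#' centrality, and an *HBS* (hub-bottleneck-switch) is all three at once.
#' Strict inequality means a regular (vertex-transitive) network yields no
#' labels at all — every score equals its mean.
#'
#' @param centralities Tibble from [node_centralities()].
#' @return An `hbs_result`: the input tibble extended with `is_hub`,
#'   `is_bottleneck`, `is_switch`, `is_hbs`, with the three mean thresholds in
#'   `attr(, "thresholds")`.
#' @export
classify_hbs <- function(centralities) {
  if (nrow(centralities) == 0L) abort("`centralities` must be non-empty.")
  thr <- list(degree = mean(centralities$degree),
              betweenness = mean(centralities$betweenness),
              eigenvector = mean(centralities$eigenvector))
  out <- centralities |>
    mutate(
      is_hub = .data$degree > thr$degree,
      is_bottleneck = .data$betweenness > thr$betweenness,
      is_switch = .data$eigenvector > thr$eigenvector,
      is_hbs = .data$is_hub & .data$is_bottleneck & .data$is_switch
    )
  attr(out, "thresholds") <- thr
  attr(out, "sample_id") <- attr(centralities, "sample_id", exact = TRUE)
  attr(out, "condition") <- attr(centralities, "condition", exact = TRUE)
  class(out) <- c("hbs_result", class(out))
  out
}

#' HBS members of a classification
#' @param hbs An `hbs_result`.
#' @return Sorted character vector of HBS node symbols.
#' @export
hbs_members <- function(hbs) {
  sort(hbs$node[hbs$is_hbs])
}

#' @method tidy hbs_result
#' @export
tidy.hbs_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "hbs_result")
  as_tibble(out)
}

#' One-row summary of an HBS classification
#' @param x An `hbs_result`.
#' @param ... Unused.
#' @method glance hbs_result
#' @export
glance.hbs_result <- function(x, ...) {
  thr <- attr(x, "thresholds", exact = TRUE)
  tibble(
    sample_id = attr(x, "sample_id", exact = TRUE) %||% NA_character_,
    condition = attr(x, "condition", exact = TRUE) %||% NA_character_,
    n_nodes = nrow(x),
    n_hubs = sum(x$is_hub), n_bottlenecks = sum(x$is_bottleneck),
    n_switches = sum(x$is_switch), n_hbs = sum(x$is_hbs),
    mean_degree = thr$degree, mean_betweenness = thr$betweenness,
    mean_eigenvector = thr$eigenvector
  )
}
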