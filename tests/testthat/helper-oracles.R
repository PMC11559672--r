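# Independent oracles used across the suite. They deliberately share no code
# with the package: betweenness is recomputed from matrix powers of the
# adjacency matrix, eigenvector centrality from a dense eigendecomposition,
# hypergeometric tails from explicit binomial-coefficient sums, and BH from
# the step-up formula written out directly.

# Shortest-path betweenness via matrix powers: sigma[s,t] = (A^d(s,t))[s,t],
# d = first power with a positive walk count. Dependency of v on pair (s,t)
# is sigma[s,v] * sigma[v,t] / sigma[s,t] when v lies on a shortest path.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- diag(1, n)
  P <- diag(1, n)
  for (l in seq_len(max(n - 1L, 1L))) {
    P <- P %*% A
    newly <- is.infinite(D) & P > 0
    D[newly] <- l
    S[newly] <- P[newly]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        if (s == v || t == v || is.infinite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  bc
}

# Principal eigenvector from a dense symmetric eigendecomposition,
# max-normalized with the Perron sign fixed.
oracle_eigenvector <- function(A) {
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  v / max(v)
}

# Upper-tail hypergeometric probability as an explicit coefficient sum.
# For N <= 30 every term is an exact ratio of integers below 2^53.
oracle_hyper_p <- function(N, K, n, k) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- seq.int(k, hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j, mapped back
# to the original order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Random connected simple graph with vertex names in lexicographic = index
# order; rejection-sampled from G(n, p).
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# igraph graph from an undirected edge list given as a 2-column matrix/pairs.
graph_from_pairs <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(e, directed = FALSE)
}

centralities_by_index <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("n%02d", seq_len(igraph::vcount(g)))
  }
  ct <- node_centralities(g)
  ct[order(ct$node), ]
}

# Write a 1-based inclusive segment TSV from internal-style fields.
write_segment_file <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                                .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

tiny_cytobands <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 1000L, 0L),
    end = c(1000L, 2000L, 1500L),
    name = c("1p11", "1q11", "2p11")
  )
}

tiny_genes <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 500L, 1200L, 200L),
    end = c(200L, 650L, 1400L, 400L),
    symbol = c("AKT9", "MIR99", "TP99", "BRC9"),
    biotype = c("protein_coding", "miRNA", "protein_coding", "protein_coding")
  )
}

# Minimal classified segment tibble builder.
make_segments <- function(mean_log2, probe_count, sample_id = "S1",
                          condition = "pre", chrom = "chr1",
                          start = 0L, end = 100L) {
  tibble::tibble(
    sample_id = sample_id, condition = condition, chrom = chrom,
    start = start, end = end, mean_log2 = mean_log2,
    probe_count = probe_count, direction = "neutral"
  )
}

# BH step-up rejection set at level alpha, straight from the procedure:
# reject the smallest j* p-values where j* = max{j : p_(j) < alpha * j / m}.
oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] < alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(ks) > 0L) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}
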