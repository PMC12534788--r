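# Shared fixtures and independent oracles used across test files.

# Write a small OBO file from named is_a lists and return its path.
write_obo_fixture <- function(is_a, obsolete = character(0),
                              path = tempfile(fileext = ".obo")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in names(is_a)) {
    writeLines(c("", "[Term]", paste0("id: ", t), paste0("name: name ", t)), con)
    for (p in is_a[[t]]) writeLines(paste0("is_a: ", p, " ! parent"), con)
    if (t %in% obsolete) writeLines("is_obsolete: true", con)
  }
  path
}

# Independent ancestor closure by repeated expansion (no memoized DFS).
brute_ancestors <- function(is_a, term) {
  out <- term
  repeat {
    grown <- unique(c(out, unlist(is_a[out], use.names = FALSE)))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

# Independent Newman-Girvan Q from the incidence edge list.
brute_modularity <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(c(edges[, 1L], edges[, 2L]))
  comms <- unique(membership)
  q <- 0
  for (cc in comms) {
    nodes <- names(membership)[membership == cc]
    e_c <- sum(edges[, 1L] %in% nodes & edges[, 2L] %in% nodes)
    d_c <- sum(deg[names(deg) %in% nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# All set partitions of a vector, as lists of integer membership vectors
# (restricted growth strings). Bell(8) = 4140, so fine for <= 8 nodes.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    k <- if (length(prefix)) max(prefix) else 0L
    for (v in seq_len(k + 1L)) grow(c(prefix, v))
  }
  grow(integer(0))
  out
}

# Exhaustive maximum modularity over all partitions of a small graph.
exhaustive_max_q <- function(net) {
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    best <- max(best, brute_modularity(el, memb))
  }
  best
}

# Adjusted Rand Index between two labelings (independent closed form).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Tiny gene interval table on one chromosome.
toy_genes <- function() {
  data.frame(
    gene = c("geneA", "geneB", "geneC"),
    chrom = "chr1",
    start = c(100L, 1000L, 5000L),
    end = c(300L, 1500L, 5400L),
    strand = "+"
  )
}

# Degree-sequence pair (genes, traits) of a bipartite igraph graph.
bipartite_degrees <- function(net) {
  deg <- igraph::degree(net)
  type <- igraph::V(net)$type
  list(genes = sort(deg[!type]), traits = sort(deg[type]))
}

# Hash a text file's contents (for byte-identical reproducibility checks).
digest_file <- function(path) {
  paste(tools::md5sum(path), collapse = "")
}
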