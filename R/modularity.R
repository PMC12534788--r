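# Genotype-to-phenotype bipartite network modularity.
#
# The gene-by-trait incidence matrix defines a bipartite graph; communities
# are found by greedy agglomerative modularity maximization and the observed
# Newman-Girvan modularity Q is compared with 100 degree-preserving
# (checkerboard-swap) shuffles of the incidence matrix.

#' Build a bipartite network from a gene-by-trait incidence matrix
#'
#' One edge per nonzero entry. Gene node names are prefixed `g:` and trait
#' node names `t:` so the two sides never collide. Isolated declared nodes
#' (all-zero rows/columns) are dropped with a message.
#'
#' @param m binary matrix, genes in rows, traits/clusters in columns.
#' @return an igraph graph with vertex attributes `name` and `type`
#'   (FALSE = gene, TRUE = trait).
#' @export
build_network <- function(m) {
  m <- as.matrix(m)
  if (all(m == 0)) stop("all-zero incidence matrix")
  iso_g <- rowSums(m) == 0; iso_t <- colSums(m) == 0
  if (any(iso_g) || any(iso_t)) {
    message("dropping ", sum(iso_g), " isolated gene and ",
            sum(iso_t), " isolated trait nodes")
    m <- m[!iso_g, !iso_t, drop = FALSE]
  }
  nz <- which(m != 0, arr.ind = TRUE)
  genes <- paste0("g:", rownames(m)[nz[, 1L]])
  traits <- paste0("t:", colnames(m)[nz[, 2L]])
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes, to = traits),
    directed = FALSE,
    vertices = data.frame(
      name = c(paste0("g:", rownames(m)), paste0("t:", colnames(m))),
      type = c(rep(FALSE, nrow(m)), rep(TRUE, ncol(m)))
    )
  )
  g
}

#' Greedy community detection
#'
#' Agglomerative greedy modularity maximization: starting from singleton
#' communities, repeatedly merge the community pair with the largest
#' modularity gain dQ = e_ab/m - d_a d_b / (2 m^2), until no merge strictly
#' improves Q. Ties in dQ are broken deterministically by the smallest
#' community-index pair (communities indexed by first-node order).
#'
#' After agglomeration, a deterministic single-node reassignment sweep
#' (each node in order is moved to the adjacent community with the largest
#' strict Q gain, repeated until a full pass makes no move) polishes the
#' partition out of the shallow local optima plain agglomeration is known
#' to hit on small dense graphs.
#'
#' @param net an igraph graph from [build_network()].
#' @param refine run the reassignment sweep. Default TRUE.
#' @return named integer vector: node name -> community id.
#' @export
greedy_communities <- function(net, refine = TRUE) {
  nodes <- igraph::V(net)$name
  if (igraph::ecount(net) == 0L) stop("graph has no edges")
  comm <- agglomerate_partition(net, seq_along(nodes))
  if (refine) {
    # alternate single-node sweeps with further community merges until Q
    # stops improving; both steps only accept strict gains, so this ends
    part <- setNames(match(comm, sort(unique(comm))), nodes)
    q <- modularity_score(net, part)
    repeat {
      comm2 <- agglomerate_partition(net, refine_partition(net, comm))
      part2 <- setNames(match(comm2, sort(unique(comm2))), nodes)
      q2 <- modularity_score(net, part2)
      if (q2 <= q + 1e-12) break
      comm <- comm2; q <- q2
    }
  }
  setNames(match(comm, sort(unique(comm))), nodes)
}

# Agglomerative greedy merges starting from an arbitrary partition:
# repeatedly merge the community pair with the largest strict modularity
# gain dQ = e_ab/m - d_a d_b/(2 m^2); ties break on the smallest index pair.
agglomerate_partition <- function(net, comm) {
  n <- length(comm)
  el <- igraph::as_edgelist(net, names = FALSE)
  m <- nrow(el)
  E <- matrix(0, n, n)   # between-community edge counts
  for (i in seq_len(m)) {
    a <- comm[el[i, 1L]]; b <- comm[el[i, 2L]]
    if (a != b) { E[a, b] <- E[a, b] + 1; E[b, a] <- E[b, a] + 1 }
  }
  deg <- as.numeric(igraph::degree(net))
  d <- vapply(seq_len(n), function(cc) sum(deg[comm == cc]), numeric(1))
  active <- tabulate(comm, n) > 0L
  while (sum(active) > 1L) {
    idx <- which(active)
    dq <- E[idx, idx, drop = FALSE] / m -
      outer(d[idx], d[idx]) / (2 * m^2)
    diag(dq) <- -Inf
    best <- max(dq)
    if (best <= 0) break
    w <- which(dq == best, arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    ord <- order(idx[w[, 1L]], idx[w[, 2L]])
    a <- idx[w[ord[1L], 1L]]; b <- idx[w[ord[1L], 2L]]
    # merge b into a (a < b by the tie rule's ordering)
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b]
    E[a, a] <- 0; E[b, ] <- 0; E[, b] <- 0
    d[a] <- d[a] + d[b]
    active[b] <- FALSE
    comm[comm == b] <- a
  }
  comm
}

# Single-node reassignment sweep: move each node (in index order) to the
# neighboring community (or a fresh singleton) with the largest strict Q
# gain; repeat passes until stable. Deterministic: ties keep the node where
# it is or prefer the smallest community index.
refine_partition <- function(net, comm) {
  el <- igraph::as_edgelist(net, names = FALSE)
  m <- nrow(el)
  n <- length(comm)
  deg <- as.numeric(igraph::degree(net))
  nbrs <- lapply(seq_len(n), function(v) {
    c(el[el[, 1L] == v, 2L], el[el[, 2L] == v, 1L])
  })
  d_comm <- vapply(seq_len(n), function(cc) sum(deg[comm == cc]), numeric(1))
  repeat {
    moved <- FALSE
    for (v in seq_len(n)) {
      a <- comm[v]
      e_to <- table(comm[nbrs[[v]]])
      e_va <- if (as.character(a) %in% names(e_to)) e_to[[as.character(a)]] else 0
      d_a_rest <- d_comm[a] - deg[v]
      # candidate communities: adjacent ones plus an empty singleton slot
      empty <- which(d_comm == 0)
      cand <- sort(unique(c(as.integer(names(e_to)),
                            if (length(empty)) empty[1L])))
      cand <- setdiff(cand, a)
      best_gain <- 0; best_b <- a
      for (b in cand) {
        e_vb <- if (as.character(b) %in% names(e_to)) e_to[[as.character(b)]] else 0
        gain <- (e_vb - e_va) / m -
          deg[v] * (d_comm[b] - d_a_rest) / (2 * m^2)
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_b <- b }
      }
      if (best_b != a) {
        comm[v] <- best_b
        d_comm[a] <- d_comm[a] - deg[v]
        d_comm[best_b] <- d_comm[best_b] + deg[v]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities of (e_c / m - (d_c / 2m)^2), with m the edge
#' count, e_c the number of within-community edges and d_c the total degree
#' of community c. Computed directly from the formula; the graph is treated
#' as undirected and unweighted.
#'
#' @param net an igraph graph.
#' @param partition named vector node name -> community, covering all nodes.
#' @return Q in [-0.5, 1].
#' @export
modularity_score <- function(net, partition) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(partition))) stop("partition missing nodes")
  comm <- partition[nodes]
  el <- igraph::as_edgelist(net)
  m <- nrow(el)
  if (m == 0L) stop("graph has no edges")
  within <- comm[el[, 1L]] == comm[el[, 2L]]
  e_c <- tapply(within, comm[el[, 1L]], sum)
  # e_c indexed by the community of endpoint 1; within-edges have equal
  # endpoint communities so the indexing is consistent
  deg <- igraph::degree(net)
  d_c <- tapply(deg, comm, sum)
  e_full <- setNames(numeric(length(d_c)), names(d_c))
  e_full[names(e_c)] <- e_c
  sum(e_full / m - (d_c / (2 * m))^2)
}

#' Degree-preserving shuffle of a bipartite network
#'
#' Checkerboard swaps on the incidence structure: repeatedly pick two edges
#' (g1,t1), (g2,t2) with g1 != g2, t1 != t2 and both (g1,t2), (g2,t1)
#' absent, and swap them. Every node keeps its exact degree; bipartiteness
#' and simplicity are preserved.
#'
#' @param net an igraph bipartite graph.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_swaps number of attempted swaps. Default `10 * ecount`.
#' @return a shuffled igraph graph with the same vertex set.
#' @export
degree_preserving_shuffle <- function(net, seed, n_swaps = NULL) {
  stopifnot(!missing(seed))
  el <- igraph::as_edgelist(net)
  m <- nrow(el)
  if (m < 2L) stop("need at least 2 edges to shuffle")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  # orient edges gene -> trait using the type attribute
  type <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  flip <- type[el[, 1L]]
  el[flip, ] <- el[flip, 2:1]
  key <- function(g, t) paste0(g, "\r", t)
  present <- new.env(parent = emptyenv(), size = m * 2L)
  for (i in seq_len(m)) assign(key(el[i, 1L], el[i, 2L]), TRUE, envir = present)
  done <- 0L
  set.seed(seed)
  pairs <- matrix(sample.int(m, 2L * n_swaps, replace = TRUE), ncol = 2L)
  for (s in seq_len(n_swaps)) {
    i <- pairs[s, 1L]; j <- pairs[s, 2L]
    if (i == j) next
    g1 <- el[i, 1L]; t1 <- el[i, 2L]
    g2 <- el[j, 1L]; t2 <- el[j, 2L]
    if (g1 == g2 || t1 == t2) next
    if (exists(key(g1, t2), envir = present, inherits = FALSE) ||
        exists(key(g2, t1), envir = present, inherits = FALSE)) next
    rm(list = c(key(g1, t1), key(g2, t2)), envir = present)
    assign(key(g1, t2), TRUE, envir = present)
    assign(key(g2, t1), TRUE, envir = present)
    el[i, 2L] <- t2; el[j, 2L] <- t1
    done <- done + 1L
  }
  if (done == 0L) {
    warning("no valid checkerboard swap found; returning the input network")
    return(net)
  }
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L]),
    directed = FALSE,
    vertices = data.frame(name = igraph::V(net)$name, type = igraph::V(net)$type)
  )
}

#' Modularity permutation test against a degree-preserving null
#'
#' Observed Q from the greedy partition; null Q values from greedy
#' partitions of shuffled networks; empirical
#' p = (1 + #\{null Q >= observed Q\}) / (1 + n_perm).
#'
#' @param net an igraph bipartite graph.
#' @param n_perm number of shuffled networks. Default 100.
#' @param seed RNG seed; permutation i uses seed + i.
#' @return list `partition`, `Q`, `null_Q` (length `n_perm`), `p`.
#' @export
modularity_null_test <- function(net, n_perm = 100L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  part <- greedy_communities(net)
  q_obs <- modularity_score(net, part)
  null_q <- vapply(seq_len(n_perm), function(i) {
    shuf <- degree_preserving_shuffle(net, seed = seed + i)
    modularity_score(shuf, greedy_communities(shuf))
  }, numeric(1))
  list(partition = part, Q = q_obs, null_Q = null_q,
       p = (1 + sum(null_q >= q_obs)) / (1 + n_perm))
}
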