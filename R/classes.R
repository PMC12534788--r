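# NP/ST/MP/HP pleiotropy classes and cross-dataset comparison.
#
# NP: no known phenotype (degree 0); ST: single trait/term (degree 1);
# HP: highly pleiotropic, top quartile of positive degrees (degree >= cutoff);
# MP: the remaining pleiotropic genes (1 < degree < cutoff).

#' Classify genes into NP/ST/MP/HP pleiotropy classes
#'
#' The HP cutoff is the smallest integer at or above the 75th percentile
#' (linear-interpolation quantile) of degrees among genes with degree >= 1,
#' floored at 2. Classes follow: NP = degree 0, ST = degree 1,
#' HP = degree >= cutoff, MP otherwise. The percentile is computed over
#' annotated genes only; including the degree-0 mass would collapse the
#' cutoff for sparse GWAS datasets.
#'
#' @param degrees data.frame with `gene` and `degree`
#'   ([degree_of_pleiotropy()]).
#' @param universe optional gene universe; universe genes missing from
#'   `degrees` are added with degree 0 (NP).
#' @param hp_inclusive if TRUE (default) HP means degree >= cutoff.
#' @param cutoff override the computed cutoff (integer >= 2).
#' @return the table with `class` filled in; attributes `cutoff` and
#'   `dataset`.
#' @export
classify_pleiotropy <- function(degrees, universe = NULL, hp_inclusive = TRUE,
                                cutoff = NULL) {
  df <- degrees[, c("gene", "degree"), drop = FALSE]
  if (!is.null(universe)) {
    extra <- setdiff(universe, df$gene)
    if (length(extra)) {
      df <- rbind(df, data.frame(gene = extra, degree = 0L))
    }
  }
  pos <- df$degree[df$degree >= 1L]
  if (is.null(cutoff)) {
    if (length(pos) < 4L) stop("need at least 4 genes with degree >= 1 to set a quartile cutoff")
    q75 <- quantile(pos, 0.75, type = 7, names = FALSE)
    cutoff <- max(2L, as.integer(ceiling(q75)))
  }
  stopifnot(cutoff >= 2L)
  hp <- if (hp_inclusive) df$degree >= cutoff else df$degree > cutoff
  df$class <- ifelse(df$degree == 0L, "NP",
              ifelse(df$degree == 1L, "ST",
              ifelse(hp, "HP", "MP")))
  if ("n_raw_terms" %in% names(degrees)) {
    df$n_raw_terms <- degrees$n_raw_terms[match(df$gene, degrees$gene)]
  }
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "cutoff") <- cutoff
  attr(df, "dataset") <- attr(degrees, "dataset")
  df
}

#' Spearman correlation of pleiotropy degrees across datasets
#'
#' Joins two pleiotropy tables, within-species on shared gene ids or
#' cross-species through a one-to-one ortholog table, and reports the
#' Spearman rank correlation of degrees.
#'
#' @param a,b pleiotropy tables with `gene` and `degree`.
#' @param orthologs optional data.frame `human`, `mouse` (one-to-one);
#'   `a` is taken as the human-side table.
#' @return list `rho`, `p`, `n` (join size).
#' @export
cross_correlate <- function(a, b, orthologs = NULL) {
  if (is.null(orthologs)) {
    shared <- intersect(a$gene, b$gene)
    da <- a$degree[match(shared, a$gene)]
    db <- b$degree[match(shared, b$gene)]
  } else {
    keep <- orthologs$human %in% a$gene & orthologs$mouse %in% b$gene
    oo <- orthologs[keep, , drop = FALSE]
    da <- a$degree[match(oo$human, a$gene)]
    db <- b$degree[match(oo$mouse, b$gene)]
  }
  if (length(da) < 10L) stop("fewer than 10 joined genes")
  ct <- suppressWarnings(cor.test(da, db, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(da))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the given overlap when
#' drawing |B| genes from the universe with |A| marked.
#'
#' @param set_a,set_b gene sets (subsets of `universe`).
#' @param universe the gene universe.
#' @return list `overlap`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("empty universe")
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1L, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Venn region counts over class membership in several datasets
#'
#' Counts genes in every non-empty region of the membership diagram of the
#' given class (e.g. all pleiotropic genes) across 2-4 pleiotropy tables.
#'
#' @param tables named list of pleiotropy tables.
#' @param classes classes defining membership. Default
#'   `c("ST","MP","HP")` i.e. any annotated gene; use `"HP"` for highly
#'   pleiotropic overlap.
#' @param harmonize optional function mapping each table's gene ids into a
#'   common id space (e.g. mouse -> human via orthologs) before counting.
#' @return named integer vector; names like `"a&b"` list member datasets.
#' @export
venn_counts <- function(tables, classes = c("ST", "MP", "HP"),
                        harmonize = NULL) {
  stopifnot(length(tables) >= 2L, length(tables) <= 4L)
  sets <- lapply(tables, function(t) t$gene[t$class %in% classes])
  if (!is.null(harmonize)) sets <- lapply(sets, harmonize)
  all_genes <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, function(r) paste(names(tables)[r], collapse = "&"))
  counts <- table(key)
  # emit all 2^k - 1 regions, zero-filled
  k <- length(tables)
  regions <- unlist(lapply(seq_len(k), function(m) {
    combn(names(tables), m, paste, collapse = "&", simplify = FALSE)
  }))
  out <- setNames(integer(length(regions)), regions)
  out[names(counts)] <- as.integer(counts)
  out
}
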