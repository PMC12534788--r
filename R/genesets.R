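# Gene-set over-representation in highly pleiotropic genes, greedy
# construction of a non-redundant pathway collection, and ranking of sets
# by minimum HP fraction across datasets.

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per set for the overlap between the query
#' (e.g. HP genes) and each set, both intersected with the universe, with
#' BH adjustment across the collection.
#'
#' @param query gene set of interest (subset of universe).
#' @param sets named list of gene sets ([read_gmt()]).
#' @param universe gene universe.
#' @return data.frame: set, set_size, overlap, universe_size, p, p_adj,
#'   hp_fraction (overlap / set_size within universe).
#' @export
ora <- function(query, sets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  query <- intersect(query, universe)
  if (length(query) == 0L) stop("empty query after universe intersection")
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- phyper(k - 1L, length(s), length(universe) - length(s),
                length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k,
               universe_size = length(universe), p = p,
               hp_fraction = if (length(s)) k / length(s) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), c("set", "set_size", "overlap", "universe_size",
                               "p", "p_adj", "hp_fraction")]
}

#' Greedy construction of a non-redundant pathway collection
#'
#' Iteratively selects the pathway with the largest residual gene count,
#' removes its genes from all remaining pathways, and repeats while any
#' residual pathway still has more than `min_size` genes (strict).
#' Residual-size ties break lexicographically on the set name.
#'
#' @param sets named list of gene sets.
#' @param min_size strict residual-size stopping threshold. Default 25.
#' @return list `selected` (set names in selection order), `covered`
#'   (genes covered), `coverage` (fraction of the collection's gene
#'   universe covered).
#' @export
greedy_nonredundant <- function(sets, min_size = 25L) {
  stopifnot(length(sets) > 0L)
  residual <- lapply(sets, unique)
  all_genes <- unique(unlist(residual, use.names = FALSE))
  selected <- character(0)
  covered <- character(0)
  repeat {
    sizes <- lengths(residual)
    if (length(sizes) == 0L || max(sizes) <= min_size) break
    nm <- names(residual)[order(-sizes, names(residual))][1L]
    selected <- c(selected, nm)
    removed <- residual[[nm]]
    covered <- c(covered, removed)
    residual[[nm]] <- NULL
    residual <- lapply(residual, function(s) setdiff(s, removed))
  }
  list(selected = selected, covered = covered,
       coverage = length(covered) / length(all_genes))
}

#' Rank gene sets by minimum HP fraction across datasets
#'
#' For each set passing the size filter in every dataset, the per-dataset
#' HP fraction is |set intersect HP_d| / |set intersect universe_d|; sets
#' are ranked by the minimum fraction across datasets, descending. Sets
#' absent from a dataset's universe are dropped with a message.
#'
#' @param sets named list of gene sets.
#' @param class_tables named list of pleiotropy tables (one per dataset);
#'   each table's `gene` column is its universe.
#' @param min_set_size strict lower bound on the per-dataset intersected
#'   set size. Default 500.
#' @return data.frame: set, per-dataset `frac_<dataset>` columns,
#'   min_fraction; ordered by min_fraction descending.
#' @export
rank_min_hp_fraction <- function(sets, class_tables, min_set_size = 500L) {
  stopifnot(length(class_tables) >= 2L)
  ds <- names(class_tables)
  rows <- lapply(names(sets), function(nm) {
    fr <- vapply(class_tables, function(tab) {
      inter <- intersect(sets[[nm]], tab$gene)
      if (length(inter) <= min_set_size) return(NA_real_)
      hp <- tab$gene[tab$class == "HP"]
      length(intersect(inter, hp)) / length(inter)
    }, numeric(1))
    if (anyNA(fr)) return(NULL)
    out <- data.frame(set = nm, min_fraction = min(fr))
    out[paste0("frac_", ds)] <- as.list(fr)
    out
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    message(dropped, " sets dropped by the per-dataset size filter")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(data.frame(set = character(0), min_fraction = numeric(0)))
  out <- out[order(-out$min_fraction, out$set),
             c("set", paste0("frac_", ds), "min_fraction")]
  rownames(out) <- NULL
  out
}

#' Venn-region counts of significantly enriched sets across datasets
#'
#' Significance = BH-adjusted p < `alpha` in each dataset's ORA table;
#' counts sets in every membership region.
#'
#' @param rows_per_dataset named list of ORA tables ([ora()]), same
#'   collection in each.
#' @param alpha adjusted-p threshold.
#' @return named integer vector of region counts (as in [venn_counts()]).
#' @export
enriched_term_overlap <- function(rows_per_dataset, alpha = 0.05) {
  tabs <- lapply(rows_per_dataset, function(r) {
    data.frame(gene = r$set, class = ifelse(r$p_adj < alpha, "HP", "NP"))
  })
  venn_counts(tabs, classes = "HP")
}
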