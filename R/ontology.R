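# Upper-level term propagation and the degree of pleiotropy.
#
# A gene's degree of pleiotropy in the Mendelian-trait domain is the number
# of distinct upper-level ontology terms (direct children of the root)
# reachable from its annotations, after removing excluded terms such as the
# mortality/aging term MP:0010768, whose annotation bias would otherwise
# dominate the counts.

#' Upper-level terms of an ontology
#'
#' The upper-level set used as the unit of independent phenotype is the set
#' of direct children of the ontology root.
#'
#' @param dag an `ontology_dag`.
#' @return character vector of term ids.
#' @export
derive_upper_level_set <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  upper <- dag$terms[vapply(dag$is_a, function(p) dag$root %in% p, logical(1))]
  if (length(upper) == 0L) stop("ontology root ", dag$root, " has no children")
  sort(upper)
}

#' Reflexive-transitive ancestors of each term
#'
#' @param dag an `ontology_dag`.
#' @param terms terms to compute ancestors for (default: all).
#' @return named list: term -> character vector of ancestors including the
#'   term itself.
#' @export
term_ancestors <- function(dag, terms = dag$terms) {
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    out <- t
    for (p in dag$is_a[[t]]) out <- c(out, anc(p))
    out <- unique(out)
    memo[[t]] <- out
    out
  }
  lapply(setNames(terms, terms), anc)
}

#' Propagate annotations to upper-level terms
#'
#' Each annotated term is mapped to every upper-level ancestor
#' (reflexive-transitive over `is_a`), or through an explicit upper-level
#' mapping table when one is supplied (the table wins over the DAG).
#' Terms listed in `excluded` are removed after propagation. Annotations to
#' terms unknown to the ontology (and absent from the map) contribute
#' nothing; their count is reported via a message.
#'
#' @param annotations data.frame with `gene` and `term` columns
#'   (as from [read_annotations()]).
#' @param dag an `ontology_dag`.
#' @param upper either a character vector (the upper-level set) or a named
#'   list term -> upper terms (an explicit mapping). Default: derived from
#'   the DAG root's children.
#' @param excluded upper-level terms to drop after propagation. Default
#'   `"MP:0010768"` (mortality/aging).
#' @param translate optional named list translating annotated terms to
#'   another ontology's term ids before propagation (e.g. HPO to MP);
#'   untranslatable terms pass through unchanged.
#' @return named list: gene -> character vector of upper-level terms;
#'   attributes `n_no_upper` (annotations reaching no upper term) and
#'   `upper_set`.
#' @export
propagate_to_upper <- function(annotations, dag,
                               upper = derive_upper_level_set(dag),
                               excluded = "MP:0010768",
                               translate = NULL) {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  terms <- as.character(annotations$term)
  if (!is.null(translate)) {
    hit <- terms %in% names(translate)
    terms[hit] <- vapply(translate[terms[hit]], `[`, character(1), 1L)
  }
  if (is.list(upper)) {
    map <- upper
    upper_set <- sort(unique(unlist(map, use.names = FALSE)))
    # reflexivity: an annotation to an upper-level term counts as itself
    for (u in upper_set) map[[u]] <- unique(c(map[[u]], u))
  } else {
    upper_set <- upper
    known <- unique(terms[terms %in% dag$terms])
    anc <- term_ancestors(dag, known)
    map <- lapply(anc, function(a) a[a %in% upper_set])
  }
  genes <- as.character(annotations$gene)
  uppers_per_record <- map[terms]
  reached <- lengths(uppers_per_record) > 0L
  n_no_upper <- sum(!reached)
  if (n_no_upper > 0L) {
    message(n_no_upper, " annotation records reach no upper-level term")
  }
  ul <- lapply(
    split(uppers_per_record[reached], genes[reached]),
    function(x) setdiff(sort(unique(unlist(x, use.names = FALSE))), excluded)
  )
  # genes all of whose annotations were excluded or unmapped keep an empty set
  missing_genes <- setdiff(unique(genes), names(ul))
  ul[missing_genes] <- list(character(0))
  ul <- ul[order(names(ul))]
  attr(ul, "n_no_upper") <- n_no_upper
  attr(ul, "upper_set") <- setdiff(upper_set, excluded)
  ul
}

#' Degree of pleiotropy from upper-level annotations
#'
#' The degree of pleiotropy of a gene is the size of its upper-level term
#' set. Genes in `universe` without annotations get degree 0 and the
#' placeholder class NP.
#'
#' @param ul named list gene -> upper-level terms, from
#'   [propagate_to_upper()].
#' @param universe optional character vector of all genes under study.
#' @param n_raw optional named integer vector of raw (pre-propagation) term
#'   counts per gene, reported alongside.
#' @param dataset dataset label.
#' @return data.frame `gene`, `degree`, `n_raw_terms`, `class` (all "NP"
#'   placeholder until [classify_pleiotropy()]), with a `dataset` attribute.
#' @export
degree_of_pleiotropy <- function(ul, universe = names(ul), n_raw = NULL,
                                 dataset = "ontology") {
  genes <- sort(unique(c(names(ul), universe)))
  degree <- vapply(genes, function(g) {
    if (is.null(ul[[g]])) 0L else length(ul[[g]])
  }, integer(1))
  raw <- if (is.null(n_raw)) rep(NA_integer_, length(genes)) else {
    out <- n_raw[genes]; out[is.na(out)] <- 0L; as.integer(out)
  }
  res <- data.frame(gene = genes, degree = as.integer(degree),
                    n_raw_terms = raw, class = "NP",
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "dataset") <- dataset
  res
}
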