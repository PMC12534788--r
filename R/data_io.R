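#' @importFrom stats cor cor.test chisq.test cutree fisher.test hclust
#'   median p.adjust phyper pnorm qnorm quantile rbinom rlnorm rnorm
#'   rpois runif sd setNames as.dist wilcox.test
#' @importFrom utils combn head read.delim write.table
NULL

# Coordinate conventions, enforced package-wide:
#   * gene intervals are BED-style 0-based half-open [start, end)
#   * SNP positions are 1-based
# bed_to_point() is the single conversion utility between the two.

#' Convert BED interval bounds to 1-based inclusive point coordinates
#'
#' A BED interval `[start, end)` (0-based half-open) covers the 1-based
#' positions `start + 1 .. end`.
#'
#' @param start,end integer vectors of 0-based half-open interval bounds.
#' @return A list with `first` and `last`, the 1-based inclusive bounds.
#' @export
bed_to_point <- function(start, end) {
  stopifnot(all(start < end))
  list(first = start + 1L, last = as.integer(end))
}

#' Test whether 1-based positions fall inside BED intervals
#'
#' @param pos 1-based positions.
#' @param start,end 0-based half-open interval bounds (recycled).
#' @return logical vector.
#' @export
pos_in_interval <- function(pos, start, end) {
  pos > start & pos <= end
}

#' Read a phenotype ontology from an OBO file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, keeping only the
#' `id`, `name`, `is_a` and `is_obsolete` tags. Obsolete terms are dropped.
#' The result must be a rooted DAG: acyclic, with exactly one term that has
#' no `is_a` parent, reachable from every other term.
#'
#' @param path path to an OBO text file.
#' @return An object of class `ontology_dag`: a list with `terms` (character),
#'   `names` (named character), `is_a` (named list of parent vectors) and
#'   `root` (single term id).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found in ", path)
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
  ids <- character(0); nms <- character(0); parents <- list()
  for (k in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[k]:stanza_ends[k]]
    # stop at the next non-[Term] stanza header if any
    other <- grep("^\\[(?!Term\\])", block, perl = TRUE)
    if (length(other)) block <- block[seq_len(other[1L] - 1L)]
    get_tag <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ":"))]
      sub("\\s*!.*$", "", trimws(substring(v, nchar(tag) + 2L)))
    }
    id <- get_tag("id")
    if (length(id) == 0L) next
    id <- id[1L]
    obs <- get_tag("is_obsolete")
    if (length(obs) && tolower(obs[1L]) == "true") next
    nm <- get_tag("name")
    ids <- c(ids, id)
    nms[id] <- if (length(nm)) nm[1L] else id
    parents[[id]] <- get_tag("is_a")
  }
  if (length(ids) == 0L) stop("no usable terms in ", path)
  new_ontology_dag(ids, nms, parents)
}

#' Construct and validate an ontology DAG
#'
#' @param terms character vector of term ids.
#' @param names named character vector of labels (defaults to ids).
#' @param is_a named list mapping each term to its parent term ids.
#' @return An `ontology_dag` object.
#' @export
new_ontology_dag <- function(terms, names = setNames(terms, terms), is_a = list()) {
  terms <- unique(terms)
  is_a <- lapply(setNames(terms, terms), function(t) {
    p <- is_a[[t]]
    unique(p[p %in% terms & p != t])
  })
  # cycle check via Kahn's algorithm on is_a edges (child -> parent)
  indeg <- vapply(is_a, length, integer(1))  # number of parents still unprocessed
  children <- split(
    rep(names(is_a), lengths(is_a)),
    unlist(is_a, use.names = FALSE)
  )
  # process terms whose parents are all done: peel from the root downwards
  done <- character(0)
  queue <- terms[indeg == 0L]
  remaining <- indeg
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    done <- c(done, t)
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(done) < length(terms)) {
    cyc <- setdiff(terms, done)
    stop("ontology is_a edges contain a cycle involving term ", cyc[1L])
  }
  roots <- terms[vapply(is_a, length, integer(1)) == 0L]
  if (length(roots) == 0L) stop("ontology has no root term")
  if (length(roots) > 1L) {
    stop("ontology has ", length(roots), " parentless terms (",
         paste(head(roots, 3L), collapse = ", "), " ...); a single root is required")
  }
  structure(
    list(terms = terms, names = names[terms], is_a = is_a, root = roots),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag> ", length(x$terms), " terms, root ", x$root,
      " (", sum(lengths(x$is_a)), " is_a edges)\n", sep = "")
  invisible(x)
}

#' Read a gene-to-term annotation table
#'
#' Expects a TSV with (at least) a gene and a term column. Duplicate
#' (gene, term) pairs are collapsed; records whose term is unknown to the
#' ontology are retained but flagged, and their count is reported via a
#' message (such terms contribute nothing to upper-level propagation).
#'
#' @param path path to a TSV file (a `#`-comment header is tolerated).
#' @param ontology an `ontology_dag`, used to flag unknown terms.
#' @param gene_col,term_col column names holding gene and term ids.
#' @param dataset dataset label stored on the result.
#' @return A data.frame with columns `gene`, `term`, `known` plus a
#'   `dataset` attribute.
#' @export
read_annotations <- function(path, ontology, gene_col = "gene",
                             term_col = "term", dataset = "annotations") {
  df <- read_tsv(path)
  if (nrow(df) == 0L) stop("annotation file ", path, " is empty")
  if (!all(c(gene_col, term_col) %in% names(df))) {
    stop("annotation file lacks columns ", gene_col, "/", term_col)
  }
  ann <- data.frame(gene = as.character(df[[gene_col]]),
                    term = as.character(df[[term_col]]),
                    stringsAsFactors = FALSE)
  bad <- !nzchar(ann$gene) | !nzchar(ann$term) | is.na(ann$gene) | is.na(ann$term)
  if (all(bad)) stop("all annotation rows are malformed in ", path)
  if (any(bad)) {
    warning(sum(bad), " malformed annotation rows skipped")
    ann <- ann[!bad, , drop = FALSE]
  }
  ann <- unique(ann)
  ann$known <- ann$term %in% ontology$terms
  n_unknown <- sum(!ann$known)
  if (n_unknown > 0L) {
    message(n_unknown, " annotation records refer to terms unknown to the ontology")
  }
  attr(ann, "dataset") <- dataset
  ann[order(ann$gene, ann$term), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Empty sets are an error; duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @param label collection label stored as an attribute.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path, label = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  attr(sets, "label") <- label
  sets
}

#' Read a per-SNP score track (iHS, DRC150 or phastCons)
#'
#' Accepts a TSV with columns `chrom`, `pos` (1-based), `score`, or a
#' bedGraph (chrom, start, end, value; 0-based half-open) whose intervals
#' are collapsed to their midpoint position. Rows are sorted by
#' (chrom, pos) on load; non-finite scores are an error.
#'
#' @param path path to the track file.
#' @param statistic one of `"iHS"`, `"DRC150"`, `"phastCons"`.
#' @param format `"tsv"` or `"bedgraph"`.
#' @return A data.frame `chrom`, `pos`, `score` with a `statistic` attribute.
#' @export
read_track <- function(path, statistic = c("iHS", "DRC150", "phastCons"),
                       format = c("tsv", "bedgraph")) {
  statistic <- match.arg(statistic)
  format <- match.arg(format)
  if (format == "bedgraph") {
    df <- read_tsv(path, header = FALSE)
    if (ncol(df) < 4L) stop("bedGraph needs 4 columns in ", path)
    names(df)[1:4] <- c("chrom", "start", "end", "score")
    if (!is.numeric(df$start) || !is.numeric(df$end)) {
      stop("coordinate parse failure in ", path)
    }
    pt <- bed_to_point(df$start, df$end)
    track <- data.frame(chrom = as.character(df$chrom),
                        pos = as.integer(floor((pt$first + pt$last) / 2)),
                        score = as.numeric(df$score))
  } else {
    df <- read_tsv(path)
    need <- c("chrom", "pos", "score")
    if (!all(need %in% names(df))) stop("track TSV needs columns chrom/pos/score")
    track <- data.frame(chrom = as.character(df$chrom),
                        pos = as.integer(df$pos),
                        score = as.numeric(df$score))
  }
  if (anyNA(track$pos)) {
    stop("coordinate parse failure in ", path, " at line ",
         which(is.na(track$pos))[1L])
  }
  if (any(!is.finite(track$score))) stop("non-finite scores in ", path)
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  rownames(track) <- NULL
  attr(track, "statistic") <- statistic
  track
}

#' Read gene intervals from a BED3+ file
#'
#' BED is 0-based half-open. Column 4, when present, is the gene id;
#' column 6 the strand. One canonical interval per gene is enforced.
#'
#' @param path path to a BED file (no header).
#' @return data.frame `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_intervals <- function(path) {
  df <- read_tsv(path, header = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns in ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (anyNA(suppressWarnings(as.integer(df$start))) ||
      anyNA(suppressWarnings(as.integer(df$end)))) {
    stop("coordinate parse failure in ", path)
  }
  out <- data.frame(
    gene = if (ncol(df) >= 4L) as.character(df[[4L]]) else paste0("iv", seq_len(nrow(df))),
    chrom = as.character(df$chrom),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "+",
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("interval with start >= end in ", path)
  if (anyDuplicated(out$gene)) stop("duplicate gene intervals in ", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read GWAS summary statistics for one trait
#'
#' @param path TSV with columns for variant, chromosome, 1-based position,
#'   beta, se and p (names configurable via `cols`).
#' @param trait trait identifier attached to the result.
#' @param cols named character vector mapping the canonical names
#'   `variant`, `chrom`, `pos`, `beta`, `se`, `p` to file columns.
#' @return data.frame with the canonical columns and a `trait` column.
#' @export
read_sumstats <- function(path, trait,
                          cols = c(variant = "variant", chrom = "chrom",
                                   pos = "pos", beta = "beta", se = "se", p = "p")) {
  df <- read_tsv(path)
  if (!all(cols %in% names(df))) {
    stop("summary statistics file lacks columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  }
  out <- data.frame(trait = trait,
                    variant = as.character(df[[cols[["variant"]]]]),
                    chrom = as.character(df[[cols[["chrom"]]]]),
                    pos = as.integer(df[[cols[["pos"]]]]),
                    beta = as.numeric(df[[cols[["beta"]]]]),
                    se = as.numeric(df[[cols[["se"]]]]),
                    p = as.numeric(df[[cols[["p"]]]]),
                    stringsAsFactors = FALSE)
  if (any(out$se <= 0, na.rm = TRUE)) stop("non-positive standard errors in ", path)
  if (any(out$p <= 0 | out$p > 1, na.rm = TRUE)) stop("p-values outside (0, 1] in ", path)
  out
}

#' Read a trait manifest
#'
#' @param path TSV with columns `trait`, `z_h2` (heritability z-score) and
#'   optionally `trait_type` and `h2` (point estimate, used to break
#'   duplicate encodings).
#' @return data.frame `trait`, `z_h2`, `trait_type`, `h2`.
#' @export
read_manifest <- function(path) {
  df <- read_tsv(path)
  if (!all(c("trait", "z_h2") %in% names(df))) {
    stop("manifest needs columns trait and z_h2")
  }
  data.frame(trait = as.character(df$trait),
             z_h2 = as.numeric(df$z_h2),
             trait_type = if ("trait_type" %in% names(df)) as.character(df$trait_type) else "continuous",
             h2 = if ("h2" %in% names(df)) as.numeric(df$h2) else as.numeric(df$z_h2),
             stringsAsFactors = FALSE)
}

#' Read a gene feature table
#'
#' Free-schema TSV keyed by a `gene` column; all other columns are features.
#' Missing values must be encoded as NA.
#'
#' @param path TSV path.
#' @return data.frame with `gene` first.
#' @export
read_features <- function(path) {
  df <- read_tsv(path)
  if (!"gene" %in% names(df)) stop("feature table needs a gene column")
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene)) stop("duplicate genes in feature table")
  df
}

#' Read an ortholog pair table
#'
#' @param path TSV with columns `human` and `mouse`.
#' @param one_to_one if TRUE, restrict to pairs where both genes appear
#'   exactly once.
#' @return data.frame `human`, `mouse`.
#' @export
read_orthologs <- function(path, one_to_one = TRUE) {
  df <- read_tsv(path)
  if (!all(c("human", "mouse") %in% names(df))) {
    stop("ortholog table needs columns human and mouse")
  }
  out <- unique(data.frame(human = as.character(df$human),
                           mouse = as.character(df$mouse),
                           stringsAsFactors = FALSE))
  if (one_to_one) {
    out <- out[!(out$human %in% out$human[duplicated(out$human)]) &
               !(out$mouse %in% out$mouse[duplicated(out$mouse)]), , drop = FALSE]
  }
  out
}

#' Read an upper-level term mapping table
#'
#' @param path TSV with columns `term` and `upper` (one row per pair).
#' @return named list: term -> character vector of upper-level terms.
#' @export
read_upper_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("term", "upper") %in% names(df))) {
    stop("upper-level map needs columns term and upper")
  }
  split(as.character(df$upper), as.character(df$term))
}

#' Write a TSV with a provenance header
#'
#' All pipeline outputs are TSVs with a header row preceded by a
#' `# pleioscope` comment line recording the writing function.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param what short description placed on the provenance line.
#' @export
write_tsv <- function(df, path, what = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pleioscope ", what), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared TSV reader: data.table::fread, tolerating "#" comment lines.
read_tsv <- function(path, header = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(data.frame())
  data.table::fread(text = lines, sep = "\t", header = header,
                    data.table = FALSE)
}
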