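# Gene-level aggregation of per-SNP selection statistics.
#
# For each gene (or 100 kb locus around a lead SNP) the maximum absolute
# score x over the n SNPs in the interval is retrieved; significance of a
# maximum iHS uses p(x|n) = 1 - Phi(x)^n, treating each SNP's iHS as
# standard normal. Hard cutoffs (|iHS| > 4, DRC150 > 0.0025) and a
# length-matched resampling enrichment test complement the analytic p.

#' Per-gene SNP count and maximum absolute score
#'
#' In `gene` mode the gene body interval is used; in `locus` mode a
#' `flank_bp` window around each gene's lead SNP position (column
#' `lead_pos` of `intervals`) is used instead.
#'
#' @param track sorted score track ([read_track()]).
#' @param intervals gene intervals; `locus` mode additionally needs a
#'   `lead_pos` column.
#' @param mode `"gene"` or `"locus"`.
#' @param flank_bp locus half-window. Default 100000.
#' @return data.frame `gene`, `n`, `x` (NA when n = 0).
#' @export
gene_max_score <- function(track, intervals, mode = c("gene", "locus"),
                           flank_bp = 100000L) {
  mode <- match.arg(mode)
  if (mode == "locus" && !"lead_pos" %in% names(intervals)) {
    stop("locus mode needs a lead_pos column")
  }
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    tr <- track[track$chrom == intervals$chrom[i], , drop = FALSE]
    inside <- if (mode == "gene") {
      pos_in_interval(tr$pos, intervals$start[i], intervals$end[i])
    } else {
      abs(tr$pos - intervals$lead_pos[i]) <= flank_bp
    }
    n <- sum(inside)
    data.frame(gene = intervals$gene[i], n = n,
               x = if (n > 0L) max(abs(tr$score[inside])) else NA_real_)
  })
  do.call(rbind, out)
}

#' Significance of a gene-wise maximum iHS
#'
#' p(x|n) = 1 - Phi(x)^n, the probability that the maximum of n iid
#' standard normal scores exceeds x. Computed in log space
#' (`-expm1(n * log Phi(x))`) for numerical stability at large n. With
#' `folded = TRUE` the folded-normal CDF `2 Phi(x) - 1` replaces `Phi(x)`,
#' the stricter variant appropriate when x is a maximum of absolute values.
#'
#' @param x observed maximum (absolute) iHS; finite.
#' @param n number of SNPs in the interval; positive integer.
#' @param folded use the folded-normal CDF. Default FALSE.
#' @return p in (0, 1). Vectorized over `x` and `n`.
#' @export
max_ihs_pvalue <- function(x, n, folded = FALSE) {
  if (any(!is.finite(x))) stop("non-finite x")
  if (any(n < 1L)) stop("n must be a positive integer")
  log_cdf <- if (folded) {
    log(pmax(2 * pnorm(x) - 1, .Machine$double.xmin))
  } else {
    pnorm(x, log.p = TRUE)
  }
  -expm1(n * log_cdf)
}

#' Flag genes with significant maximum iHS
#'
#' BH adjustment across all genes with at least one SNP (genes with n = 0
#' carry no evidence and are excluded from the family, their count
#' reported); flag = adjusted p < `alpha`. When a pleiotropy table is
#' given, class-wise flagged proportions with Wilson intervals are added.
#'
#' @param stats data.frame from [gene_max_score()].
#' @param alpha adjusted-p threshold. Default 0.01.
#' @param classes optional pleiotropy table.
#' @param folded passed to [max_ihs_pvalue()].
#' @return list `genes` (gene, n, x, p, p_adj, flag) and, when classes are
#'   given, `by_class` proportions.
#' @export
flag_significant <- function(stats, alpha = 0.01, classes = NULL,
                             folded = FALSE) {
  has <- !is.na(stats$x) & stats$n >= 1L
  if (any(!has)) message(sum(!has), " genes without SNPs excluded from BH family")
  res <- stats
  res$p <- NA_real_; res$p_adj <- NA_real_; res$flag <- NA
  res$p[has] <- max_ihs_pvalue(stats$x[has], stats$n[has], folded = folded)
  res$p_adj[has] <- p.adjust(res$p[has], method = "BH")
  res$flag[has] <- res$p_adj[has] < alpha
  out <- list(genes = res)
  if (!is.null(classes)) out$by_class <- class_proportions(res$flag, res$gene, classes)
  out
}

class_proportions <- function(flag, genes, classes) {
  flag <- setNames(flag, genes)
  cls <- setNames(classes$class, classes$gene)
  do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    f <- flag[names(cls)[cls == cl]]
    f <- f[!is.na(f)]
    if (length(f) == 0L) return(NULL)
    ci <- wilson_ci(sum(f), length(f))
    data.frame(class = cl, n = length(f), x = sum(f),
               prop = ci$p_hat, lower = ci$lower, upper = ci$upper)
  }))
}

#' Hard iHS cutoff flag
#'
#' flag = x > cutoff, strict; genes with missing x get FALSE (their count
#' is reported).
#'
#' @param stats data.frame from [gene_max_score()].
#' @param cutoff strict threshold on the maximum |iHS|. Default 4.
#' @return logical vector named by gene.
#' @export
flag_hard_cutoff <- function(stats, cutoff = 4) {
  miss <- is.na(stats$x)
  if (any(miss)) message(sum(miss), " genes without SNPs set to FALSE")
  out <- !miss & stats$x > cutoff
  setNames(out, stats$gene)
}

#' Hard DRC150 cutoff flag
#'
#' flag = max DRC150 > cutoff (strict).
#'
#' @param stats data.frame from [gene_max_score()] on a DRC150 track.
#' @param cutoff strict threshold. Default 0.0025.
#' @return logical vector named by gene.
#' @export
flag_drc <- function(stats, cutoff = 0.0025) {
  flag_hard_cutoff(stats, cutoff = cutoff)
}

#' Length-matched resampling enrichment of selection flags
#'
#' Compares the flagged proportion in a target gene set with draws of
#' random gene sets matched to the target's gene-length distribution:
#' the universe is binned into `n_bins` length quantiles and each draw
#' samples, per bin without replacement, as many genes as the target has
#' there. Empirical p = (1 + #\{null >= observed\}) / (1 + n_draws).
#'
#' @param flags named logical vector gene -> flag.
#' @param target target gene set (subset of universe).
#' @param universe gene universe.
#' @param lengths named numeric vector gene -> interval length (bp).
#' @param n_draws number of random draws. Default 1000.
#' @param n_bins number of length-quantile bins. Default 10.
#' @param seed RNG seed.
#' @return list `observed`, `null` (length `n_draws`), `p`.
#' @export
length_matched_enrichment <- function(flags, target, universe, lengths,
                                      n_draws = 1000L, n_bins = 10L, seed = 1L) {
  universe <- universe[universe %in% names(lengths)]
  target <- intersect(target, universe)
  stopifnot(length(target) > 0L)
  br <- unique(quantile(lengths[universe], probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(lengths[universe], breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- universe
  tgt_hist <- table(bin[target])
  by_bin <- split(universe, bin)
  for (b in names(tgt_hist)) {
    if (tgt_hist[[b]] > length(by_bin[[b]])) {
      stop("length bin ", b, " has more target than universe genes")
    }
  }
  prop <- function(g) { f <- flags[g]; mean(f[!is.na(f)]) }
  observed <- prop(target)
  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(i) {
    draw <- unlist(lapply(names(tgt_hist), function(b) {
      sample(by_bin[[b]], tgt_hist[[b]], replace = FALSE)
    }), use.names = FALSE)
    prop(draw)
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_draws))
}

#' Combined negative + positive selection flag
#'
#' flag = (LOEUF < `loeuf_cut`, strict) AND (BH-adjusted max-iHS p <
#' `alpha`). A DRC150 variant substitutes the hard DRC cutoff for the iHS
#' condition. Genes with missing LOEUF are excluded (their count reported).
#'
#' @param stats data.frame from [gene_max_score()] (iHS track).
#' @param loeuf named numeric vector gene -> LOEUF.
#' @param loeuf_cut strict LOEUF upper bound. Default 0.6.
#' @param alpha adjusted-p threshold. Default 0.05.
#' @param drc_stats optional DRC150 [gene_max_score()] table; when given,
#'   a `flag_drc_combined` column is added using the DRC cutoff.
#' @param drc_cutoff strict DRC150 threshold. Default 0.0025.
#' @param classes optional pleiotropy table for class-wise proportions.
#' @return list `genes` (gene, loeuf, p_adj, flag[, flag_drc_combined]) and
#'   optional `by_class`.
#' @export
combined_selection_flags <- function(stats, loeuf, loeuf_cut = 0.6,
                                     alpha = 0.05, drc_stats = NULL,
                                     drc_cutoff = 0.0025, classes = NULL) {
  fs <- flag_significant(stats, alpha = alpha)$genes
  lo <- loeuf[fs$gene]
  miss <- is.na(lo)
  if (any(miss)) message(sum(miss), " genes without LOEUF excluded")
  res <- data.frame(gene = fs$gene, loeuf = unname(lo), p_adj = fs$p_adj)
  res$flag <- !miss & !is.na(fs$p_adj) & lo < loeuf_cut & fs$p_adj < alpha
  res$flag[miss] <- NA
  if (!is.null(drc_stats)) {
    drc <- flag_drc(drc_stats, cutoff = drc_cutoff)[fs$gene]
    res$flag_drc_combined <- !miss & !is.na(drc) & lo < loeuf_cut & drc
    res$flag_drc_combined[miss] <- NA
  }
  out <- list(genes = res)
  if (!is.null(classes)) out$by_class <- class_proportions(res$flag, res$gene, classes)
  out
}
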