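# Functional gene feature comparisons across pleiotropy classes:
# expression summaries, rank-sum tests with BH adjustment, proportion
# tests with Wilson intervals, interval-averaged conservation and FUSIL
# phenotype fractions.

#' Per-gene expression summaries across tissues
#'
#' Breadth = number of tissues at or above `tpm_threshold` TPM (the
#' "five or more TPM" rule, boundary inclusive), plus the median and
#' maximum across all tissues.
#'
#' @param expr numeric matrix genes x tissues (TPM, non-negative).
#' @param tpm_threshold TPM at or above which a tissue counts as
#'   expressing. Default 5.
#' @return data.frame `gene`, `breadth`, `median_tpm`, `max_tpm`.
#' @export
expression_summary <- function(expr, tpm_threshold = 5) {
  expr <- as.matrix(expr)
  if (ncol(expr) == 0L) {
    return(data.frame(gene = rownames(expr), breadth = NA_integer_,
                      median_tpm = NA_real_, max_tpm = NA_real_))
  }
  stopifnot(all(expr >= 0, na.rm = TRUE))
  data.frame(
    gene = rownames(expr),
    breadth = as.integer(rowSums(expr >= tpm_threshold, na.rm = TRUE)),
    median_tpm = apply(expr, 1L, median, na.rm = TRUE),
    max_tpm = apply(expr, 1L, max, na.rm = TRUE),
    row.names = NULL
  )
}

#' Wilson score 95% interval for a binomial proportion
#'
#' @param x successes; @param n trials; @param conf confidence level.
#' @return data.frame `p_hat`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(p_hat = p, lower = pmax(0, centre - half),
             upper = pmin(1, centre + half))
}

#' Rank-sum comparisons of numeric features between pleiotropy classes
#'
#' Two-sided Wilcoxon-Mann-Whitney test for every requested (feature,
#' class pair), with Benjamini-Hochberg adjustment across all tests of the
#' invocation (one BH family per call).
#'
#' @param features data.frame with `gene` and numeric feature columns.
#' @param classes pleiotropy table with `gene` and `class`.
#' @param feature_names features to test.
#' @param pairs list of 2-vectors of class labels, e.g.
#'   `list(c("HP","NP"), c("HP","ST"))`.
#' @return data.frame: feature, group1, group2, n1, n2, median1, median2,
#'   statistic, p, p_adj. Degenerate pairs (fewer than 2 non-missing values
#'   in a group) are skipped with a message.
#' @export
compare_numeric <- function(features, classes, feature_names, pairs) {
  cls <- setNames(classes$class, classes$gene)
  rows <- list()
  for (f in feature_names) {
    v <- setNames(features[[f]], features$gene)
    for (pr in pairs) {
      x <- v[names(cls)[cls == pr[1L]]]; x <- x[!is.na(x)]
      y <- v[names(cls)[cls == pr[2L]]]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) {
        message("skipping degenerate comparison ", f, ": ", pr[1L], " vs ", pr[2L])
        next
      }
      wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = pr[1L], group2 = pr[2L],
        n1 = length(x), n2 = length(y),
        median1 = median(x), median2 = median(y),
        statistic = unname(wt$statistic), p = wt$p.value
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable feature/class pairs")
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Proportion comparison between two pleiotropy classes
#'
#' 2x2 chi-squared test (no continuity correction by default) on a per-gene
#' boolean flag, with Wilson 95% intervals per group. Falls back to
#' Fisher's exact test when a table margin is zero.
#'
#' @param flag named logical vector gene -> flag (NA excluded).
#' @param classes pleiotropy table with `gene` and `class`.
#' @param reference,target class labels to compare (target vs reference).
#' @param correct continuity correction for [stats::chisq.test()].
#' @return one-row data.frame with counts, proportions, Wilson bounds and p.
#' @export
compare_proportion <- function(flag, classes, reference, target,
                               correct = FALSE) {
  cls <- setNames(classes$class, classes$gene)
  groups <- lapply(c(target = target, reference = reference), function(cl) {
    f <- flag[names(cls)[cls == cl]]
    f[!is.na(f)]
  })
  n <- vapply(groups, length, integer(1))
  if (any(n == 0L)) stop("empty class group in proportion comparison")
  x <- vapply(groups, sum, numeric(1))
  tab <- rbind(x, n - x)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("zero-margin table; using Fisher's exact test")
    p <- fisher.test(tab)$p.value
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = correct))$p.value
  }
  ci <- wilson_ci(x, n)
  data.frame(
    target = target, reference = reference,
    x_target = x[["target"]], n_target = n[["target"]],
    x_ref = x[["reference"]], n_ref = n[["reference"]],
    prop_target = ci$p_hat[1L], lower_target = ci$lower[1L], upper_target = ci$upper[1L],
    prop_ref = ci$p_hat[2L], lower_ref = ci$lower[2L], upper_ref = ci$upper[2L],
    p = p
  )
}

#' Proportion of LoF-intolerant (pLI > 0.9) genes per pleiotropy class
#'
#' The pLI threshold is strict (exactly 0.9 does not count); genes with
#' missing pLI are excluded.
#'
#' @param features data.frame with `gene` and `pLI`.
#' @param classes pleiotropy table.
#' @return data.frame per class: n, x, proportion and Wilson bounds.
#' @export
pli_proportions <- function(features, classes) {
  pli <- setNames(features$pLI, features$gene)
  flag <- pli > 0.9
  cls <- setNames(classes$class, classes$gene)
  out <- lapply(sort(unique(cls)), function(cl) {
    f <- flag[names(cls)[cls == cl]]
    f <- f[!is.na(f)]
    ci <- wilson_ci(sum(f), length(f))
    data.frame(class = cl, n = length(f), x = sum(f),
               prop = ci$p_hat, lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, out)
}

#' Mean track score over gene intervals
#'
#' Arithmetic mean of per-position scores (e.g. phastCons) at track
#' positions inside each gene's interval; NA when no position falls inside.
#'
#' @param track sorted score track ([read_track()]).
#' @param intervals gene intervals ([read_intervals()]).
#' @return data.frame `gene`, `n_pos`, `mean_score`.
#' @export
interval_mean_score <- function(track, intervals) {
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    tr <- track[track$chrom == intervals$chrom[i], , drop = FALSE]
    inside <- pos_in_interval(tr$pos, intervals$start[i], intervals$end[i])
    data.frame(gene = intervals$gene[i], n_pos = sum(inside),
               mean_score = if (any(inside)) mean(tr$score[inside]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Fraction of genes with any phenotype per FUSIL category
#'
#' For each essentiality category (CL, DL, SV, VP, VN), the fraction of its
#' genes with degree >= 1 in the given pleiotropy table, with Wilson 95%
#' intervals. Unknown categories are excluded with a message.
#'
#' @param classes pleiotropy table with `gene` and `degree`.
#' @param fusil named character vector gene -> FUSIL category.
#' @return data.frame `category`, `n`, `x`, `frac`, `lower`, `upper`.
#' @export
fusil_phenotype_fraction <- function(classes, fusil) {
  valid <- c("CL", "DL", "SV", "VP", "VN")
  bad <- !(fusil %in% valid)
  if (any(bad)) {
    message(sum(bad), " genes with unknown FUSIL category excluded")
    fusil <- fusil[!bad]
  }
  deg <- setNames(classes$degree, classes$gene)
  out <- lapply(intersect(valid, unique(fusil)), function(cat) {
    g <- names(fusil)[fusil == cat]
    d <- deg[g]
    d[is.na(d)] <- 0L  # genes absent from the table have no phenotype
    ci <- wilson_ci(sum(d >= 1L), length(d))
    data.frame(category = cat, n = length(d), x = sum(d >= 1L),
               frac = ci$p_hat, lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, out)
}
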