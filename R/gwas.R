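# From GWAS summary statistics to gene-by-trait-cluster associations:
# trait filtering by heritability z-score, greedy distance-based clumping,
# lead-SNP-to-gene assignment, reconstituted phenotypic correlation and
# hierarchical trait clustering on d = 1 - r_p.

#' Filter traits by heritability z-score
#'
#' Keeps traits whose heritability z-score exceeds `z_threshold`
#' (Z > 2.32 corresponds to P(h2 = 0) < 0.01 under the standard normal).
#' Among duplicate encodings of one trait (rows sharing a base identifier),
#' the entry with the maximum heritability estimate is kept.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param z_threshold strict lower bound on `z_h2`. Default 2.32.
#' @param trait_types trait types retained; default keeps continuous traits
#'   and biomarkers. Use NULL to keep all.
#' @param base_id optional function mapping trait ids to a duplicate-group
#'   key; default strips a trailing `__<encoding>` suffix.
#' @return the filtered manifest.
#' @export
filter_traits <- function(manifest, z_threshold = 2.32,
                          trait_types = c("continuous", "biomarker"),
                          base_id = function(x) sub("__[^_]+$", "", x)) {
  stopifnot(all(c("trait", "z_h2") %in% names(manifest)))
  keep <- manifest$z_h2 > z_threshold
  if (!is.null(trait_types) && "trait_type" %in% names(manifest)) {
    keep <- keep & manifest$trait_type %in% trait_types
  }
  out <- manifest[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no traits pass the heritability filter")
  key <- base_id(out$trait)
  # one entry per duplicate group: maximum heritability estimate wins
  ord <- order(key, -out$h2, out$trait)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(base_id(out$trait)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy distance-window clumping of lead SNPs
#'
#' LD-free surrogate for PLINK clumping: repeatedly take the
#' smallest-p remaining variant with p <= `p_threshold` as a lead and
#' remove all variants within `window_bp` on the same chromosome.
#' Ties in p are broken lexicographically on the variant identifier.
#' An optional per-chromosome LD matrix extends removal to variants with
#' r^2 >= `r2_threshold` with the lead.
#'
#' @param stats summary statistics for one trait ([read_sumstats()]).
#' @param p_threshold genome-wide significance threshold. Default 5e-8.
#' @param window_bp clump half-window in bp. Default 250000.
#' @param ld optional named list `chrom -> r2 matrix` with variant ids as
#'   dimnames; `r2_threshold` then also joins variants to a clump.
#' @param r2_threshold r^2 at or above which a variant joins the lead's
#'   clump. Default 0.1.
#' @return data.frame `trait`, `variant`, `chrom`, `pos`, `p` of lead SNPs
#'   (possibly 0 rows).
#' @export
clump_lead_snps <- function(stats, p_threshold = 5e-8, window_bp = 250000L,
                            ld = NULL, r2_threshold = 0.1) {
  cand <- stats[!is.na(stats$p) & stats$p <= p_threshold, , drop = FALSE]
  empty <- stats[0L, c("trait", "variant", "chrom", "pos", "p"), drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$p, cand$variant), , drop = FALSE]
  leads <- list()
  while (nrow(cand) > 0L) {
    lead <- cand[1L, , drop = FALSE]
    leads[[length(leads) + 1L]] <- lead
    drop <- cand$chrom == lead$chrom & abs(cand$pos - lead$pos) <= window_bp
    if (!is.null(ld) && lead$chrom %in% names(ld)) {
      m <- ld[[lead$chrom]]
      if (lead$variant %in% rownames(m)) {
        r2 <- m[lead$variant, ]
        linked <- names(r2)[r2 >= r2_threshold]
        drop <- drop | (cand$chrom == lead$chrom & cand$variant %in% linked)
      }
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  out <- do.call(rbind, leads)[, c("trait", "variant", "chrom", "pos", "p")]
  rownames(out) <- NULL
  out
}

#' Closest gene for each lead SNP
#'
#' Distance is 0 when the 1-based SNP position lies inside the 0-based
#' half-open gene interval, otherwise `min(|pos - start|, |pos - end|)`.
#' Equidistant genes are resolved to the lexicographically smaller gene id.
#'
#' @param leads data.frame with `chrom` and `pos` columns (one row per lead).
#' @param genes gene intervals ([read_intervals()]).
#' @return `leads` with `gene` and `distance` columns appended; leads on
#'   chromosomes without genes get NA and are counted in a message.
#' @export
closest_gene <- function(leads, genes) {
  gene <- character(nrow(leads)); dist <- numeric(nrow(leads))
  for (i in seq_len(nrow(leads))) {
    g <- genes[genes$chrom == leads$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { gene[i] <- NA_character_; dist[i] <- NA_real_; next }
    p <- leads$pos[i]
    d <- ifelse(pos_in_interval(p, g$start, g$end), 0,
                pmin(abs(p - g$start), abs(p - g$end)))
    best <- which(d == min(d))
    pick <- best[order(g$gene[best])][1L]
    gene[i] <- g$gene[pick]; dist[i] <- d[pick]
  }
  if (anyNA(gene)) {
    message(sum(is.na(gene)), " lead SNPs on chromosomes without genes left unassigned")
  }
  leads$gene <- gene
  leads$distance <- dist
  leads
}

#' All genes within a flank window of each lead SNP
#'
#' Returns every gene whose interval overlaps `[pos - flank_bp, pos + flank_bp]`.
#'
#' @inheritParams closest_gene
#' @param flank_bp half-window in bp. Default 100000.
#' @return list (one element per lead row) of character vectors of gene ids.
#' @export
window_genes <- function(leads, genes, flank_bp = 100000L) {
  lapply(seq_len(nrow(leads)), function(i) {
    g <- genes[genes$chrom == leads$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(character(0))
    lo <- leads$pos[i] - flank_bp; hi <- leads$pos[i] + flank_bp
    # 1-based inclusive gene span is [start+1, end]
    hit <- (g$start + 1L) <= hi & g$end >= lo
    sort(g$gene[hit])
  })
}

#' Reconstituted phenotypic correlation between two traits
#'
#' Pearson correlation of the z-statistics (beta/se) over variants shared by
#' both traits, restricted to null variants with |z| < `null_z_max` in both
#' traits, so that the correlation reflects shared phenotypic (not causal)
#' structure.
#'
#' @param stats_a,stats_b summary statistics for the two traits.
#' @param null_z_max strict upper bound on |z| for a variant to count as
#'   null. Default 4: high enough that truncation of the null z
#'   distribution does not attenuate the correlation estimate (truncating
#'   at 2 biases rho = 0.8 down to about 0.74), while still excluding
#'   genuinely associated variants.
#' @param min_shared minimum number of shared null variants. Default 50.
#' @return list with `r_p` (NA when too few shared variants) and `n_shared`.
#' @export
reconstituted_rp <- function(stats_a, stats_b, null_z_max = 4, min_shared = 50L) {
  za <- setNames(stats_a$beta / stats_a$se, stats_a$variant)
  zb <- setNames(stats_b$beta / stats_b$se, stats_b$variant)
  shared <- intersect(names(za), names(zb))
  za <- za[shared]; zb <- zb[shared]
  ok <- abs(za) < null_z_max & abs(zb) < null_z_max
  if (sum(ok) < min_shared) {
    message("only ", sum(ok), " shared null variants; r_p set to NA")
    return(list(r_p = NA_real_, n_shared = sum(ok)))
  }
  list(r_p = cor(za[ok], zb[ok]), n_shared = sum(ok))
}

#' Pairwise trait distance matrix d = 1 - r_p
#'
#' @param stats_list named list of per-trait summary statistics.
#' @param rp_matrix optional precomputed phenotypic correlation matrix
#'   (traits x traits); when given, summary statistics are not used.
#' @param ... passed to [reconstituted_rp()].
#' @return list with `d` (distance matrix), `r_p` (correlation matrix) and
#'   `n_shared`. Missing r_p values are imputed as 0 (d = 1).
#' @export
trait_distance_matrix <- function(stats_list = NULL, rp_matrix = NULL, ...) {
  if (!is.null(rp_matrix)) {
    stopifnot(isSymmetric(unname(rp_matrix)))
    rp <- rp_matrix
    n <- matrix(NA_integer_, nrow(rp), ncol(rp), dimnames = dimnames(rp))
  } else {
    traits <- names(stats_list)
    k <- length(traits)
    rp <- matrix(1, k, k, dimnames = list(traits, traits))
    n <- matrix(0L, k, k, dimnames = list(traits, traits))
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
        est <- reconstituted_rp(stats_list[[i]], stats_list[[j]], ...)
        rp[i, j] <- rp[j, i] <- est$r_p
        n[i, j] <- n[j, i] <- est$n_shared
      }
    }
  }
  rp_filled <- rp
  rp_filled[is.na(rp_filled)] <- 0
  d <- 1 - rp_filled
  diag(d) <- 0
  list(d = d, r_p = rp, n_shared = n)
}

#' Hierarchical trait clustering on the distance matrix
#'
#' Agglomerative clustering of traits (average linkage by default) with the
#' dendrogram cut at `cut_height` on the d = 1 - r_p scale.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param linkage linkage method for [stats::hclust()]. Default "average".
#' @param cut_height tree cut height. Default 0.8.
#' @return named integer vector: trait -> cluster id.
#' @export
cluster_traits <- function(d, linkage = "average", cut_height = 0.8) {
  if (!isSymmetric(unname(as.matrix(d)))) stop("distance matrix must be symmetric")
  d <- as.matrix(d)
  if (nrow(d) == 1L) return(setNames(1L, rownames(d)))
  hc <- hclust(as.dist(d), method = linkage)
  cutree(hc, h = cut_height)
}

#' Gene-by-trait-cluster incidence matrix
#'
#' A gene is associated with a cluster if it is the assigned gene for a lead
#' SNP in at least one trait of the cluster. Row sums of the binary matrix
#' are the GWAS degree of pleiotropy.
#'
#' @param assignments data.frame with `trait` and `gene` columns (one row
#'   per lead SNP, as from [closest_gene()]; NA genes dropped).
#' @param clusters named vector trait -> cluster id ([cluster_traits()]).
#' @param dataset dataset label.
#' @return binary matrix genes x clusters with a `dataset` attribute.
#' @export
gene_cluster_matrix <- function(assignments, clusters, dataset = "gwas") {
  a <- assignments[!is.na(assignments$gene), , drop = FALSE]
  missing <- setdiff(unique(a$trait), names(clusters))
  if (length(missing)) {
    stop("traits without cluster assignment: ", paste(head(missing, 3L), collapse = ", "))
  }
  genes <- sort(unique(a$gene))
  cl_ids <- sort(unique(clusters))
  m <- matrix(0L, length(genes), length(cl_ids),
              dimnames = list(genes, paste0("cluster", cl_ids)))
  if (nrow(a)) {
    ci <- match(clusters[a$trait], cl_ids)
    gi <- match(a$gene, genes)
    m[cbind(gi, ci)] <- 1L
  }
  attr(m, "dataset") <- dataset
  m
}

#' GWAS degree of pleiotropy from a gene-by-cluster matrix
#'
#' @param m binary matrix from [gene_cluster_matrix()].
#' @param universe optional gene universe; genes absent from `m` get 0.
#' @param dataset dataset label.
#' @return data.frame as from [degree_of_pleiotropy()].
#' @export
gwas_degree <- function(m, universe = rownames(m),
                        dataset = attr(m, "dataset") %||% "gwas") {
  ul <- apply(m, 1L, function(r) colnames(m)[r > 0L], simplify = FALSE)
  degree_of_pleiotropy(ul, universe = universe, dataset = dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
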