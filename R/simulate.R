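# Synthetic data with planted structure for every pipeline stage.
#
# The generator emulates the statistical shape of the real inputs: an
# L-shaped (discrete power-law) degree-of-pleiotropy distribution, a
# block-modular gene-by-trait network, block-correlated trait z-scores,
# planted selective sweeps in the iHS/DRC150 tracks, and functional
# features that increase (or, for LOEUF, decrease) with planted degree.
# All generators are deterministic under cfg$seed; stage k uses
# cfg$seed + k so stages are independently reproducible.

#' Simulation configuration
#'
#' @param seed master RNG seed (integer; stage generators use small fixed
#'   offsets from it).
#' @param n_genes number of genes G. Default 1000.
#' @param n_traits number of GWAS traits T. Default 24.
#' @param n_upper upper-level ontology terms U. Default 12.
#' @param n_leaves leaf ontology terms L. Default 60.
#' @param n_snps shared null GWAS variants per trait. Default 10000.
#' @param n_tissues expression tissues K. Default 10.
#' @param exponent discrete power-law exponent of the planted
#'   degree-of-pleiotropy distribution. Default 2.5.
#' @param np_fraction fraction of genes with no annotation (degree 0).
#'   Default 0.3.
#' @param n_blocks trait-correlation blocks B. Default 4.
#' @param rho_within,rho_between planted trait z-score correlations within
#'   and between blocks. Defaults 0.8 and 0.1.
#' @param causal_per_block causal genes planted per trait block. Default 8.
#' @param n_domains trait blocks are grouped into this many domains with
#'   disjoint causal-gene pools; blocks of one domain draw from a shared
#'   pool, so genes can be causal for several clusters within a domain but
#'   never across domains. This skews the GWAS cluster-degree distribution
#'   (most causal genes hit one cluster) and plants modular structure in
#'   the gene-by-cluster network. Default 2.
#' @param pool_factor per-domain pool size as a fraction of
#'   `blocks_in_domain * causal_per_block`; values below 1 create
#'   within-domain overlap. Default 0.75.
#' @param p_in,p_out edge probabilities of the planted block-modular
#'   bipartite network. Defaults 0.9 and 0.02.
#' @param sweep_fraction fraction of genes carrying a planted sweep.
#'   Default 0.05.
#' @param delta |iHS| shift added at sweep-gene SNPs. Default 3.
#' @param feature_slope slope of feature means in log(1 + degree).
#'   Default 1.5.
#' @param feature_sd noise sd of simulated features. Default 1.
#' @param n_chrom,gene_length,gap_length genome layout: chromosome count
#'   and uniform ranges (bp) for gene lengths and intergenic gaps.
#' @param track_spacing mean spacing (bp) between selection-track SNPs.
#'   Default 500.
#' @param diamond_fraction fraction of ontology leaves with two upper-level
#'   parents. Default 0.3.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_traits = 24L,
                       n_upper = 12L, n_leaves = 60L, n_snps = 10000L,
                       n_tissues = 10L, exponent = 2.5, np_fraction = 0.3,
                       n_blocks = 4L, rho_within = 0.8, rho_between = 0.1,
                       causal_per_block = 8L, n_domains = 2L,
                       pool_factor = 0.75, p_in = 0.9, p_out = 0.02,
                       sweep_fraction = 0.05, delta = 3,
                       feature_slope = 1.5, feature_sd = 1,
                       n_chrom = 2L, gene_length = c(2000L, 10000L),
                       gap_length = c(2000L, 10000L), track_spacing = 500,
                       diamond_fraction = 0.3) {
  stopifnot(n_upper >= 2L, n_leaves >= n_upper,
            rho_within >= rho_between, rho_between >= 0, rho_within <= 1,
            p_in > p_out, np_fraction >= 0, np_fraction < 1,
            n_traits %% n_blocks == 0L)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Lay out a toy genome of non-overlapping genes
#'
#' Genes are placed sequentially with uniform lengths and intergenic gaps,
#' split evenly across chromosomes.
#'
#' @param cfg a [sim_config()].
#' @return gene interval data.frame (`gene`, `chrom`, `start`, `end`,
#'   `strand`); BED convention (0-based half-open).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed + 1L)
  G <- cfg$n_genes
  len <- sample(cfg$gene_length[1L]:cfg$gene_length[2L], G, replace = TRUE)
  gap <- sample(cfg$gap_length[1L]:cfg$gap_length[2L], G, replace = TRUE)
  chrom_of <- rep(seq_len(cfg$n_chrom), length.out = G)
  chrom_of <- sort(chrom_of)
  start <- integer(G); pos <- integer(cfg$n_chrom)
  for (i in seq_len(G)) {
    c_i <- chrom_of[i]
    start[i] <- pos[c_i] + gap[i]
    pos[c_i] <- start[i] + len[i]
  }
  data.frame(
    gene = sprintf("gene%04d", seq_len(G)),
    chrom = paste0("chr", chrom_of),
    start = start, end = start + len, strand = "+",
    stringsAsFactors = FALSE
  )
}

#' Simulate a three-level phenotype ontology
#'
#' Root, `n_upper` upper-level terms, and `n_leaves` leaves each with one
#' or (for a `diamond_fraction` of leaves) two upper-level parents.
#'
#' @param cfg a [sim_config()].
#' @return list `dag` (an `ontology_dag`) and `upper_map` (term -> upper
#'   terms, as an explicit mapping table).
#' @export
simulate_ontology <- function(cfg) {
  set.seed(cfg$seed + 2L)
  root <- "SP:0000000"
  upper <- sprintf("SP:%07d", seq_len(cfg$n_upper))
  leaves <- sprintf("SP:%07d", 1000L + seq_len(cfg$n_leaves))
  is_a <- c(
    setNames(lapply(upper, function(u) root), upper),
    setNames(lapply(seq_len(cfg$n_leaves), function(i) {
      k <- if (runif(1) < cfg$diamond_fraction) 2L else 1L
      sample(upper, k)
    }), leaves)
  )
  # guarantee every upper term owns at least one single-parent leaf
  for (j in seq_len(cfg$n_upper)) is_a[[leaves[j]]] <- upper[j]
  dag <- new_ontology_dag(c(root, upper, leaves), is_a = is_a)
  anc <- term_ancestors(dag)
  upper_map <- lapply(anc, function(a) a[a %in% upper])
  upper_map <- upper_map[lengths(upper_map) > 0L]
  list(dag = dag, upper_map = upper_map, upper = upper)
}

# Truncated discrete power law on 1..kmax: P(k) proportional to k^(-alpha).
rpowerlaw <- function(n, alpha, kmax) {
  p <- (1:kmax)^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

#' Simulate gene-to-term annotations with planted degrees
#'
#' Each annotated gene gets a target upper-level degree drawn from a
#' truncated discrete power law; the target is realized exactly by
#' annotating the gene to its chosen upper-level terms directly plus a few
#' leaves whose upper-level ancestors stay inside the chosen set.
#'
#' @param cfg a [sim_config()].
#' @param onto result of [simulate_ontology()].
#' @return list `annotations` (gene, term data.frame), `planted_degree`
#'   (named integer vector over all genes, 0 for NP genes).
#' @export
simulate_annotations <- function(cfg, onto) {
  set.seed(cfg$seed + 3L)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  n_np <- round(cfg$np_fraction * cfg$n_genes)
  annotated <- genes[seq_len(cfg$n_genes) > n_np]
  target <- rpowerlaw(length(annotated), cfg$exponent, cfg$n_upper)
  anc <- term_ancestors(onto$dag)
  leaf_uppers <- lapply(anc, function(a) a[a %in% onto$upper])
  leaves <- setdiff(onto$dag$terms, c(onto$dag$root, onto$upper))
  rows <- vector("list", length(annotated))
  for (i in seq_along(annotated)) {
    k <- target[i]
    chosen <- sample(onto$upper, k)
    terms <- chosen
    # add leaf annotations that do not extend the upper set
    ok_leaves <- leaves[vapply(leaf_uppers[leaves],
                               function(u) all(u %in% chosen), logical(1))]
    if (length(ok_leaves)) {
      n_extra <- sample(0:min(2L, length(ok_leaves)), 1L)
      terms <- c(terms, sample(ok_leaves, n_extra))
    }
    rows[[i]] <- data.frame(gene = annotated[i], term = terms,
                            stringsAsFactors = FALSE)
  }
  planted <- setNames(integer(cfg$n_genes), genes)
  planted[annotated] <- target
  list(annotations = do.call(rbind, rows), planted_degree = planted)
}

#' Simulate GWAS summary statistics with block-correlated traits
#'
#' Null variants share z-scores structured as
#' z = sqrt(rho_b) g + sqrt(rho_w - rho_b) f_block + sqrt(1 - rho_w) e,
#' giving pairwise z correlation `rho_within` inside a block and
#' `rho_between` across blocks. Each block additionally gets
#' `causal_per_block` causal genes; every trait of the block carries one
#' genome-wide-significant lead variant inside each causal gene.
#'
#' @param cfg a [sim_config()].
#' @param genome gene intervals from [simulate_genome()].
#' @return list `stats` (named list of per-trait summary statistics),
#'   `manifest`, `block` (trait -> block), `causal` (block -> gene ids),
#'   `planted_matrix` (binary gene x block incidence over causal genes).
#' @export
simulate_gwas <- function(cfg, genome) {
  set.seed(cfg$seed + 4L)
  B <- cfg$n_blocks; Tt <- cfg$n_traits; S <- cfg$n_snps
  traits <- sprintf("trait%02d", seq_len(Tt))
  block <- setNames(rep(seq_len(B), each = Tt / B), traits)
  chrom_len <- tapply(genome$end, genome$chrom, max)
  snp_chrom <- sample(names(chrom_len), S, replace = TRUE,
                      prob = chrom_len / sum(chrom_len))
  snp_pos <- vapply(snp_chrom, function(ch) sample.int(chrom_len[[ch]], 1L),
                    integer(1))
  variant <- sprintf("rs%06d", seq_len(S))
  g_v <- rnorm(S)
  f_bv <- matrix(rnorm(S * B), S, B)
  se <- 0.1
  # blocks grouped into domains with disjoint causal pools; within-domain
  # pools are undersized so genes recur across a domain's clusters
  domain_of <- ceiling(seq_len(B) / (B / cfg$n_domains))
  pool_sizes <- vapply(seq_len(cfg$n_domains), function(dd) {
    as.integer(max(cfg$causal_per_block,
                   ceiling(cfg$pool_factor * sum(domain_of == dd) *
                           cfg$causal_per_block)))
  }, integer(1))
  all_pool <- sample(genome$gene, min(sum(pool_sizes), nrow(genome)))
  pools <- split(all_pool, rep(seq_len(cfg$n_domains), pool_sizes)[seq_along(all_pool)])
  causal <- lapply(seq_len(B), function(b) {
    p <- pools[[domain_of[b]]]
    sort(sample(p, min(cfg$causal_per_block, length(p))))
  })
  names(causal) <- paste0("block", seq_len(B))
  stats <- list()
  for (t in traits) {
    b <- block[[t]]
    z <- sqrt(cfg$rho_between) * g_v +
      sqrt(cfg$rho_within - cfg$rho_between) * f_bv[, b] +
      sqrt(1 - cfg$rho_within) * rnorm(S)
    df <- data.frame(trait = t, variant = variant, chrom = snp_chrom,
                     pos = snp_pos, beta = z * se, se = se,
                     p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
    cg <- genome[genome$gene %in% causal[[b]], , drop = FALSE]
    zlead <- 12 + abs(rnorm(nrow(cg)))
    lead <- data.frame(
      trait = t,
      variant = paste0("lead_", t, "_", cg$gene),
      chrom = cg$chrom,
      pos = as.integer(floor((cg$start + 1L + cg$end) / 2)),
      beta = zlead * se, se = se, p = 2 * pnorm(-zlead),
      stringsAsFactors = FALSE
    )
    stats[[t]] <- rbind(df, lead)
  }
  manifest <- data.frame(
    trait = traits,
    z_h2 = round(runif(Tt, 3, 12), 2),
    trait_type = "continuous",
    h2 = round(runif(Tt, 0.05, 0.5), 3),
    stringsAsFactors = FALSE
  )
  causal_genes <- sort(unique(unlist(causal, use.names = FALSE)))
  pm <- matrix(0L, length(causal_genes), B,
               dimnames = list(causal_genes, paste0("cluster", seq_len(B))))
  for (b in seq_len(B)) pm[causal[[b]], b] <- 1L
  list(stats = stats, manifest = manifest, block = block,
       causal = causal, planted_matrix = pm)
}

#' Simulate iHS and DRC150 score tracks with planted sweeps
#'
#' Background iHS is standard normal; SNPs inside sweep genes have their
#' absolute value shifted by `delta` (sign preserved). Background DRC150 is
#' small and positive; sweep-gene SNPs exceed the 0.0025 cutoff.
#'
#' @param cfg a [sim_config()].
#' @param genome gene intervals.
#' @param sweep_genes character vector of sweep gene ids; default samples
#'   `sweep_fraction` of genes.
#' @return list `ihs`, `drc` (score tracks), `sweep_genes`.
#' @export
simulate_tracks <- function(cfg, genome, sweep_genes = NULL) {
  set.seed(cfg$seed + 5L)
  if (is.null(sweep_genes)) {
    sweep_genes <- sort(sample(genome$gene,
                               max(1L, round(cfg$sweep_fraction * nrow(genome)))))
  }
  chrom_len <- tapply(genome$end, genome$chrom, max)
  tracks <- lapply(names(chrom_len), function(ch) {
    n <- ceiling(chrom_len[[ch]] / cfg$track_spacing)
    data.frame(chrom = ch, pos = sort(sample.int(chrom_len[[ch]], n)),
               stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, tracks)
  in_sweep <- rep(FALSE, nrow(tr))
  sw <- genome[genome$gene %in% sweep_genes, , drop = FALSE]
  for (i in seq_len(nrow(sw))) {
    in_sweep <- in_sweep | (tr$chrom == sw$chrom[i] &
                            pos_in_interval(tr$pos, sw$start[i], sw$end[i]))
  }
  z <- rnorm(nrow(tr))
  ihs_score <- ifelse(in_sweep, sign(z) * (abs(z) + cfg$delta), z)
  drc_score <- abs(rnorm(nrow(tr), 0, 5e-4))
  if (cfg$delta > 0 && any(in_sweep)) {
    drc_score[in_sweep] <- 0.0025 + abs(rnorm(sum(in_sweep), 0, 2e-3))
  }
  ihs <- data.frame(chrom = tr$chrom, pos = tr$pos, score = ihs_score)
  drc <- data.frame(chrom = tr$chrom, pos = tr$pos, score = drc_score)
  ihs <- ihs[order(ihs$chrom, ihs$pos), ]; rownames(ihs) <- NULL
  drc <- drc[order(drc$chrom, drc$pos), ]; rownames(drc) <- NULL
  attr(ihs, "statistic") <- "iHS"
  attr(drc, "statistic") <- "DRC150"
  list(ihs = ihs, drc = drc, sweep_genes = sweep_genes)
}

#' Simulate functional gene features linked to planted degree
#'
#' Expression breadth, PPI count, GO counts, pHaplo/pTriplo, missense Z and
#' s_het increase with log(1 + degree); LOEUF decreases (and pLI follows
#' LOEUF); FUSIL categories are drawn from a degree-linked multinomial.
#' With `feature_slope = 0` all features are independent of degree.
#'
#' @param cfg a [sim_config()].
#' @param planted_degree named integer vector gene -> planted degree.
#' @return list `features` (data.frame) and `expression` (genes x tissues
#'   TPM matrix).
#' @export
simulate_features <- function(cfg, planted_degree) {
  set.seed(cfg$seed + 6L)
  genes <- names(planted_degree)
  G <- length(genes); K <- cfg$n_tissues
  ld <- log1p(planted_degree)
  s <- cfg$feature_slope; sdv <- cfg$feature_sd
  breadth <- pmin(K, pmax(0L, round(2 + s * ld + rnorm(G, 0, sdv))))
  expr <- matrix(runif(G * K, 0, 4.9), G, K,
                 dimnames = list(genes, paste0("tissue", seq_len(K))))
  for (i in seq_len(G)) {
    if (breadth[i] > 0L) {
      on <- sample.int(K, breadth[i])
      expr[i, on] <- 5 + rlnorm(breadth[i], meanlog = 2, sdlog = 1)
    }
  }
  loeuf <- pmin(2, pmax(0.03, 1.2 - 0.2 * s * ld + rnorm(G, 0, 0.15 * sdv + 0.05)))
  fusil_p <- function(d) {
    w <- c(CL = 0.05 + 0.03 * d, DL = 0.1 + 0.05 * d, SV = 0.15 + 0.02 * d,
           VP = 0.4, VN = pmax(0.05, 0.3 - 0.05 * d))
    w / sum(w)
  }
  fusil <- vapply(ld, function(d) {
    sample(c("CL", "DL", "SV", "VP", "VN"), 1L, prob = fusil_p(d))
  }, character(1))
  features <- data.frame(
    gene = genes,
    ppi_count = rpois(G, lambda = exp(1 + 0.4 * s * ld)),
    go_bp_count = rpois(G, lambda = exp(1.2 + 0.3 * s * ld)),
    go_mf_count = rpois(G, lambda = exp(0.8 + 0.2 * s * ld)),
    pHaplo = plogis(-1 + 0.6 * s * ld + rnorm(G, 0, sdv)),
    pTriplo = plogis(-1.2 + 0.5 * s * ld + rnorm(G, 0, sdv)),
    LOEUF = loeuf,
    pLI = plogis(12 * (0.72 - loeuf)),
    missense_z = 0.5 * s * ld + rnorm(G, 0, sdv),
    s_het = plogis(-3 + 0.5 * s * ld + rnorm(G, 0, sdv)) / 2,
    fusil = fusil,
    stringsAsFactors = FALSE
  )
  rownames(features) <- NULL
  list(features = features, expression = expr)
}

#' Simulate a planted block-modular bipartite incidence matrix
#'
#' Genes and traits are split evenly into `n_blocks` aligned blocks; an
#' edge appears with probability `p_in` inside a gene's own block and
#' `p_out` elsewhere.
#'
#' @param n_genes,n_traits node counts (multiples of `n_blocks`).
#' @param n_blocks number of planted blocks.
#' @param p_in,p_out within/between-block edge probabilities.
#' @param seed RNG seed.
#' @return list `matrix` (binary incidence), `gene_block`, `trait_block`.
#' @export
simulate_block_matrix <- function(n_genes = 20L, n_traits = 20L, n_blocks = 2L,
                                  p_in = 0.9, p_out = 0.02, seed = 1L) {
  stopifnot(n_genes %% n_blocks == 0L, n_traits %% n_blocks == 0L, p_in > p_out)
  set.seed(seed)
  gb <- rep(seq_len(n_blocks), each = n_genes / n_blocks)
  tb <- rep(seq_len(n_blocks), each = n_traits / n_blocks)
  pmat <- matrix(p_out, n_genes, n_traits)
  pmat[outer(gb, tb, "==")] <- p_in
  m <- matrix(rbinom(n_genes * n_traits, 1L, pmat), n_genes, n_traits,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("t%03d", seq_len(n_traits))))
  list(matrix = m, gene_block = gb, trait_block = tb)
}

#' Simulate a GMT gene-set collection
#'
#' Random sets over the gene universe plus a few sets enriched in
#' high-degree genes, so over-representation of HP genes has signal.
#'
#' @param cfg a [sim_config()].
#' @param planted_degree named integer vector gene -> degree.
#' @param n_sets number of sets. Default 30.
#' @param set_size range of set sizes. Default c(20, 120).
#' @return named list of gene sets.
#' @export
simulate_genesets <- function(cfg, planted_degree, n_sets = 30L,
                              set_size = c(20L, 120L)) {
  set.seed(cfg$seed + 7L)
  genes <- names(planted_degree)
  w_hi <- planted_degree + 0.25
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- min(sample(set_size[1L]:set_size[2L], 1L), length(genes))
    if (i <= ceiling(n_sets / 5)) {
      sample(genes, k, prob = w_hi)      # degree-enriched sets
    } else {
      sample(genes, k)
    }
  })
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  sets
}

#' Simulate an ortholog pair table
#'
#' A one-to-one mapping between "human" ids (the simulated genes) and
#' derived "mouse" ids for a random subset of genes.
#'
#' @param cfg a [sim_config()].
#' @param genes gene ids.
#' @param fraction fraction with a one-to-one ortholog. Default 0.9.
#' @return data.frame `human`, `mouse`.
#' @export
simulate_orthologs <- function(cfg, genes, fraction = 0.9) {
  set.seed(cfg$seed + 8L)
  keep <- sort(sample(genes, round(fraction * length(genes))))
  data.frame(human = keep, mouse = sub("^gene", "mgene", keep),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every external format the pipeline reads: OBO ontology,
#' annotation TSV, upper-level map TSV, gene BED, per-trait summary
#' statistics TSVs, trait manifest, iHS/DRC150 tracks, feature table,
#' expression TSV, GMT collection and ortholog pairs, plus a ground-truth
#' TSV of planted degrees and sweep genes.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created).
#' @return invisibly, a named list of the paths written.
#' @export
simulate_bundle <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  onto <- simulate_ontology(cfg)
  ann <- simulate_annotations(cfg, onto)
  gwas <- simulate_gwas(cfg, genome)
  tracks <- simulate_tracks(cfg, genome)
  feat <- simulate_features(cfg, ann$planted_degree)
  sets <- simulate_genesets(cfg, ann$planted_degree)
  orth <- simulate_orthologs(cfg, genome$gene)
  paths <- list()
  p <- function(f) file.path(outdir, f)

  paths$obo <- p("ontology.obo")
  write_obo(onto$dag, paths$obo)
  paths$upper_map <- p("upper_map.tsv")
  um <- data.frame(term = rep(names(onto$upper_map), lengths(onto$upper_map)),
                   upper = unlist(onto$upper_map, use.names = FALSE))
  write_tsv(um, paths$upper_map, "upper-level term map")
  paths$annotations <- p("annotations.tsv")
  write_tsv(ann$annotations, paths$annotations, "gene-term annotations")
  paths$genes <- p("genes.bed")
  write.table(genome[, c("chrom", "start", "end", "gene", "strand")],
              paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths$manifest <- p("manifest.tsv")
  write_tsv(gwas$manifest, paths$manifest, "trait manifest")
  dir.create(p("sumstats"), showWarnings = FALSE)
  paths$sumstats <- vapply(names(gwas$stats), function(t) {
    f <- p(file.path("sumstats", paste0(t, ".tsv")))
    write_tsv(gwas$stats[[t]][, c("variant", "chrom", "pos", "beta", "se", "p")],
              f, paste0("summary statistics ", t))
    f
  }, character(1))
  paths$ihs <- p("ihs.tsv")
  write_tsv(tracks$ihs, paths$ihs, "iHS track")
  paths$drc <- p("drc150.tsv")
  write_tsv(tracks$drc, paths$drc, "DRC150 track")
  paths$features <- p("features.tsv")
  write_tsv(feat$features, paths$features, "gene features")
  paths$expression <- p("expression.tsv")
  write_tsv(data.frame(gene = rownames(feat$expression), feat$expression),
            paths$expression, "expression TPM")
  paths$gmt <- p("sets.gmt")
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1)), paths$gmt)
  paths$orthologs <- p("orthologs.tsv")
  write_tsv(orth, paths$orthologs, "ortholog pairs")
  paths$truth <- p("truth.tsv")
  write_tsv(data.frame(gene = names(ann$planted_degree),
                       planted_degree = unname(ann$planted_degree),
                       sweep = names(ann$planted_degree) %in% tracks$sweep_genes),
            paths$truth, "planted ground truth")
  invisible(paths)
}

#' Write an ontology DAG as an OBO file
#'
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", dag$names[[t]]),
                 paste0("is_a: ", dag$is_a[[t]])), con)
  }
  invisible(path)
}
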