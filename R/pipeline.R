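# End-to-end orchestration: read inputs, run each stage in dependency
# order, write provenance-stamped TSVs. A failing stage skips its
# dependents; independent stages still run.

#' Run the full pleiotropy pipeline
#'
#' Executes degree -> classify -> modularity -> gwas -> features ->
#' selection -> genesets over a directory of input files (as written by
#' [simulate_bundle()] or assembled from real resources). All randomized
#' stages (modularity null, length-matched enrichment) use `seed`.
#'
#' @param config a named list or path to a YAML file with elements
#'   `inputs` (named paths: obo, annotations, upper_map, genes, manifest,
#'   sumstats (directory), ihs, drc, features, expression, gmt, orthologs),
#'   `outdir`, `seed`, and optional `params` overriding stage defaults
#'   (p_threshold, window_bp, cut_height, n_perm, alpha, excluded_terms,
#'   n_draws).
#' @return invisibly, a list of stage results with a `status` data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$outdir))
  seed <- config$seed %||% 1L
  prm <- config$params %||% list()
  p_threshold <- prm$p_threshold %||% 5e-8
  window_bp <- prm$window_bp %||% 250000L
  cut_height <- prm$cut_height %||% 0.8
  n_perm <- prm$n_perm %||% 100L
  alpha <- prm$alpha %||% 0.01
  excluded <- prm$excluded_terms %||% "MP:0010768"
  n_draws <- prm$n_draws %||% 1000L
  inp <- config$inputs
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  res <- list()
  status <- list()
  stage <- function(name, deps, expr) {
    failed_dep <- deps[!vapply(deps, function(d) isTRUE(status[[d]]), logical(1))]
    if (length(failed_dep)) {
      message("skipping stage ", name, " (failed dependency: ",
              paste(failed_dep, collapse = ", "), ")")
      status[[name]] <<- FALSE
      return(invisible(NULL))
    }
    r <- tryCatch(expr, error = function(e) {
      message("stage ", name, " failed: ", conditionMessage(e)); e
    })
    ok <- !inherits(r, "error")
    status[[name]] <<- ok
    if (ok) res[[name]] <<- r
    invisible(NULL)
  }

  stage("degree", character(0), {
    dag <- read_obo(inp$obo)
    ann <- read_annotations(inp$annotations, dag)
    upper <- if (!is.null(inp$upper_map)) read_upper_map(inp$upper_map)
             else derive_upper_level_set(dag)
    ul <- propagate_to_upper(ann, dag, upper = upper, excluded = excluded)
    genes <- read_intervals(inp$genes)
    n_raw <- table(ann$gene[ann$known])
    deg <- degree_of_pleiotropy(ul, universe = genes$gene,
                                n_raw = setNames(as.integer(n_raw), names(n_raw)),
                                dataset = "ontology")
    write_tsv(deg, out("degrees_ontology.tsv"), "degrees (ontology)")
    list(dag = dag, ann = ann, degrees = deg, genes = genes)
  })

  stage("classify", "degree", {
    cls <- classify_pleiotropy(res$degree$degrees)
    write_tsv(cls, out("classes_ontology.tsv"),
              paste0("classes (ontology), HP cutoff ", attr(cls, "cutoff")))
    cls
  })

  stage("gwas", "degree", {
    manifest <- filter_traits(read_manifest(inp$manifest))
    # sumstats may be a directory of <trait>.tsv files or a vector of paths
    ss <- unlist(inp$sumstats, use.names = FALSE)
    files <- if (length(ss) == 1L && dir.exists(ss)) {
      file.path(ss, paste0(manifest$trait, ".tsv"))
    } else {
      ss[match(paste0(manifest$trait, ".tsv"), basename(ss))]
    }
    present <- !is.na(files) & file.exists(files)
    stats <- lapply(which(present), function(i) {
      read_sumstats(files[i], manifest$trait[i])
    })
    names(stats) <- manifest$trait[present]
    leads <- do.call(rbind, lapply(stats, clump_lead_snps,
                                   p_threshold = p_threshold,
                                   window_bp = window_bp))
    assigned <- closest_gene(leads, res$degree$genes)
    dm <- trait_distance_matrix(stats)
    clusters <- cluster_traits(dm$d, cut_height = cut_height)
    m <- gene_cluster_matrix(assigned, clusters, dataset = "gwas")
    deg <- gwas_degree(m, universe = res$degree$genes$gene)
    cls <- classify_pleiotropy(deg)
    write_tsv(assigned, out("lead_snps.tsv"), "lead SNPs")
    write_tsv(cls, out("classes_gwas.tsv"),
              paste0("classes (gwas), HP cutoff ", attr(cls, "cutoff")))
    list(stats = stats, leads = assigned, clusters = clusters,
         matrix = m, degrees = deg, classes = cls)
  })

  stage("modularity", "gwas", {
    net <- build_network(res$gwas$matrix)
    mr <- modularity_null_test(net, n_perm = n_perm, seed = seed)
    write_tsv(data.frame(Q = mr$Q, null_mean = mean(mr$null_Q),
                         null_sd = sd(mr$null_Q), p = mr$p),
              out("modularity.tsv"), "modularity null test")
    mr
  })

  stage("features", "classify", {
    feats <- read_features(inp$features)
    expr_df <- read_features(inp$expression)
    expr <- as.matrix(expr_df[, -1, drop = FALSE])
    rownames(expr) <- expr_df$gene
    es <- expression_summary(expr)
    feats <- merge(feats, es, by = "gene", all.x = TRUE)
    cmp <- compare_numeric(
      feats, res$classify,
      feature_names = intersect(c("breadth", "median_tpm", "max_tpm",
                                  "ppi_count", "go_bp_count", "pHaplo",
                                  "pTriplo", "LOEUF", "missense_z"),
                                names(feats)),
      pairs = list(c("HP", "NP"), c("HP", "ST"), c("HP", "MP"))
    )
    write_tsv(cmp, out("feature_comparisons.tsv"), "feature comparisons")
    pli <- pli_proportions(feats, res$classify)
    write_tsv(pli, out("pli_proportions.tsv"), "pLI > 0.9 proportions")
    fus <- fusil_phenotype_fraction(
      res$classify, setNames(feats$fusil, feats$gene))
    write_tsv(fus, out("fusil_fractions.tsv"), "FUSIL phenotype fractions")
    list(features = feats, comparisons = cmp, pli = pli, fusil = fus)
  })

  stage("selection", "classify", {
    ihs <- read_track(inp$ihs, "iHS")
    drc <- read_track(inp$drc, "DRC150")
    gs <- gene_max_score(ihs, res$degree$genes, mode = "gene")
    ds <- gene_max_score(drc, res$degree$genes, mode = "gene")
    fs <- flag_significant(gs, alpha = alpha, classes = res$classify)
    feats <- read_features(inp$features)
    comb <- combined_selection_flags(
      gs, setNames(feats$LOEUF, feats$gene),
      drc_stats = ds, classes = res$classify)
    lengths_bp <- setNames(res$degree$genes$end - res$degree$genes$start,
                           res$degree$genes$gene)
    hp <- res$classify$gene[res$classify$class == "HP"]
    flags <- setNames(fs$genes$flag, fs$genes$gene)
    lme <- length_matched_enrichment(flags, hp, res$degree$genes$gene,
                                     lengths_bp, n_draws = n_draws,
                                     seed = seed)
    write_tsv(fs$genes, out("selection_ihs.tsv"), "gene-level max iHS")
    write_tsv(fs$by_class, out("selection_by_class.tsv"),
              "flagged proportions by class")
    write_tsv(data.frame(observed = lme$observed, p = lme$p),
              out("length_matched.tsv"), "length-matched enrichment")
    list(ihs = fs, drc_stats = ds, combined = comb, length_matched = lme)
  })

  stage("genesets", "classify", {
    sets <- read_gmt(inp$gmt)
    universe <- res$degree$genes$gene
    hp <- res$classify$gene[res$classify$class == "HP"]
    enr <- ora(hp, sets, universe)
    nr <- greedy_nonredundant(sets)
    write_tsv(enr, out("enrichment.tsv"), "HP over-representation")
    write_tsv(data.frame(set = nr$selected, order = seq_along(nr$selected)),
              out("nonredundant_sets.tsv"), "greedy non-redundant sets")
    list(ora = enr, nonredundant = nr)
  })

  res$status <- data.frame(stage = names(status),
                           ok = unlist(status, use.names = FALSE))
  invisible(res)
}
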