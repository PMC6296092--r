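#' Default pipeline configuration
#'
#' One nested configuration object drives every stage; the defaults
#' reproduce all published thresholds: pairing gates 95% identity /
#' e-value 1e-5 / coverage 25-800 / contigs > 500 bp; the nine-criterion
#' quality cascade; 100 bp flanks; array design 50 bp clean window /
#' 20 bp end distance / functionality score 0.60; QC gates GenTrain 0.13 /
#' call rate 0.80 / Fe 0.80; abundance decile 0.10 with floored depth;
#' enrichment nodesize 5.
#'
#' @param rng_seed master seed, propagated to the synthetic generator.
#' @param ... replacement values for any top-level section (`synth`,
#'   `pairing`, `filters`, `flank_width`, `array`, `qc`, `abundance`,
#'   `enrichment`), merged over the defaults.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L, ...) {
  cfg <- list(
    rng_seed = as.integer(rng_seed),
    synth = unclass(synth_config(rng_seed = rng_seed)),
    pairing = list(min_identity = 95, max_evalue = 1e-5,
                   coverage_window = c(25, 800), min_length = 500),
    filters = c(default_filter_thresholds(), list(mgof_invert = FALSE)),
    flank_width = 100,
    array = list(window = 50, end_distance = 20, min_score = 0.60,
                 per_gene = 1),
    qc = list(gentrain_min = 0.13, call_rate_min = 0.80, fe_min = 0.80),
    abundance = list(decile = 0.10, d_mode = "floor"),
    enrichment = list(nodesize = 5, method = "classic", alpha_elim = 0.01,
                      min_in_top = 2, adjust = "BH")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("pipeline_config: unknown section '", nm, "'")
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg$synth$rng_seed <- cfg$rng_seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$synth$rng_seed <- as.integer(cfg$synth$rng_seed)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stages <- function() {
  c("synth", "pair", "consensus", "abundance", "array", "qc", "enrich",
    "report")
}

#' Run one pipeline stage
#'
#' Stages consume the in-memory `state` produced by their predecessors
#' and, when `outdir` is given, write their tabular outputs plus a
#' provenance record (`<stage>.provenance.json`: stage, seed, package
#' version, configuration and output checksums).
#'
#' @param stage one of `synth`, `pair`, `consensus`, `abundance`,
#'   `array`, `qc`, `enrich`, `report`.
#' @param config a [pipeline_config()].
#' @param state named list carrying earlier stage results (empty for
#'   `synth`).
#' @param outdir optional output directory (created if missing).
#' @return the updated state, invisibly when writing.
#' @export
run_stage <- function(stage, config, state = list(), outdir = NULL) {
  stages <- pipeline_stages()
  if (!is.character(stage) || length(stage) != 1L || !stage %in% stages) {
    stop("unknown stage '", stage, "'; available stages: ",
         paste(stages, collapse = ", "))
  }
  state <- switch(stage,
    synth = stage_synth(config, state),
    pair = stage_pair(config, state),
    consensus = stage_consensus(config, state),
    abundance = stage_abundance(config, state),
    array = stage_array(config, state),
    qc = stage_qc(config, state),
    enrich = stage_enrich(config, state),
    report = stage_report(config, state)
  )
  if (!is.null(outdir)) {
    write_stage_outputs(stage, config, state, outdir)
  }
  state
}

#' Run the full pipeline on synthetic data
#'
#' Chains all stages in order.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return the final state list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  state <- list()
  for (stage in pipeline_stages()) {
    state <- run_stage(stage, config, state, outdir)
  }
  state
}

stage_synth <- function(config, state) {
  scfg <- do.call(synth_config, config$synth)
  state$study <- generate_study(scfg)
  state
}

stage_pair <- function(config, state) {
  p <- config$pairing
  retained <- filter_hits(state$study$reference$hits, p$min_identity,
                          p$max_evalue, p$coverage_window, p$min_length)
  state$pairing <- pair_and_summarize(retained,
                                      n_targeted = config$synth$n_genes)
  state$contigs <- state$study$reference$contigs[
    state$study$reference$contigs$contig_id %in%
      state$pairing$retained_hits$contig_id, , drop = FALSE]
  state
}

stage_consensus <- function(config, state) {
  cs <- state$study$callsets
  inter <- intersect_callsets(cs$setA, cs$setB)
  thr <- config$filters
  filt <- apply_quality_filters(inter$common,
                                thresholds = thr[names(default_filter_thresholds())],
                                mgof_invert = isTRUE(thr$mgof_invert))
  catalog <- build_catalog(filt$passing, state$contigs,
                           width = config$flank_width)
  gene_len <- tapply(state$contigs$length, state$contigs$gene_id, sum)
  state$intersection <- inter
  state$filter_audit <- filt$audit
  state$catalog <- catalog
  state$catalog_summary <- summarize_catalog(
    catalog, paired_genes = state$pairing$paired_genes,
    gene_lengths = gene_len
  )
  state
}

stage_abundance <- function(config, state) {
  ca <- contig_abundance(state$catalog, state$contigs,
                         d_mode = config$abundance$d_mode)
  genes <- rank_genes(aggregate_gene_beta(ca),
                      decile = config$abundance$decile)
  state$contig_abundance <- ca
  state$gene_abundance <- genes
  state$depth_correlation <- depth_correlation(ca)
  state
}

stage_array <- function(config, state) {
  set.seed(stage_seed(state$study$config, 5L))
  snps <- state$catalog
  snps$functionality_score <- sample_functionality_scores(nrow(snps))
  raw <- rbind(
    state$study$callsets$setA[, c("contig_id", "pos")],
    state$study$callsets$setB[, c("contig_id", "pos")]
  )
  a <- config$array
  state$array_candidates <- select_candidates(
    snps, raw, state$contigs, per_gene = a$per_gene,
    min_score = a$min_score, end_distance = a$end_distance,
    window = a$window
  )
  state
}

stage_qc <- function(config, state) {
  gt <- state$study$genotypes
  st <- marker_stats(gt$calls)
  q <- config$qc
  klass <- classify_markers(st, gt$markers$gentrain_score,
                            gentrain_min = q$gentrain_min,
                            call_rate_min = q$call_rate_min,
                            fe_min = q$fe_min)
  state$marker_qc <- cbind(st, gentrain_score = gt$markers$gentrain_score,
                           source = gt$markers$source, klass = klass)
  state$concordance <- replicate_concordance(gt$calls, gt$replicate_pairs)
  state$tpr <- tpr_report(state$marker_qc)
  state
}

stage_enrich <- function(config, state) {
  ann <- state$study$annotations$annotations
  full <- propagate_go(go_pairs(ann), state$study$annotations$go_edges)
  genes <- state$gene_abundance
  top <- genes$gene_id[genes$top_decile]
  universe_all <- genes$gene_id
  universe_go <- intersect(universe_all, unique(full$gene_id))
  e <- config$enrichment
  state$go_enrichment <- fisher_term_tests(
    full, intersect(top, universe_go), universe_go, nodesize = e$nodesize,
    method = e$method, alpha_elim = e$alpha_elim,
    edges = state$study$annotations$go_edges
  )
  state$family_enrichment <- family_tests(
    ann, top, universe_all, min_in_top = e$min_in_top, adjust = e$adjust
  )
  state$flag_enrichment <- list(
    orphan = flag_tests(ann, top, universe_all, "orphan"),
    conifer_specific = flag_tests(ann, top, universe_all, "conifer_specific")
  )
  state
}

stage_report <- function(config, state) {
  state$report <- list(
    pairing = state$pairing[c("n_contigs_retained", "n_paired_genes",
                              "contigs_per_gene", "recovery_rate")],
    catalog = unclass(state$catalog_summary),
    filter_audit = as.list(state$filter_audit),
    depth_correlation = state$depth_correlation[c("r_raw", "r_beta")],
    concordance = state$concordance,
    tpr = state$tpr,
    n_array_selected = sum(state$array_candidates$selected)
  )
  state
}

write_stage_outputs <- function(stage, config, state, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_tsv <- function(x, name) {
    p <- file.path(outdir, name); write_tsv(x, p); files[[length(files) + 1]] <<- p
  }
  put_json <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[[length(files) + 1]] <<- p
  }
  if (stage == "synth") {
    ref <- state$study$reference
    p <- file.path(outdir, "contigs.fasta")
    write_contig_fasta(ref$contigs, p); files <- c(files, p)
    put_tsv(ref$hits, "hit_table.tsv")
    pa <- file.path(outdir, "caller_A.vcf")
    pb <- file.path(outdir, "caller_B.vcf")
    write_caller_vcf(state$study$callsets$setA, pa)
    write_caller_vcf(state$study$callsets$setB, pb)
    files <- c(files, pa, pb)
    pg <- file.path(outdir, "genotypes.tsv")
    write_genotype_matrix(state$study$genotypes$calls, pg)
    files <- c(files, pg)
    put_tsv(state$study$genotypes$markers, "marker_metadata.tsv")
    put_tsv(state$study$annotations$annotations, "annotations.tsv")
    put_tsv(state$study$annotations$go_edges, "go_edges.tsv")
  } else if (stage == "pair") {
    put_tsv(state$pairing$retained_hits, "retained_pairs.tsv")
    put_json(state$pairing[c("n_contigs_retained", "n_paired_genes",
                             "contigs_per_gene", "recovery_rate")],
             "pairing_summary.json")
  } else if (stage == "consensus") {
    put_tsv(state$catalog, "snp_catalog.tsv")
    put_json(c(unclass(state$catalog_summary),
               list(filter_audit = as.list(state$filter_audit))),
             "catalog_summary.json")
  } else if (stage == "abundance") {
    put_tsv(state$gene_abundance, "gene_abundance.tsv")
    put_tsv(utils::head(state$gene_abundance, 30), "top30_genes.tsv")
  } else if (stage == "array") {
    put_tsv(state$array_candidates, "array_manifest.tsv")
  } else if (stage == "qc") {
    put_tsv(state$marker_qc, "marker_qc.tsv")
    put_tsv(state$tpr, "tpr_report.tsv")
    put_json(state$concordance, "concordance.json")
  } else if (stage == "enrich") {
    put_tsv(state$go_enrichment, "go_enrichment.tsv")
    put_tsv(state$family_enrichment, "family_enrichment.tsv")
    put_json(state$flag_enrichment, "flag_enrichment.json")
  } else if (stage == "report") {
    put_json(state$report, "report.json")
  }
  prov <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("sprucesnp")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    outputs = as.list(setNames(unname(tools::md5sum(unlist(files))),
                               basename(unlist(files))))
  )
  jsonlite::write_json(prov, file.path(outdir,
                                       paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
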