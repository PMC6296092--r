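#' Generate synthetic gene annotations and a GO DAG with planted enrichment
#'
#' Builds a four-level GO-like DAG (root, 4 mid, 12 lower, 24 leaf terms,
#' with a few multi-parent cross edges), assigns genes direct annotations
#' to non-root terms, partitions genes into families (genes without a
#' family are orphans) and flags a fraction as conifer-specific. One
#' designated family and one designated leaf GO term are planted as
#' enriched among highly polymorphic genes: their member genes receive a
#' SNP-rate multiplier (`enrichment_multiplier`) which, fed to
#' [simulate_snp_counts()], drives them into the top beta decile.
#'
#' @param config a [synth_config()].
#' @return list with
#'   * `annotations`: data frame `gene_id, go_terms` (semicolon-separated
#'     direct annotations), `family` (`NA` for orphans), `orphan`,
#'     `conifer_specific`;
#'   * `go_edges`: data frame `child, parent` (a DAG obeying the
#'     true-path rule after propagation);
#'   * `truth`: list with `enriched_family`, `enriched_term` and
#'     `rate_multiplier`, a named per-gene vector.
#' @export
generate_annotations <- function(config) {
  validate_synth_config(config)
  set.seed(stage_seed(config, 4L))
  genes <- gene_ids(config$n_genes)
  ng <- length(genes)

  root <- "GO:0000001"
  lvl1 <- sprintf("GO:00001%02d", 1:4)
  lvl2 <- sprintf("GO:00002%02d", 1:12)
  lvl3 <- sprintf("GO:00003%02d", 1:24)
  edges <- rbind(
    data.frame(child = lvl1, parent = root, stringsAsFactors = FALSE),
    data.frame(child = lvl2, parent = lvl1[rep(1:4, each = 3)],
               stringsAsFactors = FALSE),
    data.frame(child = lvl3, parent = lvl2[rep(1:12, each = 2)],
               stringsAsFactors = FALSE),
    # cross edges: some leaves have a second parent (still acyclic)
    data.frame(child = lvl3[c(1, 7, 13)], parent = lvl2[c(4, 10, 2)],
               stringsAsFactors = FALSE)
  )

  annotatable <- c(lvl2, lvl3)
  n_terms <- 1L + rpois(ng, 1.2)
  annotated <- runif(ng) < 0.85
  go_direct <- character(ng)
  go_direct[annotated] <- vapply(which(annotated), function(i) {
    paste(sample(annotatable, min(n_terms[i], length(annotatable))),
          collapse = ";")
  }, character(1))

  # disjoint designated enriched sets: one family, one leaf term (capped at
  # a quarter of the genes each so small test universes stay meaningful)
  shuffled <- sample(genes)
  n_fam <- min(config$enriched_family_size, floor(ng / 4))
  n_term <- min(config$enriched_term_genes, floor(ng / 4))
  fam_genes <- shuffled[seq_len(n_fam)]
  term_genes <- shuffled[n_fam + seq_len(n_term)]
  enriched_term <- lvl3[24]
  ti <- match(term_genes, genes)
  go_direct[ti] <- ifelse(go_direct[ti] == "", enriched_term,
                          paste(go_direct[ti], enriched_term, sep = ";"))

  # families: designated FAM001 plus ~40 background families over ~93% of
  # the remaining genes; the rest are orphans
  family <- rep(NA_character_, ng)
  family[match(fam_genes, genes)] <- "FAM001"
  rest <- setdiff(genes, fam_genes)
  in_family <- rest[runif(length(rest)) < 0.93]
  family[match(in_family, genes)] <-
    sprintf("FAM%03d", 1 + sample.int(40, length(in_family), replace = TRUE))

  conifer <- runif(ng) < 0.06

  mult <- setNames(rep(1, ng), genes)
  mult[c(fam_genes, term_genes)] <- config$enrichment_multiplier

  annotations <- data.frame(
    gene_id = genes, go_terms = go_direct, family = family,
    orphan = is.na(family), conifer_specific = conifer,
    stringsAsFactors = FALSE
  )
  list(annotations = annotations, go_edges = edges,
       truth = list(enriched_family = "FAM001", enriched_term = enriched_term,
                    rate_multiplier = mult))
}

#' Generate a full synthetic study
#'
#' Orchestrates the individual generators into one coherent study: a
#' reference with hit table, pairing under the default gates, annotations
#' with planted enrichment, two caller call sets on the retained contigs
#' (with enriched genes' contigs drawn at an elevated SNP rate), a
#' genotype matrix, and functionality scores for array design.
#'
#' @param config a [synth_config()].
#' @return list with components `config`, `reference`, `pairing`
#'   (a [pair_and_summarize()] result on the default-filtered hit table),
#'   `contigs` (retained contigs only), `callsets`, `annotations` and
#'   `genotypes`.
#' @export
generate_study <- function(config) {
  validate_synth_config(config)
  ref <- generate_reference(config)
  retained <- filter_hits(ref$hits)
  pairing <- pair_and_summarize(retained, n_targeted = config$n_genes)
  contigs <- ref$contigs[ref$contigs$contig_id %in% retained$contig_id, ,
                         drop = FALSE]
  ann <- generate_annotations(config)
  mult <- ann$truth$rate_multiplier[contigs$gene_id]
  callsets <- generate_caller_sets(contigs, config, rate_multiplier = mult)
  genotypes <- generate_genotype_matrix(config)
  list(config = config, reference = ref, pairing = pairing, contigs = contigs,
       callsets = callsets, annotations = ann, genotypes = genotypes)
}
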