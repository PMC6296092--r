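#' Configuration for the synthetic study generator
#'
#' Builds and validates the single configuration object that drives all
#' synthetic-data generators. Defaults emulate the design of an
#' exome-capture SNP-discovery study in Norway spruce, scaled down so a
#' full run takes seconds: a few hundred target genes recovered as ~1.5
#' contigs per gene, two variant callers whose call sets overlap with a
#' Jaccard index near 0.29, roughly 9% of intersection variants failing
#' exactly one quality filter, and a 2,000-marker genotyping array scored
#' on 200 samples with failure-class proportions (monomorphic, paralogous,
#' weak signal) matching those of a real Infinium validation panel.
#'
#' @param n_genes number of targeted genes.
#' @param n_contigs number of assembled contigs (contigs are assigned to
#'   genes at random, so some genes receive several contigs and some none,
#'   emulating incomplete target recovery).
#' @param contig_len_range two-element bp interval for contig lengths;
#'   the minimum must exceed 200 bp so that full +/-100 bp flanks exist
#'   somewhere on every contig.
#' @param mean_depth_range two-element interval for per-contig mean read
#'   depth; depths are drawn log-uniformly, giving the right-skewed depth
#'   distribution typical of capture data.
#' @param true_snp_rate scaled polymorphism rate theta per bp. When
#'   `depth_coupled = TRUE` the expected number of variants discovered on
#'   a contig is `theta * L * H(floor(D) - 1)` (more reads reveal more
#'   segregating sites, as in the Watterson model); otherwise the harmonic
#'   factor is replaced by its average over contigs.
#' @param caller_jaccard intended Jaccard overlap of the two call sets in
#'   `[0, 1]`; each true variant is reported by both callers with this
#'   probability, otherwise by one caller only.
#' @param filter_fail_fraction fraction of intersection variants planted
#'   with an annotation violating exactly one named quality filter.
#' @param n_markers,n_samples genotyping-array dimensions. Two replicate
#'   columns are appended to the samples for concordance testing.
#' @param paralog_fraction fraction of markers simulated as probes
#'   annealing to two paralogous loci (near-obligate heterozygotes,
#'   `P(AB) = 0.95`).
#' @param monomorph_fraction fraction of markers simulated monomorphic
#'   (one homozygous class).
#' @param other_fail_fraction fraction of markers simulated with a
#'   clustering-quality (GenTrain-style) score below the QC gate.
#' @param control_fraction fraction of markers labelled as recycled
#'   control SNPs rather than newly predicted ones.
#' @param genotype_error_rate per-call miscall probability.
#' @param nocall_rate per-call probability of a missing (NoCall) genotype.
#' @param enriched_family_size number of genes in the designated
#'   SNP-enriched gene family.
#' @param enriched_term_genes number of genes directly annotated to the
#'   designated SNP-enriched GO term.
#' @param enrichment_multiplier multiplicative boost of `true_snp_rate`
#'   for genes in the designated enriched categories; drives them into the
#'   top beta decile by construction.
#' @param depth_coupled logical; couple variant discovery to depth (the
#'   realistic default) or not (for null checks of the beta correction).
#' @param rng_seed integer seed; identical configurations produce
#'   byte-identical outputs.
#'
#' @return a list of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_contigs = 20, n_genes = 15, rng_seed = 1)
#' @export
synth_config <- function(n_genes = 600,
                         n_contigs = 900,
                         contig_len_range = c(300, 2500),
                         mean_depth_range = c(30, 400),
                         true_snp_rate = 1.6e-3,
                         caller_jaccard = 0.285,
                         filter_fail_fraction = 0.09,
                         n_markers = 2000,
                         n_samples = 200,
                         paralog_fraction = 0.09,
                         monomorph_fraction = 0.055,
                         other_fail_fraction = 0.013,
                         control_fraction = 0.016,
                         genotype_error_rate = 3e-4,
                         nocall_rate = 2e-3,
                         enriched_family_size = 15,
                         enriched_term_genes = 20,
                         enrichment_multiplier = 6,
                         depth_coupled = TRUE,
                         rng_seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_contigs = n_contigs,
    contig_len_range = contig_len_range,
    mean_depth_range = mean_depth_range,
    true_snp_rate = true_snp_rate,
    caller_jaccard = caller_jaccard,
    filter_fail_fraction = filter_fail_fraction,
    n_markers = n_markers, n_samples = n_samples,
    paralog_fraction = paralog_fraction,
    monomorph_fraction = monomorph_fraction,
    other_fail_fraction = other_fail_fraction,
    control_fraction = control_fraction,
    genotype_error_rate = genotype_error_rate,
    nocall_rate = nocall_rate,
    enriched_family_size = enriched_family_size,
    enriched_term_genes = enriched_term_genes,
    enrichment_multiplier = enrichment_multiplier,
    depth_coupled = isTRUE(depth_coupled),
    rng_seed = as.integer(rng_seed)
  )
  validate_synth_config(cfg)
  for (f in c("n_genes", "n_contigs", "n_markers", "n_samples",
              "enriched_family_size", "enriched_term_genes")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  count_fields <- c("n_genes", "n_contigs", "n_markers", "n_samples",
                    "enriched_family_size", "enriched_term_genes")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v)) {
      config_error(f, "must be a positive integer")
    }
  }
  frac_fields <- c("caller_jaccard", "filter_fail_fraction", "paralog_fraction",
                   "monomorph_fraction", "other_fail_fraction", "control_fraction",
                   "genotype_error_rate", "nocall_rate")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      config_error(f, "must be a fraction in [0, 1]")
    }
  }
  if (cfg$paralog_fraction + cfg$monomorph_fraction + cfg$other_fail_fraction > 1) {
    config_error("paralog_fraction", "+ monomorph_fraction + other_fail_fraction exceeds 1")
  }
  for (f in c("contig_len_range", "mean_depth_range")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2L || any(is.na(v)) || v[1] > v[2]) {
      config_error(f, "must be a non-decreasing interval of length 2")
    }
  }
  if (cfg$contig_len_range[1] <= 200) {
    config_error("contig_len_range", "minimum must exceed 200 bp (room for 100 bp flanks)")
  }
  if (cfg$mean_depth_range[1] < 2) {
    config_error("mean_depth_range", "minimum mean depth must be >= 2")
  }
  if (cfg$n_samples < 4) {
    config_error("n_samples", "must be >= 4")
  }
  if (!is.numeric(cfg$true_snp_rate) || cfg$true_snp_rate < 0) {
    config_error("true_snp_rate", "must be a non-negative rate per bp")
  }
  if (cfg$enrichment_multiplier < 1) {
    config_error("enrichment_multiplier", "must be >= 1")
  }
  if (is.na(cfg$rng_seed)) config_error("rng_seed", "must be an integer")
  invisible(cfg)
}

# Internal: derive a stage-specific seed from the master seed so the
# individual generators are deterministic when called standalone and when
# orchestrated. Kept below 2^31 - 1.
stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$rng_seed) * 37 + offset) %% 2147483647)
}

gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
contig_ids <- function(n) sprintf("contig%06d", seq_len(n))
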