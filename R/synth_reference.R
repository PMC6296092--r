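#' Generate a synthetic de novo reference with a contig-to-target hit table
#'
#' Draws contig lengths and mean depths, assigns each contig to a target
#' gene (at random, so some genes attract multiple contigs and others are
#' never recovered), synthesises random nucleotide sequences, and emits a
#' blastn-style hit table in which a known subset of rows is constructed
#' to fail exactly one of the pairing criteria (identity, e-value or
#' coverage); contigs shorter than the length gate fail it naturally.
#'
#' @param config a [synth_config()] object.
#' @param sequences logical; set `FALSE` to skip nucleotide sequence
#'   synthesis when only contig statistics are needed (e.g. abundance
#'   simulations).
#' @return a list with elements
#'   * `contigs`: data frame `contig_id, gene_id, length, mean_depth,
#'     sequence`;
#'   * `hits`: data frame `contig_id, gene_id, identity, evalue,
#'     mean_coverage, contig_length` (one hit per contig against its true
#'     gene);
#'   * `gene_map`: data frame `contig_id, gene_id`;
#'   * `truth`: data frame with per-hit labels `passes_pairing` and
#'     `fail_reason` (`none`, `identity`, `evalue`, `coverage`, `length`).
#' @examples
#' ref <- generate_reference(synth_config(n_contigs = 20, n_genes = 15))
#' @export
generate_reference <- function(config, sequences = TRUE) {
  validate_synth_config(config)
  set.seed(stage_seed(config, 1L))
  n <- config$n_contigs
  genes <- gene_ids(config$n_genes)

  len <- round(runif(n, config$contig_len_range[1], config$contig_len_range[2]))
  lr <- log(config$mean_depth_range)
  depth <- exp(runif(n, lr[1], lr[2]))
  gene <- sample(genes, n, replace = TRUE)
  cid <- contig_ids(n)

  # planted pairing-filter failures: ~4% per failing criterion
  mode <- sample(c("none", "identity", "evalue", "coverage"), n,
                 replace = TRUE, prob = c(0.88, 0.04, 0.04, 0.04))
  identity <- runif(n, 95, 100)
  identity[mode == "identity"] <- runif(sum(mode == "identity"), 90, 94.9)
  evalue <- 10^runif(n, -30, -6)
  evalue[mode == "evalue"] <- 10^runif(sum(mode == "evalue"), -4.9, -3)
  coverage <- depth
  bad_cov <- mode == "coverage"
  if (any(bad_cov)) {
    low <- runif(sum(bad_cov)) < 0.5
    coverage[bad_cov][low] <- runif(sum(low), 2, 24.9)
    coverage[bad_cov][!low] <- runif(sum(!low), 801, 1200)
  }

  seqs <- if (sequences) random_dna(len) else rep(NA_character_, n)

  contigs <- data.frame(
    contig_id = cid, gene_id = gene, length = len,
    mean_depth = depth, sequence = seqs,
    stringsAsFactors = FALSE
  )
  hits <- data.frame(
    contig_id = cid, gene_id = gene, identity = identity,
    evalue = evalue, mean_coverage = coverage, contig_length = len,
    stringsAsFactors = FALSE
  )
  # ground truth re-derived from the planted values under default gates
  ok <- identity >= 95 & evalue < 1e-5 &
    coverage >= 25 & coverage <= 800 & len > 500
  reason <- rep("none", n)
  reason[identity < 95] <- "identity"
  reason[evalue >= 1e-5] <- "evalue"
  reason[coverage < 25 | coverage > 800] <- "coverage"
  reason[len <= 500 & reason == "none"] <- "length"
  truth <- data.frame(
    contig_id = cid, passes_pairing = ok, fail_reason = ifelse(ok, "none", reason),
    stringsAsFactors = FALSE
  )
  list(contigs = contigs, hits = hits,
       gene_map = contigs[, c("contig_id", "gene_id")], truth = truth)
}

# Internal: n random DNA sequences of the given lengths.
random_dna <- function(lengths) {
  bases <- c("A", "C", "G", "T")
  total <- sum(lengths)
  draw <- sample(bases, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  all <- paste(draw, collapse = "")
  substring(all, starts, ends)
}

#' Simulate per-contig discovered-SNP counts
#'
#' Draws the number of variant sites discovered on each contig. Under
#' depth coupling the expectation is `rate * L * H(floor(D) - 1)`, the
#' Watterson-style expectation that deeper sequencing reveals more
#' segregating sites; otherwise the harmonic factor is replaced by its
#' mean across contigs so totals remain comparable.
#'
#' @param contigs data frame with columns `length` and `mean_depth`
#'   (e.g. from [generate_reference()]).
#' @param config a [synth_config()]; `true_snp_rate` and `depth_coupled`
#'   are used.
#' @param rate_multiplier optional per-contig multiplicative factor on the
#'   SNP rate (recycled if length 1), used to plant enriched genes.
#' @return integer vector of SNP counts, one per contig row.
#' @export
simulate_snp_counts <- function(contigs, config, rate_multiplier = 1) {
  d <- pmax(floor(contigs$mean_depth), 2)
  h <- harmonic_number(d - 1L)
  scale <- if (config$depth_coupled) h else rep(mean(h), length(h))
  lambda <- config$true_snp_rate * contigs$length * scale * rate_multiplier
  rpois(length(lambda), lambda)
}
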