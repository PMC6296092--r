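#' Depth-corrected SNP abundance (beta) for a contig
#'
#' `beta = [(S + 1) / L] / H(D - 1)` where `S` is the number of SNPs in
#' the contig, `L` the contig length and `D` its average read depth, and
#' `H(n)` is the n-th harmonic number. Dividing the per-bp SNP count by
#' the harmonic number of depth minus one removes the Watterson-style
#' dependence of the number of discovered segregating sites on sequencing
#' depth, so contigs of different depths become comparable.
#'
#' Since the average depth is rarely integral, the harmonic sum is taken
#' over `i = 1 .. floor(D) - 1` by default (`d_mode = "floor"`, the
#' conservative reading); `d_mode = "digamma"` instead interpolates
#' `H(D - 1) = digamma(D) + gamma` for sensitivity analysis.
#'
#' @param S SNP count(s), `>= 0`.
#' @param L contig length(s) in bp, `> 0`.
#' @param D average depth(s); `floor(D)` must be `>= 2` (the harmonic sum
#'   is empty below that).
#' @param d_mode `"floor"` or `"digamma"` (see above).
#' @return numeric vector of beta values.
#' @examples
#' snp_beta(0, 100, 2)           # 0.01: harmonic sum is 1
#' snp_beta(4, 1000, 10)         # 0.005 / H(9)
#' @export
snp_beta <- function(S, L, D, d_mode = c("floor", "digamma")) {
  d_mode <- match.arg(d_mode)
  n <- max(length(S), length(L), length(D))
  S <- rep_len(S, n); L <- rep_len(L, n); D <- rep_len(D, n)
  if (any(S < 0)) stop("snp_beta: S must be >= 0")
  if (any(L <= 0)) stop("snp_beta: L must be > 0")
  if (any(floor(D) < 2)) {
    stop("snp_beta: floor(D) must be >= 2 (harmonic sum over 1 .. floor(D)-1 is empty)")
  }
  h <- switch(d_mode,
    floor = harmonic_number(as.integer(floor(D)) - 1L),
    digamma = digamma(D) - digamma(1)
  )
  ((S + 1) / L) / h
}

#' Length-weighted gene beta from contig parts
#'
#' When a gene is assembled from several contigs its beta is the
#' length-weighted mean of the contig betas.
#'
#' @param parts data frame with columns `L` (contig lengths) and `beta`.
#' @return the weighted mean beta.
#' @examples
#' gene_beta(data.frame(L = c(500, 1500), beta = c(0.002, 0.004))) # 0.0035
#' @export
gene_beta <- function(parts) {
  if (is.null(nrow(parts)) || nrow(parts) == 0L) {
    stop("gene_beta: parts must be non-empty")
  }
  sum(parts$L * parts$beta) / sum(parts$L)
}

#' Per-contig abundance table
#'
#' Counts catalog SNPs per contig, evaluates [snp_beta()], and drops
#' (with a message) contigs whose depth is too low for the harmonic sum.
#'
#' @param catalog SNP catalog from [build_catalog()] (only `contig_id` is
#'   used; contigs absent from the catalog get `S = 0`).
#' @param contigs contig table with `contig_id, gene_id, length,
#'   mean_depth`.
#' @param d_mode passed to [snp_beta()].
#' @return data frame `contig_id, gene_id, S, L, D, beta`.
#' @export
contig_abundance <- function(catalog, contigs, d_mode = "floor") {
  S <- as.integer(table(factor(catalog$contig_id, levels = contigs$contig_id)))
  ok <- floor(contigs$mean_depth) >= 2
  if (any(!ok)) {
    message(sum(!ok), " contig(s) with floor(D) < 2 excluded from abundance analysis")
  }
  data.frame(
    contig_id = contigs$contig_id[ok], gene_id = contigs$gene_id[ok],
    S = S[ok], L = contigs$length[ok], D = contigs$mean_depth[ok],
    beta = snp_beta(S[ok], contigs$length[ok], contigs$mean_depth[ok], d_mode),
    stringsAsFactors = FALSE
  )
}

#' Aggregate contig betas to genes
#'
#' @param contig_ab per-contig table from [contig_abundance()].
#' @return data frame `gene_id, beta_weighted, S_total, L_total,
#'   n_contigs`.
#' @export
aggregate_gene_beta <- function(contig_ab) {
  sp <- split(contig_ab, contig_ab$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    beta_weighted = vapply(sp, gene_beta, numeric(1)),
    S_total = vapply(sp, function(d) sum(d$S), numeric(1)),
    L_total = vapply(sp, function(d) sum(d$L), numeric(1)),
    n_contigs = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank genes by beta and mark the top decile
#'
#' Orders genes by descending weighted beta with a deterministic
#' tie-break (descending total SNP count, then gene id) and flags the
#' `floor(decile * N)` highest-ranking genes (at least one).
#'
#' @param genes data frame from [aggregate_gene_beta()].
#' @param decile fraction of genes to flag, in (0, 1).
#' @return `genes` reordered, with added `rank` and `top_decile` columns.
#' @export
rank_genes <- function(genes, decile = 0.10) {
  if (!is.numeric(decile) || decile <= 0 || decile >= 1) {
    stop("rank_genes: decile must lie in (0, 1)")
  }
  if (nrow(genes) == 0L) stop("rank_genes: genes must be non-empty")
  ord <- order(-genes$beta_weighted, -genes$S_total, genes$gene_id)
  out <- genes[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n_top <- max(1L, floor(decile * nrow(out)))
  out$top_decile <- out$rank <= n_top
  rownames(out) <- NULL
  out
}

#' Correlation of raw and depth-corrected abundance with depth
#'
#' Pearson correlations of the raw per-bp SNP density `S/L` and of beta
#' with contig mean depth. On depth-coupled discovery the corrected
#' statistic should correlate much less with depth than the raw one.
#'
#' @param contig_ab per-contig table from [contig_abundance()].
#' @return list with `r_raw`, `r_beta` and `undefined` (`TRUE` when fewer
#'   than 3 contigs or zero variance in a variable).
#' @export
depth_correlation <- function(contig_ab) {
  raw <- contig_ab$S / contig_ab$L
  if (nrow(contig_ab) < 3 ||
      stats::var(raw) == 0 || stats::var(contig_ab$D) == 0 ||
      stats::var(contig_ab$beta) == 0) {
    warning("depth_correlation: undefined (need >= 3 contigs with variance)")
    return(list(r_raw = NA_real_, r_beta = NA_real_, undefined = TRUE))
  }
  list(r_raw = cor(raw, contig_ab$D),
       r_beta = cor(contig_ab$beta, contig_ab$D),
       undefined = FALSE)
}
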