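#' Check flank cleanliness of candidate SNPs
#'
#' A candidate's flanks are clean iff no other variant — SNP or indel,
#' from either caller's raw list, regardless of filter status — lies
#' within `window` bp on either side (closed window `[pos - w, pos + w]`,
#' excluding the candidate position itself). Polymorphism under the probe
#' footprint disrupts annealing, so the check deliberately consults the
#' union of raw call sets rather than only high-confidence SNPs; pass a
#' filtered variant table to relax this.
#'
#' @param snps data frame with `contig_id` and `pos` of the candidates.
#' @param all_variants data frame with `contig_id` and `pos` of every
#'   known variant.
#' @param window half-window in bp (inclusive bounds).
#' @return logical vector, `TRUE` where the flank is clean.
#' @export
check_flank_cleanliness <- function(snps, all_variants, window = 50) {
  missing <- setdiff(unique(snps$contig_id), unique(all_variants$contig_id))
  if (length(missing)) {
    stop("check_flank_cleanliness: contig(s) absent from variant index: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  by_contig <- split(all_variants$pos, all_variants$contig_id)
  vapply(seq_len(nrow(snps)), function(i) {
    p <- snps$pos[i]
    v <- by_contig[[snps$contig_id[i]]]
    in_win <- sum(v >= p - window & v <= p + window)
    at_pos <- sum(v == p)
    (in_win - at_pos) == 0L
  }, logical(1))
}

#' Select genotyping-array candidate SNPs, one per gene
#'
#' Applies the three published design criteria — clean 50 bp flanks (no
#' other variant nearby, see [check_flank_cleanliness()]), a minimum
#' distance of 20 bp from both contig ends (`min(pos - 1, L - pos) >=
#' 20`), and an assay functionality score of at least 0.60 — then keeps
#' at most `per_gene` SNPs per gene, preferring the highest functionality
#' score (ties: highest MAF, then lowest position). Selection is
#' order-independent: candidates are sorted before the per-gene argmax.
#'
#' @param snps catalog data frame (from [build_catalog()]) with an added
#'   `functionality_score` column.
#' @param all_variants raw variant table for the flank check.
#' @param contigs contig table with `contig_id` and `length`.
#' @param per_gene maximum selections per gene.
#' @param min_score functionality-score threshold.
#' @param end_distance minimum distance from contig ends in bp.
#' @param window flank-cleanliness half-window in bp.
#' @return data frame of candidates: `contig_id, pos, gene_id,
#'   functionality_score, clean_flanks, end_distance_ok, score_ok,
#'   selected`.
#' @export
select_candidates <- function(snps, all_variants, contigs, per_gene = 1,
                              min_score = 0.60, end_distance = 20,
                              window = 50) {
  if (is.null(snps$functionality_score)) {
    stop("select_candidates: snps must carry a functionality_score column")
  }
  i <- match(snps$contig_id, contigs$contig_id)
  L <- contigs$length[i]
  out <- snps[, c("contig_id", "pos", "gene_id", "maf", "functionality_score")]
  out$clean_flanks <- if (nrow(snps)) {
    check_flank_cleanliness(snps, all_variants, window)
  } else logical(0)
  out$end_distance_ok <- pmin(out$pos - 1, L - out$pos) >= end_distance
  out$score_ok <- out$functionality_score >= min_score
  eligible <- out$clean_flanks & out$end_distance_ok & out$score_ok

  out$selected <- FALSE
  el <- out[eligible, , drop = FALSE]
  if (nrow(el)) {
    ord <- order(el$gene_id, -el$functionality_score, -el$maf, el$pos)
    el <- el[ord, , drop = FALSE]
    rank_in_gene <- stats::ave(seq_len(nrow(el)), el$gene_id,
                               FUN = seq_along)
    chosen <- el[rank_in_gene <= per_gene, c("contig_id", "pos")]
    key <- paste(out$contig_id, out$pos)
    out$selected <- key %in% paste(chosen$contig_id, chosen$pos)
  }
  rownames(out) <- NULL
  out
}

#' Manufacture-rate accounting
#'
#' @param n_submitted SNPs submitted for bead manufacture.
#' @param n_manufactured SNPs successfully manufactured.
#' @return list with the counts, `manufacture_rate` (percent) and its
#'   1-dp rendering.
#' @examples
#' manufacture_rate(6000, 5660)$manufacture_rate_1dp # 94.3
#' @export
manufacture_rate <- function(n_submitted, n_manufactured) {
  r <- 100 * n_manufactured / n_submitted
  list(n_submitted = n_submitted, n_manufactured = n_manufactured,
       manufacture_rate = r, manufacture_rate_1dp = round(r, 1))
}
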