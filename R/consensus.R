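#' Intersect two caller call sets
#'
#' A site is common to both call sets iff the two callers report it at
#' the same contig and position with an identical reference allele and an
#' identical alternative-allele list after upper-casing. Each set must be
#' internally deduplicated on (contig, position).
#'
#' @param setA,setB caller variant data frames (see
#'   [generate_caller_sets()] for the columns). `setA` is the
#'   annotation-of-record: its quality annotations and read counts are the
#'   ones carried into the matched pairs.
#' @return list with `common` (the matched pairs: `setA`'s record plus
#'   `ref_reads_B`, `alt_reads_B`), `n_common`, and `union_size`
#'   (`|A| + |B| - |common|`).
#' @export
intersect_callsets <- function(setA, setB) {
  keyA <- check_dedup(setA, "setA")
  keyB <- check_dedup(setB, "setB")
  m <- match(keyA, keyB)
  hit <- !is.na(m)
  same_alleles <- hit
  same_alleles[hit] <-
    toupper(setA$ref[hit]) == toupper(setB$ref[m[hit]]) &
    toupper(setA$alt[hit]) == toupper(setB$alt[m[hit]])
  common <- setA[same_alleles, , drop = FALSE]
  mb <- m[same_alleles]
  common$ref_reads_B <- setB$ref_reads[mb]
  common$alt_reads_B <- setB$alt_reads[mb]
  rownames(common) <- NULL
  list(common = common, n_common = nrow(common),
       union_size = union_size(nrow(setA), nrow(setB), nrow(common)))
}

check_dedup <- function(set, label) {
  key <- paste(set$contig_id, set$pos, sep = ":")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop(sprintf("%s contains duplicate (contig, pos) keys: %s", label,
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  key
}

#' Union size from set and intersection counts
#'
#' `|A| + |B| - |common|`, the number of distinct sites detected by
#' either caller.
#'
#' @param n_a,n_b,n_common set and intersection sizes.
#' @return the union size.
#' @examples
#' union_size(115336, 191334, 68004) # 238666
#' @export
union_size <- function(n_a, n_b, n_common) {
  n_a + n_b - n_common
}

#' Apply the high-confidence quality-filter cascade
#'
#' A matched pair passes iff all gates hold on the annotation-of-record:
#' `MQ >= 20`, `MMLQ >= 10`, `QD >= 10`, `PP >= 20`, `SbPval >= 0.01`,
#' `HapScore >= 15`, `MGOF >= 20`, `SC >= 0.95`, at least two reads for
#' the alternative allele (excluding singletons), and a single
#' alternative allele (bi-allelic). The cascade is a pure conjunction, so
#' it is order-independent; the audit tallies every failed filter of every
#' rejected site, so audit counts can exceed the number rejected.
#'
#' @param common matched pairs from [intersect_callsets()].
#' @param thresholds named list as [default_filter_thresholds()].
#' @param mgof_invert the max-goodness-of-fit gate is applied as
#'   `MGOF >= 20` by default, as published; set `TRUE` to invert it to
#'   `MGOF <= 20` ("max allowed value" reading).
#' @return list with `passing` (the surviving rows), `audit` (named
#'   integer vector of per-filter rejection counts) and `n_rejected`.
#' @export
apply_quality_filters <- function(common, thresholds = default_filter_thresholds(),
                                  mgof_invert = FALSE) {
  ann_fields <- c("MQ", "MMLQ", "QD", "PP", "SbPval", "HapScore", "MGOF", "SC")
  if (nrow(common)) {
    for (f in ann_fields) {
      bad <- which(is.na(common[[f]]))
      if (length(bad)) {
        stop(sprintf("missing annotation '%s' at site %s:%d", f,
                     common$contig_id[bad[1]], common$pos[bad[1]]))
      }
    }
  }
  alt1 <- first_alt_reads(common$alt_reads)
  n_alt <- n_alts(common$alt)
  mgof_ok <- if (mgof_invert) common$MGOF <= thresholds$MGOF else
    common$MGOF >= thresholds$MGOF
  checks <- list(
    MQ = common$MQ >= thresholds$MQ,
    MMLQ = common$MMLQ >= thresholds$MMLQ,
    QD = common$QD >= thresholds$QD,
    PP = common$PP >= thresholds$PP,
    SbPval = common$SbPval >= thresholds$SbPval,
    HapScore = common$HapScore >= thresholds$HapScore,
    MGOF = mgof_ok,
    SC = common$SC >= thresholds$SC,
    alt_reads = alt1 >= thresholds$min_alt_reads,
    biallelic = n_alt == 1L
  )
  pass <- Reduce(`&`, checks)
  if (length(pass) == 0L) pass <- logical(0)
  audit <- vapply(checks, function(ok) sum(!ok), integer(1))
  list(passing = common[pass, , drop = FALSE], audit = audit,
       n_rejected = sum(!pass))
}

first_alt_reads <- function(alt_reads) {
  as.numeric(sub(",.*$", "", alt_reads))
}

n_alts <- function(alt) {
  lengths(strsplit(alt, ",", fixed = TRUE))
}

#' Extract flanking sequence around a SNP
#'
#' Returns up to `width` bases upstream and downstream of position `pos`
#' on a contig sequence (1-based, closed coordinates); flanks are
#' truncated at the contig ends, so their lengths equal
#' `min(width, distance to the respective end)`.
#'
#' @param sequence contig nucleotide sequence (character scalar or vector).
#' @param pos 1-based SNP position (recycled against `sequence`).
#' @param width maximal flank length in bp.
#' @return list with character vectors `flank_up` and `flank_down`.
#' @examples
#' extract_flanks("ACGTACGT", 4, width = 2)
#' @export
extract_flanks <- function(sequence, pos, width = 100) {
  L <- nchar(sequence)
  if (any(pos < 1 | pos > L)) {
    bad <- which(pos < 1 | pos > L)[1]
    stop(sprintf("position %d outside contig of length %d", pos[bad], L[bad]))
  }
  list(
    flank_up = substring(sequence, pmax(1, pos - width), pos - 1),
    flank_down = substring(sequence, pos + 1, pmin(L, pos + width))
  )
}

#' Assemble the consensus SNP catalog
#'
#' Attaches contig sequence flanks, gene pairing, read depth and minor
#' allele frequency (from the annotation-of-record's read counts) to the
#' filter-passing sites.
#'
#' @param passing passing rows from [apply_quality_filters()].
#' @param contigs contig table with `contig_id, gene_id, length, sequence`.
#' @param width flank width in bp.
#' @return data frame with one SNP per row: `contig_id, pos, ref, alt,
#'   depth, maf, flank_up, flank_down, gene_id`.
#' @export
build_catalog <- function(passing, contigs, width = 100) {
  i <- match(passing$contig_id, contigs$contig_id)
  if (anyNA(i)) {
    stop("build_catalog: unknown contig id: ",
         passing$contig_id[which(is.na(i))[1]])
  }
  alt1 <- first_alt_reads(passing$alt_reads)
  depth <- passing$ref_reads + alt1
  f <- alt1 / depth
  fl <- if (nrow(passing)) {
    extract_flanks(contigs$sequence[i], passing$pos, width)
  } else list(flank_up = character(0), flank_down = character(0))
  data.frame(
    contig_id = passing$contig_id, pos = passing$pos,
    ref = toupper(passing$ref), alt = toupper(passing$alt),
    depth = depth, maf = pmin(f, 1 - f),
    flank_up = fl$flank_up, flank_down = fl$flank_down,
    gene_id = contigs$gene_id[i],
    stringsAsFactors = FALSE
  )
}

#' Summarise a consensus SNP catalog
#'
#' Computes catalog-level statistics: SNPs per SNPed gene, SNPs per gene
#' over all paired genes, the number of unSNPed genes, SNP abundance per
#' 100 sites (over the SNPed genes' sequence and over all paired genes'
#' sequence), and the corresponding one-SNP-per-N-sites renderings.
#'
#' @param snps catalog data frame from [build_catalog()] (needs `gene_id`).
#' @param paired_genes character vector of all paired gene ids.
#' @param gene_lengths named numeric vector, total assembled bp per gene.
#' @return list of class `catalog_summary` with fields `n_snps`,
#'   `n_snped_genes`, `n_unsnped_genes`, `snps_per_snped_gene`,
#'   `snps_per_gene_all`, `abundance_per_100` (SNPed genes),
#'   `abundance_per_100_all`, `sites_per_snp`, `sites_per_snp_all` and
#'   rounded renderings. Zero genes yield `NA` ratios flagged
#'   `undefined = TRUE`.
#' @export
summarize_catalog <- function(snps, paired_genes, gene_lengths) {
  if (!all(snps$gene_id %in% paired_genes)) {
    stop("summarize_catalog: catalog contains genes outside paired_genes")
  }
  snped <- unique(snps$gene_id)
  ratios <- catalog_ratios(nrow(snps), length(snped), length(paired_genes))
  len_snped <- sum(gene_lengths[snped])
  len_all <- sum(gene_lengths[paired_genes])
  ab <- if (len_snped > 0) 100 * nrow(snps) / len_snped else NA_real_
  ab_all <- if (len_all > 0) 100 * nrow(snps) / len_all else NA_real_
  out <- c(ratios, list(
    abundance_per_100 = ab,
    abundance_per_100_all = ab_all,
    sites_per_snp = sites_per_snp(ab),
    sites_per_snp_all = sites_per_snp(ab_all)
  ))
  class(out) <- "catalog_summary"
  out
}

#' Catalog accounting ratios from counts
#'
#' The arithmetic core of [summarize_catalog()], usable directly on
#' published counts.
#'
#' @param n_snps number of catalog SNPs.
#' @param n_snped_genes number of genes carrying at least one SNP.
#' @param n_paired_genes number of paired genes in total.
#' @return list with the counts, `n_unsnped_genes`,
#'   `snps_per_snped_gene`, `snps_per_gene_all`, their 2-dp renderings,
#'   and `undefined`.
#' @examples
#' catalog_ratios(61771, 13543, 16516)
#' @export
catalog_ratios <- function(n_snps, n_snped_genes, n_paired_genes) {
  undef <- n_paired_genes == 0
  per_snped <- if (n_snped_genes > 0) n_snps / n_snped_genes else NA_real_
  per_all <- if (n_paired_genes > 0) n_snps / n_paired_genes else NA_real_
  list(n_snps = n_snps, n_snped_genes = n_snped_genes,
       n_unsnped_genes = n_paired_genes - n_snped_genes,
       snps_per_snped_gene = per_snped,
       snps_per_gene_all = per_all,
       snps_per_snped_gene_2dp = round(per_snped, 2),
       snps_per_gene_all_2dp = round(per_all, 2),
       undefined = undef)
}

#' Sites per SNP from an abundance per 100 sites
#'
#' @param abundance_per_100 SNPs per 100 sites.
#' @return `round(100 / abundance_per_100)`.
#' @examples
#' sites_per_snp(0.234) # 427
#' @export
sites_per_snp <- function(abundance_per_100) {
  if (is.na(abundance_per_100) || abundance_per_100 <= 0) return(NA_real_)
  round(100 / abundance_per_100)
}
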