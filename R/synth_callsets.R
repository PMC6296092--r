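#' Names of the consensus quality filters
#'
#' The nine per-site criteria of the high-confidence cascade plus the
#' bi-allelism requirement: eight numeric annotation gates (`MQ`, `MMLQ`,
#' `QD`, `PP`, `SbPval`, `HapScore`, `MGOF`, `SC`), the minimum of two
#' reads supporting the alternative allele (`alt_reads`, which de facto
#' excludes singletons) and the single-alternative-allele rule
#' (`biallelic`).
#'
#' @return character vector of filter names.
#' @export
filter_names <- function() {
  c("MQ", "MMLQ", "QD", "PP", "SbPval", "HapScore", "MGOF", "SC",
    "alt_reads", "biallelic")
}

#' Default thresholds of the high-confidence quality cascade
#'
#' @return named list of the numeric gates: `MQ >= 20`, `MMLQ >= 10`,
#'   `QD >= 10`, `PP >= 20`, `SbPval >= 0.01`, `HapScore >= 15`,
#'   `MGOF >= 20`, `SC >= 0.95`, `min_alt_reads = 2`.
#' @export
default_filter_thresholds <- function() {
  list(MQ = 20, MMLQ = 10, QD = 10, PP = 20, SbPval = 0.01,
       HapScore = 15, MGOF = 20, SC = 0.95, min_alt_reads = 2)
}

# value ranges used by the generator: passing values sit comfortably inside
# each gate, failing values sit clearly outside it (per-filter attribution).
.pass_ranges <- list(
  MQ = c(30, 60), MMLQ = c(15, 40), QD = c(15, 40), PP = c(30, 120),
  SbPval = c(0.05, 1), HapScore = c(16, 60), MGOF = c(25, 80), SC = c(0.96, 1)
)
.fail_ranges <- list(
  MQ = c(5, 19.5), MMLQ = c(0, 9.5), QD = c(0, 9.5), PP = c(0, 19.5),
  SbPval = c(0, 0.009), HapScore = c(0, 14.5), MGOF = c(0, 19.5), SC = c(0.5, 0.945)
)

#' Generate two synthetic caller call sets with ground truth
#'
#' Plants true variant sites on the contigs, reports each site in both
#' call sets with probability `caller_jaccard` (otherwise in one set
#' only), and gives a known fraction of the intersection sites a quality
#' annotation violating exactly one named filter — including planted
#' singletons (one alternative read) and tri-allelic sites. The first
#' caller ("A") carries the full annotation block; the second ("B")
#' confirms sites but emits no quality annotations, as is typical when
#' pairing a haplotype-aware caller with a mapper-integrated one.
#'
#' @param contigs contig table from [generate_reference()].
#' @param config a [synth_config()].
#' @param rate_multiplier optional per-contig SNP-rate multiplier (see
#'   [simulate_snp_counts()]).
#' @return list with caller data frames `setA` and `setB` (columns
#'   `caller_id, contig_id, pos, ref, alt, MQ, MMLQ, QD, PP, SbPval,
#'   HapScore, MGOF, SC, ref_reads, alt_reads`; multi-allelic `alt` and
#'   `alt_reads` are comma-separated) and a `truth` data frame with one
#'   row per emitted site (`contig_id, pos, in_both_callers,
#'   passes_quality, failed_filter, is_singleton, is_biallelic`).
#' @export
generate_caller_sets <- function(contigs, config, rate_multiplier = 1) {
  if (nrow(contigs) == 0L) stop("generate_caller_sets: contigs must be non-empty")
  validate_synth_config(config)
  set.seed(stage_seed(config, 2L))

  counts <- simulate_snp_counts(contigs, config, rate_multiplier)
  counts <- pmin(counts, floor(contigs$length / 3))
  idx <- rep(seq_len(nrow(contigs)), counts)
  n <- length(idx)
  if (n == 0L) {
    empty <- empty_caller_set()
    return(list(setA = empty, setB = empty, truth = empty_truth()))
  }
  pos <- unlist(lapply(seq_len(nrow(contigs)), function(i) {
    if (counts[i] > 0L) sort(sample.int(contigs$length[i], counts[i])) else integer(0)
  }), use.names = FALSE)

  bases <- c("A", "C", "G", "T")
  ref <- substring(contigs$sequence[idx], pos, pos)
  ref[is.na(ref) | ref == ""] <- sample(bases, sum(is.na(ref) | ref == ""), replace = TRUE)
  alt1 <- pick_other_base(ref)

  j <- config$caller_jaccard
  membership <- sample(c("both", "A", "B"), n, replace = TRUE,
                       prob = c(j, (1 - j) / 2, (1 - j) / 2))
  failed <- rep("none", n)
  both <- membership == "both"
  fail_rows <- both & runif(n) < config$filter_fail_fraction
  failed[fail_rows] <- sample(filter_names(), sum(fail_rows), replace = TRUE)

  # quality annotations (caller A of record): passing values, then the
  # single designated violation per failing site
  ann <- lapply(names(.pass_ranges), function(f) {
    v <- runif(n, .pass_ranges[[f]][1], .pass_ranges[[f]][2])
    bad <- failed == f
    v[bad] <- runif(sum(bad), .fail_ranges[[f]][1], .fail_ranges[[f]][2])
    v
  })
  names(ann) <- names(.pass_ranges)

  depth <- rpois(n, contigs$mean_depth[idx]) + 8L
  maf <- runif(n, 0.1, 0.5)
  alt_n <- rbinom(n, depth, maf)
  alt_n <- pmin(pmax(alt_n, 2L), depth - 2L)
  alt_n[failed == "alt_reads"] <- 1L

  tri <- failed == "biallelic"
  alt2 <- pick_other_base(ref, avoid = alt1)
  alt2_n <- pmax(2L, rbinom(n, depth, 0.15))
  alt_str <- alt1
  alt_reads_str <- as.character(alt_n)
  alt_str[tri] <- paste(alt1[tri], alt2[tri], sep = ",")
  alt_reads_str[tri] <- paste(alt_n[tri], alt2_n[tri], sep = ",")
  alt_total <- alt_n + ifelse(tri, alt2_n, 0L)
  ref_n <- pmax(depth - alt_total, 2L)

  mk_set <- function(keep, caller) {
    df <- data.frame(
      caller_id = caller,
      contig_id = contigs$contig_id[idx][keep],
      pos = pos[keep], ref = ref[keep], alt = alt_str[keep],
      MQ = ann$MQ[keep], MMLQ = ann$MMLQ[keep], QD = ann$QD[keep],
      PP = ann$PP[keep], SbPval = ann$SbPval[keep],
      HapScore = ann$HapScore[keep], MGOF = ann$MGOF[keep], SC = ann$SC[keep],
      ref_reads = ref_n[keep], alt_reads = alt_reads_str[keep],
      stringsAsFactors = FALSE
    )
    if (caller == "B") {
      for (f in names(.pass_ranges)) df[[f]] <- NA_real_
      bd <- rpois(nrow(df), contigs$mean_depth[idx][keep]) + 8L
      ba <- pmin(pmax(rbinom(nrow(df), bd, maf[keep]), 2L), bd - 2L)
      tri_k <- tri[keep]
      df$ref_reads <- bd - ba
      df$alt_reads <- as.character(ba)
      df$alt_reads[tri_k] <- paste(ba[tri_k], alt2_n[keep][tri_k], sep = ",")
    }
    df
  }
  setA <- mk_set(membership != "B", "A")
  setB <- mk_set(membership != "A", "B")

  truth <- data.frame(
    contig_id = contigs$contig_id[idx], pos = pos,
    in_both_callers = both,
    passes_quality = both & failed == "none",
    failed_filter = failed,
    is_singleton = failed == "alt_reads",
    is_biallelic = failed != "biallelic",
    stringsAsFactors = FALSE
  )
  list(setA = setA, setB = setB, truth = truth)
}

pick_other_base <- function(ref, avoid = NULL) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_along(ref), function(i) {
    pool <- setdiff(bases, c(ref[i], avoid[i]))
    pool[sample.int(length(pool), 1L)]
  }, character(1))
}

empty_caller_set <- function() {
  df <- data.frame(caller_id = character(0), contig_id = character(0),
                   pos = integer(0), ref = character(0), alt = character(0),
                   stringsAsFactors = FALSE)
  for (f in names(.pass_ranges)) df[[f]] <- numeric(0)
  df$ref_reads <- integer(0)
  df$alt_reads <- character(0)
  df
}

empty_truth <- function() {
  data.frame(contig_id = character(0), pos = integer(0),
             in_both_callers = logical(0), passes_quality = logical(0),
             failed_filter = character(0), is_singleton = logical(0),
             is_biallelic = logical(0), stringsAsFactors = FALSE)
}

#' Sample Illumina-style functionality scores for SNP candidates
#'
#' Draws assay design scores from a Beta(8, 2.5) distribution, which
#' spans the 0.60 design threshold with most mass above it, emulating the
#' score distribution of submittable Infinium candidates.
#'
#' @param n number of scores.
#' @return numeric vector in `[0, 1]`.
#' @export
sample_functionality_scores <- function(n) {
  rbeta(n, 8, 2.5)
}
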