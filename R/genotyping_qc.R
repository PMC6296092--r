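#' Per-marker genotype statistics
#'
#' For each marker (row) of a calls matrix computes the call rate, allele
#' A frequency `p = (2 nAA + nAB) / (2 n_called)`, observed
#' heterozygosity `Ho = nAB / n_called`, expected heterozygosity
#' `He = 2 p (1 - p)` and the heterozygote-excess statistic `Fe`.
#'
#' `Fe` quantifies how far the marker sits between Hardy-Weinberg
#' proportions (`Fe = 0`) and an obligate-heterozygote pattern (`Fe = 1`,
#' the signature of a probe annealing to two fixed paralogous loci). The
#' default form is `Fe = (Ho - He) / (1 - He)`, clamped to 0 when
#' `Ho <= He`; `fe_mode = "ratio"` gives the alternative `Ho / He - 1`
#' (also clamped at 0). Both agree at the extremes used for
#' classification and both are invariant to swapping the allele labels.
#'
#' @param calls character matrix (markers x samples) with entries `AA`,
#'   `AB`, `BB`, `NC`, or a single marker's vector of calls.
#' @param fe_mode `"standard"` or `"ratio"` (see above).
#' @return data frame with one row per marker: `marker_id` (rownames of
#'   `calls` if present), `call_rate, p, Ho, He, Fe, n_called`. Markers
#'   with no called samples get `NA` statistics.
#' @examples
#' marker_stats(matrix(rep("AB", 10), 1))$Fe # 1: maximal excess
#' @export
marker_stats <- function(calls, fe_mode = c("standard", "ratio")) {
  fe_mode <- match.arg(fe_mode)
  if (is.vector(calls)) calls <- matrix(calls, nrow = 1)
  bad <- !calls %in% c("AA", "AB", "BB", "NC")
  if (any(bad)) {
    stop("marker_stats: invalid genotype call(s): ",
         paste(utils::head(unique(calls[bad]), 3), collapse = ", "))
  }
  nAA <- rowSums(calls == "AA")
  nAB <- rowSums(calls == "AB")
  nBB <- rowSums(calls == "BB")
  nc <- nAA + nAB + nBB
  p <- ifelse(nc > 0, (2 * nAA + nAB) / (2 * nc), NA_real_)
  Ho <- ifelse(nc > 0, nAB / nc, NA_real_)
  He <- 2 * p * (1 - p)
  Fe <- switch(fe_mode,
    standard = ifelse(Ho > He & He < 1, (Ho - He) / (1 - He), 0),
    ratio = ifelse(Ho > He & He > 0, Ho / He - 1, 0)
  )
  Fe[is.na(p)] <- NA_real_
  data.frame(
    marker_id = rownames(calls) %||% sprintf("m%d", seq_len(nrow(calls))),
    call_rate = nc / ncol(calls), p = p, Ho = Ho, He = He, Fe = Fe,
    n_called = nc, nAA = nAA, nAB = nAB, nBB = nBB,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify array markers
#'
#' Assigns each marker one of four exhaustive, mutually exclusive
#' classes, in precedence order mirroring array QC practice (signal gates
#' before genotype-pattern classes):
#'
#' 1. `other_fail` — clustering score below `gentrain_min`, call rate
#'    below `call_rate_min`, or no called samples;
#' 2. `monomorphic` — all called samples in a single homozygous class
#'    (an all-heterozygote marker is *not* monomorphic);
#' 3. `paralogous` — heterozygote excess `Fe >= fe_min`;
#' 4. `valid` otherwise.
#'
#' @param stats per-marker statistics from [marker_stats()].
#' @param gentrain numeric vector of per-marker clustering-quality scores.
#' @param gentrain_min,call_rate_min,fe_min QC gates (defaults 0.13, 0.80,
#'   0.80).
#' @return character vector of classes.
#' @export
classify_markers <- function(stats, gentrain, gentrain_min = 0.13,
                             call_rate_min = 0.80, fe_min = 0.80) {
  stopifnot(length(gentrain) == nrow(stats))
  single_homoz <- stats$n_called > 0 & stats$nAB == 0 &
    (stats$nAA == 0 | stats$nBB == 0)
  klass <- rep("valid", nrow(stats))
  klass[!is.na(stats$Fe) & stats$Fe >= fe_min] <- "paralogous"
  klass[single_homoz] <- "monomorphic"
  klass[gentrain < gentrain_min | stats$call_rate < call_rate_min |
          stats$n_called == 0] <- "other_fail"
  klass
}

#' Replicate concordance of a genotype matrix
#'
#' Over all (marker, replicate-pair) cells in which both replicates
#' received a call, the percentage of identical calls: the internal
#' reproducibility of the array.
#'
#' @param calls character matrix (markers x samples).
#' @param replicate_pairs data frame with columns `sample_id` and
#'   `replicate_id` naming columns of `calls`.
#' @return list with `concordance` (percent), `n_compared` and
#'   `n_discordant`; `NA` with a warning when nothing is comparable.
#' @export
replicate_concordance <- function(calls, replicate_pairs) {
  if (nrow(replicate_pairs) == 0L) {
    warning("replicate_concordance: no replicate pairs")
    return(list(concordance = NA_real_, n_compared = 0L, n_discordant = 0L))
  }
  a <- calls[, replicate_pairs$sample_id, drop = FALSE]
  b <- calls[, replicate_pairs$replicate_id, drop = FALSE]
  both <- a != "NC" & b != "NC"
  n <- sum(both)
  if (n == 0L) {
    warning("replicate_concordance: no cells with both replicates called")
    return(list(concordance = NA_real_, n_compared = 0L, n_discordant = 0L))
  }
  disc <- sum(a[both] != b[both])
  list(concordance = 100 * (n - disc) / n, n_compared = n, n_discordant = disc)
}

#' Genotyping success / true-positive-rate report
#'
#' Tabulates classified markers by SNP source (recycled `control` SNPs
#' versus newly `predicted` ones) into the standard validation
#' accounting: manufactured, valid, monomorphic, paralogous and
#' other-failure counts, plus the success rate (the true positive rate,
#' for predicted SNPs), with a `total` row. Rows always conserve:
#' `n_valid + n_monomorphic + n_paralogous + n_other_fail =
#' n_manufactured`.
#'
#' @param markers data frame with columns `source` (`control` /
#'   `predicted`) and `klass` (a [classify_markers()] output).
#' @return data frame with rows `control`, `predicted`, `total` and
#'   columns `n_manufactured, n_valid, n_monomorphic, n_paralogous,
#'   n_other_fail, n_failed, success_rate, success_rate_1dp`.
#' @export
tpr_report <- function(markers) {
  stopifnot(all(markers$source %in% c("control", "predicted")),
            all(markers$klass %in% c("valid", "monomorphic", "paralogous",
                                     "other_fail")))
  one <- function(df, label) {
    n <- nrow(df)
    v <- sum(df$klass == "valid")
    rate <- if (n > 0) 100 * v / n else NA_real_
    data.frame(
      source = label, n_manufactured = n, n_valid = v,
      n_monomorphic = sum(df$klass == "monomorphic"),
      n_paralogous = sum(df$klass == "paralogous"),
      n_other_fail = sum(df$klass == "other_fail"),
      n_failed = n - v,
      success_rate = rate, success_rate_1dp = round(rate, 1),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    one(markers[markers$source == "control", , drop = FALSE], "control"),
    one(markers[markers$source == "predicted", , drop = FALSE], "predicted"),
    one(markers, "total")
  )
}
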