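#' Generate a synthetic genotyping-array matrix with ground truth
#'
#' Simulates an Infinium-style genotype matrix (markers x samples, calls
#' `AA`/`AB`/`BB`/`NC`). Marker classes are planted in known proportions:
#'
#' * `valid` markers segregate under Hardy-Weinberg at a minor allele
#'   frequency drawn uniformly from `[0.05, 0.5]` (a breeding-population
#'   panel in which rare alleles are under-represented);
#' * `monomorphic` markers have a single homozygous class;
#' * `paralogous` markers emulate probes annealing to two fixed paralogous
#'   loci: near-obligate heterozygotes with `P(AB) = 0.95`;
#' * `other_fail` markers are given a clustering-quality (GenTrain-style)
#'   score below the QC gate.
#'
#' Class-defining draws are rejection-sampled so every marker's realised
#' error-free genotypes actually exhibit its class (a `valid` marker is
#' never monomorphic by chance, a `paralogous` marker always reaches
#' `Fe >= 0.80`). Per-call miscalls and NoCalls are applied afterwards.
#' Two designated replicate sample pairs (re-assays of the first two
#' samples, with independent errors) are appended for concordance testing.
#'
#' @param config a [synth_config()].
#' @return list with
#'   * `calls`: character matrix (markers x samples) of
#'     `AA`/`AB`/`BB`/`NC`;
#'   * `markers`: data frame `marker_id, gentrain_score, source,
#'     true_class`;
#'   * `samples`: data frame `sample_id, replicate_of` (`NA` for
#'     non-replicates);
#'   * `replicate_pairs`: data frame `sample_id, replicate_id`.
#' @export
generate_genotype_matrix <- function(config) {
  validate_synth_config(config)
  set.seed(stage_seed(config, 3L))
  nm <- config$n_markers
  ns <- config$n_samples

  klass <- sample(
    c("paralogous", "monomorphic", "other_fail", "valid"), nm, replace = TRUE,
    prob = c(config$paralog_fraction, config$monomorph_fraction,
             config$other_fail_fraction,
             1 - config$paralog_fraction - config$monomorph_fraction -
               config$other_fail_fraction)
  )
  source <- sample(c("control", "predicted"), nm, replace = TRUE,
                   prob = c(config$control_fraction, 1 - config$control_fraction))
  gentrain <- runif(nm, 0.4, 0.98)
  gentrain[klass == "other_fail"] <- runif(sum(klass == "other_fail"), 0.01, 0.12)

  # replicate columns re-assay samples 1 and 2, so class-defining statistics
  # are checked on the augmented sample vector the QC will actually see
  true_geno <- matrix("AA", nm, ns)
  for (i in seq_len(nm)) {
    true_geno[i, ] <- draw_marker_genotypes(klass[i], ns, rep_idx = 1:2)
  }

  marker_ids <- sprintf("marker%05d", seq_len(nm))
  sample_ids <- sprintf("S%04d", seq_len(ns))
  rep_ids <- paste0(sample_ids[1:2], "_rep")
  # replicate columns share the true genotypes of samples 1 and 2
  true_all <- cbind(true_geno, true_geno[, 1:2, drop = FALSE])
  colnames(true_all) <- c(sample_ids, rep_ids)
  rownames(true_all) <- marker_ids

  calls <- apply_call_noise(true_all, config$genotype_error_rate, config$nocall_rate)

  markers <- data.frame(marker_id = marker_ids, gentrain_score = gentrain,
                        source = source, true_class = klass,
                        stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = colnames(true_all),
    replicate_of = c(rep(NA_character_, ns), sample_ids[1:2]),
    stringsAsFactors = FALSE
  )
  list(calls = calls, markers = markers, samples = samples,
       replicate_pairs = data.frame(sample_id = sample_ids[1:2],
                                    replicate_id = rep_ids,
                                    stringsAsFactors = FALSE))
}

# Internal: error-free genotypes for one marker, rejection-sampled until the
# realised calls (including the duplicated replicate columns) exhibit the
# intended class.
draw_marker_genotypes <- function(klass, ns, rep_idx = integer(0)) {
  if (klass == "monomorphic") {
    return(rep(sample(c("AA", "BB"), 1L), ns))
  }
  if (klass == "paralogous") {
    repeat {
      g <- sample(c("AB", "AA", "BB"), ns, replace = TRUE,
                  prob = c(0.95, 0.025, 0.025))
      st <- genotype_stats(c(g, g[rep_idx]))
      if (!is.na(st["Fe"]) && st["Fe"] >= 0.80) return(g)
    }
  }
  # valid (and the genotype pattern of other_fail markers, whose failure is
  # carried by the low clustering score, not the genotypes)
  repeat {
    m <- runif(1, 0.05, 0.5)
    g <- sample(c("AA", "AB", "BB"), ns, replace = TRUE,
                prob = c((1 - m)^2, 2 * m * (1 - m), m^2))
    ga <- c(g, g[rep_idx])
    st <- genotype_stats(ga)
    polymorphic <- st["Ho"] > 0 && sum(c("AA", "AB", "BB") %in% ga) >= 2
    if (polymorphic && st["Fe"] < 0.80) return(g)
  }
}

# Internal: p, Ho, He, Fe of a vector of error-free genotype calls.
genotype_stats <- function(g) {
  nAA <- sum(g == "AA"); nAB <- sum(g == "AB"); nBB <- sum(g == "BB")
  nc <- nAA + nAB + nBB
  p <- (2 * nAA + nAB) / (2 * nc)
  Ho <- nAB / nc
  He <- 2 * p * (1 - p)
  Fe <- if (He < 1 && Ho > He) (Ho - He) / (1 - He) else 0
  c(p = p, Ho = Ho, He = He, Fe = Fe)
}

# Internal: per-call miscalls and NoCalls.
apply_call_noise <- function(true_calls, error_rate, nocall_rate) {
  out <- true_calls
  n <- length(out)
  if (error_rate > 0) {
    flip <- which(runif(n) < error_rate)
    states <- c("AA", "AB", "BB")
    for (i in flip) {
      out[i] <- sample(setdiff(states, out[i]), 1L)
    }
  }
  if (nocall_rate > 0) {
    out[runif(n) < nocall_rate] <- "NC"
  }
  out
}
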