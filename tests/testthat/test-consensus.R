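mk_var <- function(contig_id = "c1", pos = 100, ref = "A", alt = "T",
                   MQ = 40, MMLQ = 20, QD = 20, PP = 50, SbPval = 0.5,
                   HapScore = 30, MGOF = 40, SC = 0.98, ref_reads = 50,
                   alt_reads = "30", caller_id = "A") {
  data.frame(caller_id = caller_id, contig_id = contig_id, pos = pos,
             ref = ref, alt = alt, MQ = MQ, MMLQ = MMLQ, QD = QD, PP = PP,
             SbPval = SbPval, HapScore = HapScore, MGOF = MGOF, SC = SC,
             ref_reads = ref_reads, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}

test_that("set algebra of the intersection behaves on identical, disjoint and published counts", {
  a <- mk_var(pos = c(10, 20, 30))
  expect_identical(intersect_callsets(a, a)$n_common, 3L)
  expect_identical(intersect_callsets(a, a)$union_size, 3L)
  b <- mk_var(pos = c(40, 50), caller_id = "B")
  res <- intersect_callsets(a, b)
  expect_identical(res$n_common, 0L)
  expect_identical(res$union_size, 5L)
  expect_identical(union_size(115336, 191334, 68004), 238666)
})

test_that("a common site requires identical normalized alleles; duplicates are rejected", {
  a <- mk_var(pos = c(10, 20), alt = c("T", "G"))
  b <- mk_var(pos = c(10, 20), alt = c("t", "C"), caller_id = "B")
  res <- intersect_callsets(a, b)
  expect_identical(res$n_common, 1L)  # case-insensitive match at pos 10 only
  expect_identical(res$common$pos, 10)
  dup <- mk_var(pos = c(10, 10))
  expect_error(intersect_callsets(dup, b), "duplicate.*c1:10")
})

test_that("each quality gate rejects at its printed boundary and is audited", {
  base <- intersect_callsets(mk_var(), mk_var(caller_id = "B"))$common
  for (case in list(list(field = "SC", value = 0.94),
                    list(field = "MQ", value = 19.9),
                    list(field = "SbPval", value = 0.009),
                    list(field = "MGOF", value = 19))) {
    v <- base
    v[[case$field]] <- case$value
    res <- apply_quality_filters(v)
    expect_identical(nrow(res$passing), 0L)
    expect_identical(unname(res$audit[case$field]), 1L)
    expect_identical(sum(res$audit), 1L)
  }
  # singleton exclusion: one alternative read
  v <- base; v$alt_reads <- "1"
  res <- apply_quality_filters(v)
  expect_identical(nrow(res$passing), 0L)
  expect_identical(unname(res$audit["alt_reads"]), 1L)
  # tri-allelic exclusion
  v <- base; v$alt <- "T,G"; v$alt_reads <- "20,10"
  expect_identical(unname(apply_quality_filters(v)$audit["biallelic"]), 1L)
})

test_that("the max-goodness-of-fit gate can be inverted by configuration", {
  v <- intersect_callsets(mk_var(MGOF = 40), mk_var(MGOF = 40, caller_id = "B"))$common
  expect_identical(nrow(apply_quality_filters(v)$passing), 1L)
  expect_identical(nrow(apply_quality_filters(v, mgof_invert = TRUE)$passing), 0L)
})

test_that("a missing annotation raises an error naming site and field", {
  v <- intersect_callsets(mk_var(), mk_var(caller_id = "B"))$common
  v$QD <- NA_real_
  expect_error(apply_quality_filters(v), "QD.*c1:100")
})

test_that("consensus filtering recovers the planted truth exactly on synthetic sets", {
  cfg <- synth_config(n_contigs = 400, n_genes = 300,
                      filter_fail_fraction = 0.3, rng_seed = 9)
  ref <- generate_reference(cfg)
  cs <- generate_caller_sets(ref$contigs, cfg)
  expect_gte(sum(cs$truth$in_both_callers), 1000)
  inter <- intersect_callsets(cs$setA, cs$setB)
  res <- apply_quality_filters(inter$common)
  truth_pass <- cs$truth[cs$truth$passes_quality, ]
  expect_identical(nrow(res$passing), nrow(truth_pass))
  expect_setequal(site_key(res$passing), site_key(truth_pass))
  planted <- table(cs$truth$failed_filter[cs$truth$in_both_callers])
  for (f in setdiff(names(planted), "none")) {
    expect_identical(unname(res$audit[f]), as.integer(planted[[f]]))
  }
})

test_that("flank extraction truncates at contig ends exactly", {
  seq400 <- paste(rep("ACGT", 100), collapse = "")
  fl <- extract_flanks(seq400, 1)
  expect_identical(fl$flank_up, "")
  expect_identical(nchar(fl$flank_down), 100L)
  fl <- extract_flanks(seq400, 150)
  expect_identical(nchar(fl$flank_up), 100L)
  expect_identical(nchar(fl$flank_down), 100L)
  # direct slicing oracle near the downstream end
  pos <- 400 - 30
  fl <- extract_flanks(seq400, pos)
  expect_identical(fl$flank_down, substr(seq400, pos + 1, 400))
  expect_identical(nchar(fl$flank_down), 30L)
  expect_identical(fl$flank_up, substr(seq400, pos - 100, pos - 1))
  expect_error(extract_flanks(seq400, 401), "outside")
})

test_that("catalog rows carry correct MAF, depth and flanks", {
  contigs <- data.frame(contig_id = "c1", gene_id = "g1", length = 400,
                        mean_depth = 50,
                        sequence = paste(rep("ACGT", 100), collapse = ""),
                        stringsAsFactors = FALSE)
  passing <- mk_var(pos = 150, ref_reads = 30, alt_reads = "70")
  cat1 <- build_catalog(passing, contigs)
  expect_equal(cat1$depth, 100)
  expect_equal(cat1$maf, 0.3)  # min(f, 1-f) with f = 0.7
  expect_identical(nchar(cat1$flank_up), 100L)
  expect_identical(cat1$gene_id, "g1")
  expect_true(all(cat1$maf >= 0 & cat1$maf <= 0.5))
})

test_that("catalog accounting reproduces the published per-gene arithmetic", {
  r <- catalog_ratios(61771, 13543, 16516)
  expect_identical(r$snps_per_snped_gene_2dp, 4.56)
  expect_identical(r$snps_per_gene_all_2dp, 3.74)
  expect_identical(r$n_unsnped_genes, 2973)
  expect_identical(sites_per_snp(0.234), 427)
})

test_that("summarize_catalog flags the degenerate zero-gene case", {
  empty <- build_catalog(mk_var()[0, ],
                         data.frame(contig_id = character(0),
                                    gene_id = character(0),
                                    length = numeric(0),
                                    mean_depth = numeric(0),
                                    sequence = character(0)))
  s <- summarize_catalog(empty, character(0), numeric(0))
  expect_true(s$undefined)
  expect_true(is.na(s$snps_per_gene_all))
})
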