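test_that("generators are deterministic under the configured seed", {
  cfg <- small_config(n_contigs = 30, n_genes = 20)
  expect_identical(generate_reference(cfg), generate_reference(cfg))
  ref <- generate_reference(cfg)
  expect_identical(generate_caller_sets(ref$contigs, cfg),
                   generate_caller_sets(ref$contigs, cfg))
  expect_identical(generate_genotype_matrix(cfg), generate_genotype_matrix(cfg))
  expect_identical(generate_annotations(cfg), generate_annotations(cfg))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synth_config(caller_jaccard = 1.5), "caller_jaccard")
  expect_error(synth_config(n_samples = 2), "n_samples")
  expect_error(synth_config(contig_len_range = c(150, 800)), "contig_len_range")
  expect_error(synth_config(paralog_fraction = -0.1), "paralog_fraction")
})

test_that("a depth range outside the coverage window rejects every hit", {
  cfg <- small_config(mean_depth_range = c(900, 1000))
  ref <- generate_reference(cfg)
  expect_identical(nrow(filter_hits(ref$hits)), 0L)
})

test_that("random gene assignment yields multi-contig genes matching the assignment table", {
  cfg <- synth_config(n_contigs = 200, n_genes = 150, rng_seed = 5)
  ref <- generate_reference(cfg, sequences = FALSE)
  per_gene <- table(ref$gene_map$gene_id)
  expect_gt(sum(per_gene >= 2), 0)
  # output contigs agree with the generator's own assignment table
  expect_identical(as.integer(table(ref$contigs$gene_id)[names(per_gene)]),
                   as.integer(per_gene))
})

test_that("realized caller-set Jaccard is within 0.05 of the configured value", {
  for (j in c(0.2, 0.5, 0.8)) {
    cfg <- synth_config(n_contigs = 400, n_genes = 300, caller_jaccard = j,
                        rng_seed = 11)
    ref <- generate_reference(cfg, sequences = FALSE)
    cs <- generate_caller_sets(ref$contigs, cfg)
    expect_gte(nrow(cs$truth), 1000)
    realized <- sum(cs$truth$in_both_callers) / nrow(cs$truth)
    expect_lt(abs(realized - j), 0.05)
  }
})

test_that("degenerate Jaccard values collapse the consensus as expected", {
  cfg <- small_config(caller_jaccard = 1, filter_fail_fraction = 0)
  ref <- generate_reference(cfg)
  cs <- generate_caller_sets(ref$contigs, cfg)
  inter <- intersect_callsets(cs$setA, cs$setB)
  passing <- apply_quality_filters(inter$common)$passing
  expect_setequal(site_key(passing), site_key(cs$setA))

  cfg0 <- small_config(caller_jaccard = 0)
  cs0 <- generate_caller_sets(ref$contigs, cfg0)
  expect_identical(intersect_callsets(cs0$setA, cs0$setB)$n_common, 0L)
})

test_that("every emitted variant and marker has exactly one ground-truth record", {
  cfg <- small_config()
  ref <- generate_reference(cfg)
  cs <- generate_caller_sets(ref$contigs, cfg)
  emitted <- unique(c(site_key(cs$setA), site_key(cs$setB)))
  expect_setequal(site_key(cs$truth), emitted)
  expect_false(anyDuplicated(site_key(cs$truth)) > 0)

  gt <- generate_genotype_matrix(cfg)
  expect_identical(nrow(gt$markers), cfg$n_markers)
  expect_false(anyDuplicated(gt$markers$marker_id) > 0)
  expect_true(all(gt$markers$true_class %in%
                    c("valid", "monomorphic", "paralogous", "other_fail")))
})

test_that("an error-free matrix with no planted failures is all valid and fully concordant", {
  cfg <- small_config(paralog_fraction = 0, monomorph_fraction = 0,
                      other_fail_fraction = 0, genotype_error_rate = 0,
                      nocall_rate = 0)
  gt <- generate_genotype_matrix(cfg)
  expect_true(all(gt$markers$true_class == "valid"))
  st <- marker_stats(gt$calls)
  expect_true(all(classify_markers(st, gt$markers$gentrain_score) == "valid"))
  expect_equal(replicate_concordance(gt$calls, gt$replicate_pairs)$concordance,
               100)
})

test_that("planted paralog-like markers reach the heterozygote-excess gate", {
  cfg <- small_config(paralog_fraction = 1, monomorph_fraction = 0,
                      other_fail_fraction = 0, genotype_error_rate = 0,
                      nocall_rate = 0, n_markers = 40)
  gt <- generate_genotype_matrix(cfg)
  st <- marker_stats(gt$calls)
  expect_true(all(st$Fe >= 0.80))
})

test_that("the GO DAG obeys the true-path rule and carries planted enrichment", {
  cfg <- small_config()
  ann <- generate_annotations(cfg)
  full <- propagate_go(go_pairs(ann$annotations), ann$go_edges)
  # root accumulates every annotated gene (reachability oracle)
  root_genes <- unique(full$gene_id[full$term == "GO:0000001"])
  expect_setequal(root_genes, unique(go_pairs(ann$annotations)$gene_id))
  expect_true(ann$truth$enriched_family %in% ann$annotations$family)
  mult <- ann$truth$rate_multiplier
  expect_setequal(names(mult), ann$annotations$gene_id)
  boosted <- names(mult)[mult > 1]
  fam_genes <- ann$annotations$gene_id[
    !is.na(ann$annotations$family) &
      ann$annotations$family == ann$truth$enriched_family]
  expect_true(all(fam_genes %in% boosted))
})
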