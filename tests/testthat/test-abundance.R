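test_that("beta matches its closed cases and rejects its domain errors", {
  expect_equal(snp_beta(0, 100, 2), 0.01)               # harmonic sum = 1
  expect_equal(snp_beta(4, 1000, 10), 0.005 / harmonic_loop(9))
  expect_equal(snp_beta(4, 1000, 10), 0.005 / 2.8289682539682538)
  expect_gt(snp_beta(9, 1000, 2), snp_beta(9, 1000, 100))  # decreasing in D
  expect_error(snp_beta(1, 100, 1.9), "floor\\(D\\)")
  expect_error(snp_beta(1, 0, 10), "L")
  expect_error(snp_beta(-1, 100, 10), "S")
})

test_that("the interpolated-depth mode agrees with flooring at integer depths", {
  expect_equal(snp_beta(3, 500, 25, d_mode = "digamma"),
               snp_beta(3, 500, 25, d_mode = "floor"))
  # and lies between the floor values of the bracketing integers otherwise
  lo <- snp_beta(3, 500, 26, d_mode = "floor")
  hi <- snp_beta(3, 500, 25, d_mode = "floor")
  mid <- snp_beta(3, 500, 25.5, d_mode = "digamma")
  expect_true(mid > lo && mid < hi)
})

test_that("beta is monotone: increasing in S, decreasing in floor(D), non-negative", {
  grid_S <- 0:20
  expect_true(all(diff(snp_beta(grid_S, 1000, 50)) > 0))
  grid_D <- 2:100
  expect_true(all(diff(snp_beta(5, 1000, grid_D)) < 0))
  expect_true(all(snp_beta(grid_S, 1000, 50) >= 0))
})

test_that("gene beta is the length-weighted mean and stays within part range", {
  parts <- data.frame(L = c(500, 1500), beta = c(0.002, 0.004))
  expect_equal(gene_beta(parts), 0.0035)
  expect_equal(gene_beta(data.frame(L = 800, beta = 0.01)), 0.01)
  same <- data.frame(L = c(100, 900, 5000), beta = 0.007)
  expect_equal(gene_beta(same), 0.007)
  set.seed(31)
  rnd <- data.frame(L = runif(10, 100, 2000), beta = runif(10, 0, 0.01))
  expect_true(gene_beta(rnd) >= min(rnd$beta) && gene_beta(rnd) <= max(rnd$beta))
  expect_error(gene_beta(rnd[0, ]), "non-empty")
})

test_that("ranking flags floor(decile * N) genes and is a permutation", {
  genes <- data.frame(gene_id = sprintf("g%05d", 1:16516),
                      beta_weighted = runif(16516), S_total = 1)
  r <- rank_genes(genes)
  expect_identical(sum(r$top_decile), 1651L)
  expect_setequal(r$gene_id, genes$gene_id)
  expect_identical(r$rank, 1:16516)

  ten <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    beta_weighted = runif(10), S_total = 1)
  expect_identical(sum(rank_genes(ten)$top_decile), 1L)

  tied <- data.frame(gene_id = c("gB", "gA", "gC"), beta_weighted = 1,
                     S_total = c(5, 5, 9))
  r <- rank_genes(tied, decile = 0.5)
  expect_identical(r$gene_id, c("gC", "gA", "gB"))  # S_total, then gene id
  expect_error(rank_genes(ten, decile = 0), "decile")
  expect_error(rank_genes(ten, decile = 1), "decile")
})

test_that("contig abundance counts SNPs per contig and drops shallow contigs", {
  contigs <- data.frame(contig_id = c("c1", "c2", "c3"),
                        gene_id = c("g1", "g1", "g2"),
                        length = c(1000, 800, 600),
                        mean_depth = c(50, 1.5, 30),
                        stringsAsFactors = FALSE)
  catalog <- data.frame(contig_id = c("c1", "c1", "c3"))
  expect_message(ca <- contig_abundance(catalog, contigs), "excluded")
  expect_identical(ca$contig_id, c("c1", "c3"))
  expect_identical(ca$S, c(2L, 1L))
  expect_equal(ca$beta, snp_beta(c(2, 1), c(1000, 600), c(50, 30)))
})

test_that("beta removes the depth trend that raw density carries under coupled discovery", {
  cfg <- synth_config(n_contigs = 2000, n_genes = 1000, rng_seed = 13,
                      depth_coupled = TRUE)
  ref <- generate_reference(cfg, sequences = FALSE)
  S <- simulate_snp_counts(ref$contigs, cfg)
  ca <- data.frame(contig_id = ref$contigs$contig_id, gene_id = "g", S = S,
                   L = ref$contigs$length, D = ref$contigs$mean_depth,
                   beta = snp_beta(S, ref$contigs$length,
                                   ref$contigs$mean_depth))
  r <- depth_correlation(ca)
  expect_false(r$undefined)
  expect_gt(r$r_raw, 0.1)           # discovery rises with depth
  expect_lt(abs(r$r_beta), 0.1)     # beta inverts the coupling
  expect_lt(abs(r$r_beta), abs(r$r_raw))
  # a perfectly linear raw density gives r_raw = 1
  lin <- data.frame(contig_id = as.character(1:10), gene_id = "g",
                    S = (1:10) * 10, L = 1000, D = (1:10) * 10 + 20,
                    beta = snp_beta((1:10) * 10, 1000, (1:10) * 10 + 20))
  expect_equal(depth_correlation(lin)$r_raw, 1)
})

test_that("zero-variance inputs are flagged undefined", {
  flat <- data.frame(contig_id = as.character(1:5), gene_id = "g", S = 3,
                     L = 1000, D = 50, beta = snp_beta(3, 1000, 50))
  expect_warning(r <- depth_correlation(flat), "undefined")
  expect_true(r$undefined)
})
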