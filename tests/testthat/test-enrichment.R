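chain_edges <- data.frame(child = c("t3", "t2", "t1"),
                          parent = c("t2", "t1", "root"),
                          stringsAsFactors = FALSE)

test_that("true-path propagation annotates every ancestor and is idempotent", {
  direct <- data.frame(gene_id = "g1", term = "t3")
  full <- propagate_go(direct, chain_edges)
  expect_setequal(full$term, c("t3", "t2", "t1", "root"))
  expect_identical(nrow(full), 4L)
  expect_identical(propagate_go(full, chain_edges)[order(propagate_go(full, chain_edges)$term), ],
                   full[order(full$term), ])
})

test_that("propagated counts at the root match a reachability oracle on a random DAG", {
  set.seed(404)
  terms <- sprintf("t%02d", 1:30)
  edges <- data.frame(
    child = terms[2:30],
    parent = vapply(2:30, function(i) terms[sample.int(i - 1, 1)], character(1))
  )
  direct <- data.frame(gene_id = sprintf("g%03d", 1:100),
                       term = sample(terms, 100, TRUE))
  full <- propagate_go(direct, edges)
  expect_identical(sort(unique(full$gene_id[full$term == "t01"])),
                   sort(unique(direct$gene_id)))
  # parent counts never drop below child counts (monotonicity)
  counts <- table(full$term)
  for (k in seq_len(nrow(edges))) {
    expect_gte(counts[[edges$parent[k]]], counts[[edges$child[k]]])
  }
})

test_that("a cyclic edge list is rejected with a cycle edge named", {
  cyc <- rbind(chain_edges, data.frame(child = "t1", parent = "t3"))
  expect_error(propagate_go(data.frame(gene_id = "g", term = "t3"), cyc),
               "cycle")
})

test_that("one-sided term p-values equal the explicit hypergeometric tail sum", {
  expect_equal(fisher.test(matrix(c(10, 5, 90, 895), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               hyper_p_greater(10, 5, 90, 895), tolerance = 1e-12)
  universe <- sprintf("g%04d", 1:1000)
  top <- universe[1:15]
  direct <- data.frame(gene_id = universe[1:100], term = "t3")
  full <- propagate_go(direct, chain_edges)
  res <- fisher_term_tests(full, top, universe)
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p_value[k],
                 hyper_p_greater(res$a[k], res$b[k], res$c[k], res$d[k]),
                 tolerance = 1e-12)
  }
})

test_that("a term covering the whole universe cannot be enriched", {
  universe <- sprintf("g%03d", 1:50)
  full <- data.frame(gene_id = universe, term = "all")
  res <- fisher_term_tests(full, universe[1:5], universe)
  expect_equal(res$p_value, 1)
})

test_that("terms below nodesize are not tested", {
  universe <- sprintf("g%03d", 1:50)
  full <- rbind(data.frame(gene_id = universe[1:4], term = "small"),
                data.frame(gene_id = universe[1:10], term = "big"))
  res <- fisher_term_tests(full, universe[1:5], universe, nodesize = 5)
  expect_identical(res$category, "big")
})

test_that("elim with alpha 0 reduces to classic, and removes significant children's genes otherwise", {
  cfg <- small_config()
  ann <- generate_annotations(cfg)
  direct <- go_pairs(ann$annotations)
  full <- propagate_go(direct, ann$go_edges)
  universe <- unique(full$gene_id)
  set.seed(5)
  top <- sample(universe, 20)
  classic <- fisher_term_tests(full, top, universe, method = "classic")
  elim0 <- fisher_term_tests(full, top, universe, method = "elim",
                             alpha_elim = 0, edges = ann$go_edges)
  m <- match(classic$category, elim0$category)
  expect_equal(classic$p_value, elim0$p_value[m], tolerance = 1e-12)
  # with a strongly enriched leaf, elimination weakens its ancestors
  enr_genes <- unique(full$gene_id[full$term == ann$truth$enriched_term])
  top_enr <- unique(c(enr_genes, sample(universe, 5)))
  elim1 <- fisher_term_tests(full, top_enr, universe, method = "elim",
                             alpha_elim = 0.01, edges = ann$go_edges)
  classic1 <- fisher_term_tests(full, top_enr, universe, method = "classic")
  parents <- ann$go_edges$parent[ann$go_edges$child == ann$truth$enriched_term]
  for (p in intersect(parents, elim1$category)) {
    expect_gte(elim1$p_value[elim1$category == p],
               classic1$p_value[classic1$category == p])
  }
})

test_that("family tests honour the min-in-top rule and match the two-sided oracle", {
  universe <- sprintf("g%04d", 1:1000)
  ann <- data.frame(
    gene_id = universe,
    family = c(rep("famA", 100), rep("famB", 50), rep("famC", 3),
               rep(NA, 847)),
    stringsAsFactors = FALSE
  )
  top <- c(universe[1:20],    # 20 of famA in top
           universe[101],     # only 1 of famB: excluded
           universe[500:578])
  res <- family_tests(ann, top, universe)
  expect_identical(res$category, "famA")
  expect_equal(res$p_value,
               hyper_p_twosided(res$a, res$b, res$c, res$d), tolerance = 1e-10)
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("under a null annotation, BH-corrected family tests rarely call anything", {
  universe <- sprintf("g%04d", 1:2000)
  hits <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    fam <- sprintf("F%02d", 1 + (sample.int(69, 2000, TRUE) - 1))
    ann <- data.frame(gene_id = universe, family = fam)
    top <- sample(universe, 200)
    res <- family_tests(ann, top, universe)
    sum(res$p_adjusted < 0.05) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("flag tests report group proportions and handle empty flags", {
  universe <- sprintf("g%04d", 1:1000)
  ann <- data.frame(gene_id = universe, orphan = FALSE,
                    conifer_specific = c(rep(TRUE, 40), rep(FALSE, 960)))
  # strong excess of the flag in the top set
  top <- c(universe[1:30], universe[501:570])
  res <- flag_tests(ann, top, universe, "conifer_specific")
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, hyper_p_twosided(res$a, res$b, res$c, res$d),
               tolerance = 1e-10)
  expect_equal(res$prop_top, 100 * 30 / 100)
  expect_equal(res$prop_rest, 100 * 10 / 900)
  # no flagged genes at all: p = 1, zero proportions
  res0 <- flag_tests(ann, top, universe, "orphan")
  expect_equal(res0$p_value, 1)
  expect_equal(res0$prop_top, 0)
  expect_equal(res0$prop_rest, 0)
})
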