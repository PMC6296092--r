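#' Expand a semicolon-separated GO column to gene-term pairs
#'
#' @param annotations data frame with `gene_id` and `go_terms`
#'   (semicolon-separated direct annotations; empty string = none).
#' @return data frame with columns `gene_id, term`.
#' @export
go_pairs <- function(annotations) {
  terms <- strsplit(annotations$go_terms, ";", fixed = TRUE)
  n <- lengths(terms)
  out <- data.frame(gene_id = rep(annotations$gene_id, n),
                    term = unlist(terms, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out[out$term != "", , drop = FALSE]
}

#' Propagate GO annotations up the DAG (true-path rule)
#'
#' Annotates every gene to all ancestors of each of its direct terms.
#' Idempotent; terms absent from the DAG are kept as isolated terms.
#'
#' @param direct data frame `gene_id, term` of direct annotations.
#' @param edges data frame `child, parent` of is-a edges.
#' @return data frame `gene_id, term` including all implied ancestors.
#' @export
propagate_go <- function(direct, edges) {
  g <- go_graph(edges, extra_terms = unique(direct$term))
  anc <- term_ancestors(g)
  per_term <- anc[direct$term]
  n <- lengths(per_term)
  out <- data.frame(gene_id = rep(direct$gene_id, n),
                    term = unlist(per_term, use.names = FALSE),
                    stringsAsFactors = FALSE)
  unique(out)
}

# Internal: build the child -> parent igraph and fail on cycles, naming an
# edge inside a cycle.
go_graph <- function(edges, extra_terms = character(0)) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = unique(c(edges$child, edges$parent, extra_terms))
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    in_cyc <- edges$child %in% cyc & edges$parent %in% cyc
    stop(sprintf("GO edge list contains a cycle (e.g. edge %s -> %s)",
                 edges$child[in_cyc][1], edges$parent[in_cyc][1]))
  }
  g
}

# Internal: named list term -> character vector of the term and all its
# ancestors.
term_ancestors <- function(g) {
  vs <- igraph::V(g)$name
  out <- lapply(vs, function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })
  names(out) <- vs
  out
}

# Internal: longest-path depth of each term from the roots (roots = 0).
term_depths <- function(g) {
  ord <- igraph::topo_sort(g, mode = "in")  # parents before children
  depth <- setNames(rep(0L, igraph::vcount(g)), igraph::V(g)$name)
  for (v in ord$name) {
    parents <- names(igraph::neighbors(g, v, mode = "out"))
    if (length(parents)) depth[v] <- max(depth[parents]) + 1L
  }
  depth
}

# Internal: one-sided (over-representation) or two-sided Fisher test rows
# for a set of categories given as a named list of gene vectors.
fisher_rows <- function(cat_genes, top_set, universe, alternative) {
  N <- length(universe)
  n_top <- length(top_set)
  res <- lapply(names(cat_genes), function(id) {
    genes <- intersect(cat_genes[[id]], universe)
    a <- length(intersect(genes, top_set))
    b <- n_top - a
    c_ <- length(genes) - a
    d <- N - n_top - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = alternative)
    data.frame(category = id, n_genes = length(genes), a = a, b = b,
               c = c_, d = d, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Fisher's exact enrichment tests of GO terms in the top genes
#'
#' Tests each GO term (with at least `nodesize` annotated genes in the
#' universe) for over-representation among the top genes with a one-sided
#' Fisher's exact test on the propagated annotations. `method = "elim"`
#' processes terms leaves-upward: when a term is significant at
#' `alpha_elim`, its genes are removed from all its ancestors before those
#' are tested, concentrating the signal on the most specific terms.
#' Raw (non-adjusted) p-values are reported, as is conventional for
#' hierarchy-aware GO tests.
#'
#' @param full_ann propagated annotations from [propagate_go()].
#' @param top_set character vector of top-decile gene ids (a subset of
#'   `universe`).
#' @param universe character vector of all genes in the tested universe
#'   (conventionally only genes bearing annotations in the namespace).
#' @param nodesize minimum number of annotated genes for a term to be
#'   tested.
#' @param method `"classic"` or `"elim"`.
#' @param alpha_elim significance level at which a child term's genes are
#'   eliminated from its ancestors (`0` disables elimination, recovering
#'   `classic`).
#' @param edges GO edge list (`child, parent`), required for `elim`.
#' @return data frame sorted by p-value with columns `category, n_genes,
#'   a, b, c, d, odds_ratio, p_value, method`.
#' @export
fisher_term_tests <- function(full_ann, top_set, universe, nodesize = 5,
                              method = c("classic", "elim"),
                              alpha_elim = 0.01, edges = NULL) {
  method <- match.arg(method)
  if (length(universe) == 0L) stop("fisher_term_tests: empty universe")
  if (!all(top_set %in% universe)) {
    stop("fisher_term_tests: top_set must be a subset of the universe")
  }
  ann <- full_ann[full_ann$gene_id %in% universe, , drop = FALSE]
  cat_genes <- split(ann$gene_id, ann$term)
  cat_genes <- cat_genes[lengths(cat_genes) >= nodesize]
  if (length(cat_genes) == 0L) {
    return(cbind(fisher_rows(list(), top_set, universe, "greater")[0, ],
                 method = character(0)))
  }
  if (method == "classic") {
    out <- fisher_rows(cat_genes, top_set, universe, "greater")
    out$method <- "classic"
    return(out)
  }
  if (is.null(edges)) stop("fisher_term_tests: method 'elim' needs the GO edge list")
  g <- go_graph(edges, extra_terms = names(cat_genes))
  anc <- term_ancestors(g)
  depth <- term_depths(g)
  terms <- names(cat_genes)
  terms <- terms[order(-depth[terms], terms)]  # leaves first
  removed <- lapply(setNames(terms, terms), function(t) character(0))
  rows <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    t <- terms[k]
    pruned <- setdiff(cat_genes[[t]], removed[[t]])
    rows[[k]] <- fisher_rows(setNames(list(pruned), t), top_set, universe,
                             "greater")
    if (rows[[k]]$p_value < alpha_elim) {
      for (aterm in setdiff(anc[[t]], t)) {
        if (aterm %in% names(removed)) {
          removed[[aterm]] <- union(removed[[aterm]], cat_genes[[t]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  out$method <- "elim"
  rownames(out) <- NULL
  out
}

#' Fisher's exact tests of gene-family representation in the top genes
#'
#' Families represented by at least `min_in_top` genes in the top set are
#' tested with a two-sided Fisher's exact test for differential
#' representation; p-values are Benjamini-Hochberg adjusted across the
#' tested families by default.
#'
#' @param annotations data frame with `gene_id` and `family` (`NA` =
#'   orphan).
#' @param top_set,universe as in [fisher_term_tests()].
#' @param min_in_top minimum number of family members in the top set for
#'   the family to be tested.
#' @param adjust `"BH"` or `"none"`.
#' @return data frame sorted by p-value with the 2x2 counts, `p_value`
#'   and `p_adjusted`.
#' @export
family_tests <- function(annotations, top_set, universe, min_in_top = 2,
                         adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  ann <- annotations[annotations$gene_id %in% universe &
                       !is.na(annotations$family), , drop = FALSE]
  fam_genes <- split(ann$gene_id, ann$family)
  in_top <- vapply(fam_genes, function(g) length(intersect(g, top_set)),
                   integer(1))
  fam_genes <- fam_genes[in_top >= min_in_top]
  if (length(fam_genes) == 0L) {
    out <- fisher_rows(list(), top_set, universe, "two.sided")[0, ]
    out$p_adjusted <- numeric(0)
    return(out)
  }
  out <- fisher_rows(fam_genes, top_set, universe, "two.sided")
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else
    out$p_value
  out
}

#' Fisher's exact test of a gene flag in the top genes
#'
#' Single two-sided 2x2 test of whether flagged genes (orphans or
#' conifer-specific genes) are differentially represented among the top
#' genes, with the flagged proportion in each group.
#'
#' @param annotations data frame with `gene_id` and logical columns
#'   `orphan` and `conifer_specific`.
#' @param top_set,universe as in [fisher_term_tests()].
#' @param flag `"orphan"` or `"conifer_specific"`.
#' @return list with the 2x2 counts, `prop_top` and `prop_rest`
#'   (percent), `odds_ratio` and `p_value`.
#' @export
flag_tests <- function(annotations, top_set, universe,
                       flag = c("orphan", "conifer_specific")) {
  flag <- match.arg(flag)
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  flagged <- ann$gene_id[ann[[flag]]]
  row <- fisher_rows(setNames(list(flagged), flag), top_set, universe,
                     "two.sided")
  n_top <- length(top_set)
  n_rest <- length(universe) - n_top
  list(flag = flag, a = row$a, b = row$b, c = row$c, d = row$d,
       prop_top = if (n_top > 0) 100 * row$a / n_top else NA_real_,
       prop_rest = if (n_rest > 0) 100 * row$c / n_rest else NA_real_,
       odds_ratio = row$odds_ratio, p_value = row$p_value)
}
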