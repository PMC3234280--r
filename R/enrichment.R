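#' Hypergeometric over-representation of a gene class in gene sets
#'
#' For each set, tests whether membership of the class genes in the set
#' exceeds what drawing the class uniformly from the universe would give:
#' with `N` universe genes of which `K` are in the set and a class of
#' size `n` containing `k` set members, the p-value is the exact upper
#' tail `P(X >= k)` of Hypergeometric(N, K, n). One-sided
#' over-representation only; BH q-values across the sets.
#'
#' @param class_genes character vector of genes in the feature class;
#'   genes outside the universe are dropped.
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param universe character vector of analyzable genes (typically the
#'   genes with all three modalities observed).
#' @param fdr_level FDR cutoff recorded in the `significant` column.
#' @return data.frame `set_id`, `k`, `K`, `n`, `N`, `p_value`, `q_value`,
#'   `significant`, sorted by q then p. Sets disjoint from the universe
#'   are dropped with a warning.
#' @export
hypergeometric_enrichment <- function(class_genes, gene_sets, universe,
                                      fdr_level = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_input("empty universe")
  class_genes <- unique(intersect(class_genes, universe))
  if (length(class_genes) == 0) stop_input("empty gene class")
  members <- lapply(gene_sets, intersect, universe)
  empty <- vapply(members, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf("%d set(s) disjoint from the universe dropped", sum(empty)))
    members <- members[!empty]
  }
  if (length(members) == 0) {
    return(data.frame(set_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(class_genes)
  K <- vapply(members, length, integer(1))
  k <- vapply(members, function(m) length(intersect(m, class_genes)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    set_id = names(members), k = k, K = K, n = n, N = N,
    p_value = p, q_value = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$significant <- res$q_value < fdr_level
  res[order(res$q_value, res$p_value, res$set_id), , drop = FALSE]
}
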