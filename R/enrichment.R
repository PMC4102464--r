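#' Select the top fraction of consistently differential genes
#'
#' Eligible genes are those inside the consistency band; they are ranked by
#' mean RD (descending for `P>W`, ascending for `W>P`) and the top
#' `round(fraction * eligible_count)` taken, with boundary ties broken by
#' lexicographic gene id.
#'
#' @param diff_table a [classify_differential()] table.
#' @param fraction fraction of eligible genes to take (in (0, 1)).
#' @param direction `"P>W"` or `"W>P"`.
#' @param consistency_cutoff consistency band defining eligibility.
#' @return character vector of study-set gene ids.
#' @export
select_top_fraction <- function(diff_table, fraction = 0.02,
                                direction = c("P>W", "W>P"),
                                consistency_cutoff = 0.25) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction >= 1) stop_arg("fraction must be in (0, 1)")
  elig <- diff_table[abs(diff_table$consistency) < consistency_cutoff, ,
                     drop = FALSE]
  if (nrow(elig) == 0) stop_arg("no genes inside the consistency band")
  size <- round_half_up(fraction * nrow(elig), 0)
  key <- if (direction == "P>W") -elig$mean_rd else elig$mean_rd
  elig$gene_id[order(key, elig$gene_id)][seq_len(size)]
}

#' Null (background complement) gene set
#'
#' The filtered genes minus both study sets; study sets must be disjoint.
#'
#' @param filtered_genes all genes passing the low-count filter.
#' @param study_sets list of study-set gene vectors.
#' @return character vector of null-set genes.
#' @export
build_null_set <- function(filtered_genes, study_sets) {
  all_study <- unlist(study_sets, use.names = FALSE)
  if (anyDuplicated(all_study))
    stop_arg("study sets overlap")
  setdiff(filtered_genes, all_study)
}

#' Exact hypergeometric tail test
#'
#' With `X ~ Hypergeometric(N, K, n)` (a study of size `n` drawn from a
#' population of `N` genes of which `K` carry the term), the enrichment
#' p-value is `P(X >= k)` and the depletion p-value `P(X <= k)`, both by
#' exact summation of the point mass function.
#'
#' @param k study genes carrying the term.
#' @param n study size.
#' @param K population genes carrying the term.
#' @param N population size.
#' @param side `"enrichment"` (upper tail) or `"depletion"` (lower tail).
#' @return p-value.
#' @examples
#' hypergeom_test(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_test <- function(k, n, K, N, side = c("enrichment", "depletion")) {
  side <- match.arg(side)
  if (k < 0 || n > N || K > N || k > n || k > K)
    stop_arg("inconsistent hypergeometric counts")
  p <- if (side == "enrichment")
    sum(dhyper(k:min(n, K), K, N - K, n))
  else
    sum(dhyper(0:k, K, N - K, n))
  min(p, 1)  # guard against float round-up past 1 in the full-support sum
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m/j) p_(j)` on the sorted p-values, mapped back to
#' the input order and capped at 1.
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of BH-adjusted q-values.
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1)) stop_arg("p-values must be in (0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

#' GO term enrichment of a study set against a null set
#'
#' Flat gene-to-term annotations (no ancestor propagation). Unannotated
#' genes are excluded from both the study and the population; terms carried
#' by fewer than `min_pop_count` annotated population genes are not tested.
#' Two reporting tiers are flagged: significant (q < `alpha_strict`) and
#' marginal (q < `alpha_loose`).
#'
#' @param study_genes study-set gene ids.
#' @param null_genes null-set gene ids (disjoint from the study set).
#' @param annotations data.frame with columns `gene_id`, `term_id`.
#' @param side enrichment or depletion tail.
#' @param min_pop_count minimum annotated population genes per tested term.
#' @param alpha_strict,alpha_loose FDR tiers.
#' @return data.frame: `term_id`, `k`, `n`, `K`, `N`, `p`, `q`, `tier`.
#' @export
go_enrichment <- function(study_genes, null_genes, annotations,
                          side = "enrichment", min_pop_count = 2,
                          alpha_strict = 0.01, alpha_loose = 0.05) {
  ann_genes <- unique(annotations$gene_id)
  study <- intersect(study_genes, ann_genes)
  pop <- union(study, intersect(null_genes, ann_genes))
  ann <- annotations[annotations$gene_id %in% pop, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  Ktab <- table(ann$term_id)
  terms <- names(Ktab)[Ktab >= min_pop_count]
  if (length(terms) == 0)
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), tier = character(),
                      stringsAsFactors = FALSE))
  n <- length(study)
  N <- length(pop)
  res <- lapply(terms, function(t) {
    g <- ann$gene_id[ann$term_id == t]
    k <- length(intersect(g, study))
    K <- length(g)
    data.frame(term_id = t, k = k, n = n, K = K, N = N,
               p = hypergeom_test(k, n, K, N, side),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$tier <- ifelse(out$q < alpha_strict, "significant",
                     ifelse(out$q < alpha_loose, "marginal", "ns"))
  out[order(out$q, out$p, out$term_id), , drop = FALSE]
}
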