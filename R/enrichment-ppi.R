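# Random-permutation gene-set overlap tests against reference lists, and
# weighted protein-protein interaction degree comparisons.

#' Permutation test of gene-set overlap with a reference list
#'
#' Draws `n_perm` random subsets of `k` genes (without replacement) from
#' the cohort gene pool and records each draw's overlap with the reference
#' list, forming the null overlap distribution. The empirical p-value uses
#' the add-one estimator `p = (1 + #(null >= observed)) / (n_perm + 1)`,
#' which never returns exactly zero. The "5% cutoff" of the protocol is
#' reported as the 95th percentile (order statistic) of the null
#' distribution.
#'
#' @param target Observed gene set (subset of `pool`); its overlap with
#'   the reference list is the observed statistic.
#' @param pool Cohort gene pool to resample from.
#' @param reference Reference gene list.
#' @param n_perm Number of permutations (default 10000).
#' @param k Draw size (default `length(target)`).
#' @param seed Integer RNG seed; identical seeds give identical results.
#' @return A list: `p_value`, `observed`, `cutoff_95`, `null` (integer
#'   vector of length `n_perm`), `k`, `n_perm`.
#' @export
permutation_overlap_test <- function(target, pool, reference,
                                     n_perm = 10000, k = length(target),
                                     seed = NULL) {
  stopifnot(n_perm >= 1, k >= 0, k <= length(pool))
  if (!all(target %in% pool)) {
    stop("target set must be contained in the pool", call. = FALSE)
  }
  observed <- sum(unique(target) %in% reference)
  in_ref <- pool %in% reference
  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(in_ref[sample.int(length(pool), k)]),
           integer(1L))
  })
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  cutoff <- sort(null)[ceiling(0.95 * n_perm)]
  list(p_value = p, observed = observed, cutoff_95 = cutoff,
       null = null, k = k, n_perm = n_perm)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, each in `[p, 1]`, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Weighted interaction degree per gene
#'
#' For each gene, sums the reliability scores of its interactions; each
#' edge contributes its reliability to both endpoints. Self-loops are
#' counted once toward their gene (with a message). Genes listed in
#' `genes` but absent from the edge table score 0.
#'
#' @param edges Data frame `geneA, geneB, reliability` with reliabilities
#'   in `(0, 1]`.
#' @param genes Optional gene vector fixing the output's names (isolated
#'   genes included with score 0).
#' @return A named numeric vector of weighted degrees.
#' @export
ppi_weighted_degree <- function(edges, genes = NULL) {
  stop_if_not_columns(edges, c("geneA", "geneB", "reliability"), "edges")
  if (nrow(edges) > 0L &&
      (any(edges$reliability <= 0) || any(edges$reliability > 1))) {
    stop("reliability scores must lie in (0, 1]", call. = FALSE)
  }
  self <- edges$geneA == edges$geneB
  if (any(self)) {
    message(sum(self), " self-loop(s) counted once toward their gene")
  }
  contrib_genes <- c(edges$geneA, edges$geneB[!self])
  contrib_scores <- c(edges$reliability, edges$reliability[!self])
  genes <- genes %||% sort(unique(c(edges$geneA, edges$geneB)))
  score <- stats::setNames(numeric(length(genes)), genes)
  if (length(contrib_genes) > 0L) {
    s <- tapply(contrib_scores, contrib_genes, sum)
    s <- s[names(s) %in% genes]
    score[names(s)] <- s
  }
  score
}

#' Compare weighted PPI degrees between two gene groups
#'
#' @param scores_a,scores_b Numeric vectors of weighted degrees (both
#'   nonempty).
#' @return A list: `median_a`, `median_b`, `p_value` (two-sided Wilcoxon
#'   rank-sum; exact where possible, normal approximation under ties).
#' @export
compare_ppi <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  p <- suppressWarnings(stats::wilcox.test(scores_a, scores_b)$p.value)
  list(median_a = stats::median(scores_a), median_b = stats::median(scores_b),
       p_value = p)
}
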