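#' Bernoulli perturbation rate of the null model
#'
#' The probability that a background gene is differential:
#' `p_diff = n_diff / n_bg`. This is the coin-flip rate of the
#' gene-perturbation null.
#'
#' @param profile A [differential_profile()].
#' @return A number in \[0, 1\].
#' @export
diff_probability <- function(profile) {
  stopifnot(inherits(profile, "differential_profile"))
  n_bg <- length(profile$background_genes)
  if (n_bg < 1L) stop("background gene universe is empty")
  length(profile$diff_genes) / n_bg
}

#' Simulate the null distribution of the pathway score
#'
#' Each repetition flips an independent Bernoulli(`p_diff`) coin for every
#' distinct gene appearing in the pathway's node compositions, maps the
#' resulting simulated differential gene set to nodes (so nodes sharing a
#' gene stay correlated, exactly as in the observed mapping), and scores the
#' pathway with the fixed adjusted weight vector. The pathway structure and
#' the weights are never perturbed. Deterministic given `seed`.
#'
#' @param pathway A [pathway_graph()].
#' @param weights A `weight_vector` for this pathway (adjusted if needed).
#' @param p_diff Bernoulli rate in \[0, 1\]; see [diff_probability()].
#' @param reps Number of repetitions (>= 1); the smallest resolvable
#'   non-zero p-value is `1/reps`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param observed Optional observed score; if supplied, the empirical
#'   p-value is filled in.
#' @return A `null_distribution`: list with `pathway_id`, `measure`,
#'   `scores` (length `reps`), `reps`, `seed`, `observed`, `p_value`.
#' @export
simulate_null_scores <- function(pathway, weights, p_diff, reps = 1000,
                                 seed = NULL, observed = NULL) {
  stopifnot(inherits(pathway, "pathway_graph"),
            inherits(weights, "weight_vector"))
  if (is.null(weights$adjusted)) weights <- adjust_weights(weights)
  stopifnot(setequal(names(weights$adjusted), pathway$nodes))
  reps <- as.integer(reps)
  stopifnot(reps >= 1L, p_diff >= 0, p_diff <= 1)

  genes <- pathway_genes(pathway)
  scores <- with_rng_seed(seed, {
    if (!length(genes) || p_diff == 0) {
      numeric(reps)
    } else {
      inc <- gene_node_incidence(pathway, genes)        # genes x gene-bearing nodes
      w <- weights$adjusted[colnames(inc)]
      draws <- matrix(stats::runif(reps * length(genes)) < p_diff,
                      nrow = reps, ncol = length(genes))
      hits <- (draws %*% inc) > 0                       # reps x nodes
      as.vector(hits %*% w)
    }
  })
  p_value <- if (is.null(observed)) NA_real_ else mean(scores >= observed)
  structure(
    list(pathway_id = pathway$pathway_id, measure = weights$measure,
         scores = scores, reps = reps, seed = seed,
         observed = observed %||% NA_real_, p_value = p_value),
    class = "null_distribution"
  )
}

# 0/1 matrix: rows = distinct pathway genes, columns = gene-bearing nodes.
gene_node_incidence <- function(pathway, genes = pathway_genes(pathway)) {
  keep <- names(pathway$members)[lengths(pathway$members) > 0]
  inc <- matrix(0, nrow = length(genes), ncol = length(keep),
                dimnames = list(genes, keep))
  for (v in keep) inc[pathway$members[[v]], v] <- 1
  inc
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> pathway=%s measure=%s reps=%d observed=%s p=%s\n",
              x$pathway_id, x$measure, x$reps, format(x$observed),
              format(x$p_value)))
  invisible(x)
}

#' Empirical (Monte-Carlo) p-value
#'
#' The proportion of simulated scores at or above the observed score
#' (inclusive comparison). No pseudo-count is added: a reported 0 means
#' "below 1/reps".
#'
#' @param simulated Numeric vector of simulated null scores, or a
#'   `null_distribution`.
#' @param observed Observed pathway score.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' empirical_pvalue(c(1, 2, 3, 4, 5), 3)  # 0.6
empirical_pvalue <- function(simulated, observed) {
  if (inherits(simulated, "null_distribution")) simulated <- simulated$scores
  stopifnot(is.numeric(simulated), length(simulated) >= 1L,
            is.numeric(observed), length(observed) == 1L)
  mean(simulated >= observed)
}

#' Exact tail of the pathway score for independent single-gene nodes
#'
#' When every node carries exactly one distinct gene, node perturbations are
#' independent Bernoulli(`p_diff`) variables and the score distribution can
#' be computed exactly by enumerating all 2^n differential-status outcomes
#' (equivalently, summing over the number of perturbed genes k the binomial
#' probability times the probability that k weights sum past s). Feasible
#' for n <= 25; used as the small-n oracle for [simulate_null_scores()].
#'
#' @param weights Numeric vector (or multiset) of strictly positive node
#'   weights; length n <= 25.
#' @param p_diff Bernoulli rate in (0, 1) (0 and 1 are allowed and give
#'   degenerate tails).
#' @return A `theoretical_tail` object whose `$tail` element is a vectorized
#'   function `s -> P(S >= s)`, non-increasing, with `tail(0) = 1`.
#' @export
#' @examples
#' tt <- theoretical_tail(c(1, 2), 0.5)
#' tt$tail(2)  # 0.5: outcomes {}, {1}, {2}, {1,2} score 0,1,2,3
theoretical_tail <- function(weights, p_diff) {
  weights <- as.numeric(weights)
  stopifnot(length(weights) >= 1L, all(weights > 0),
            p_diff >= 0, p_diff <= 1)
  n <- length(weights)
  if (n > 25L) {
    stop("exact enumeration over 2^n outcomes is limited to n <= 25 nodes; ",
         "got n = ", n, " (use simulate_null_scores instead)")
  }
  sums <- 0
  probs <- 1
  for (w in weights) {
    sums <- c(sums, sums + w)
    probs <- c(probs * (1 - p_diff), probs * p_diff)
  }
  o <- order(sums)
  sums <- sums[o]
  upper <- rev(cumsum(rev(probs[o])))   # upper[i] = P(S >= sums[i])
  upper <- pmin(pmax(upper, 0), 1)      # guard against float accumulation
  tail_fun <- function(s) {
    vapply(s, function(si) {
      below <- findInterval(si, sums, left.open = TRUE)  # #{sums < si}
      if (below >= length(sums)) 0 else upper[below + 1L]
    }, numeric(1))
  }
  structure(list(weights = weights, p_diff = p_diff, tail = tail_fun),
            class = "theoretical_tail")
}

#' One-sided Fisher's exact p-value for over-representation
#'
#' The classical ORA baseline: the upper hypergeometric tail
#' `P(X >= k)` with `X ~ Hypergeometric(n_bg, n_diff, n_pathway)` — the
#' probability of drawing at least `k` differential genes when `n_pathway`
#' genes are sampled without replacement from a background of `n_bg` genes
#' containing `n_diff` differential ones.
#'
#' @param k_diff_in_pathway Observed differential genes in the pathway.
#' @param n_pathway Pathway gene count.
#' @param n_diff Differential genes in the background.
#' @param n_bg Background gene count.
#' @return A p-value in \[0, 1\].
#' @export
#' @examples
#' ora_fisher_pvalue(40, 200, 1000, 10000)  # 1.36e-5
ora_fisher_pvalue <- function(k_diff_in_pathway, n_pathway, n_diff, n_bg) {
  k <- k_diff_in_pathway
  stopifnot(length(k) == 1L, length(n_pathway) == 1L,
            length(n_diff) == 1L, length(n_bg) == 1L)
  if (!(k >= 0 && k <= n_pathway && n_pathway <= n_bg && n_diff <= n_bg &&
        n_diff >= 0)) {
    stop("infeasible contingency table: need 0 <= k <= n_pathway <= n_bg and ",
         "0 <= n_diff <= n_bg")
  }
  if (k > n_diff) {
    stop("infeasible contingency table: k exceeds the number of ",
         "differential genes in the background")
  }
  stats::phyper(k - 1, m = n_diff, n = n_bg - n_diff, k = n_pathway,
                lower.tail = FALSE)
}

#' Minimum differential-gene count for ORA significance
#'
#' The smallest `k` such that the one-sided Fisher's exact p-value
#' [ora_fisher_pvalue()] drops below `threshold`.
#'
#' @param n_pathway Pathway gene count.
#' @param n_diff Differential genes in the background.
#' @param n_bg Background gene count.
#' @param threshold Significance threshold in (0, 1).
#' @return Integer `k`, or `NA_integer_` if no `k <= n_pathway` attains the
#'   threshold.
#' @export
#' @examples
#' min_significant_k(200, 1000, 10000, 0.01)  # 31
min_significant_k <- function(n_pathway, n_diff, n_bg, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (threshold >= 1) return(0L)
  k_max <- min(n_pathway, n_diff)
  p <- stats::phyper(seq(0L, k_max) - 1, m = n_diff, n = n_bg - n_diff,
                     k = n_pathway, lower.tail = FALSE)
  hit <- which(p < threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - 1L)
}
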