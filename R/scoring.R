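#' Pathway score
#'
#' The pathway-level statistic: the sum of (adjusted) node weights over the
#' differentially affected nodes,
#' \deqn{s = \sum_{i=1}^{n} w_i d_i,}
#' where \eqn{d_i} is 1 if node \eqn{i} is differentially affected and 0
#' otherwise. Under the equal-weight condition the raw score is simply the
#' number of differential nodes. Scoring always uses the adjusted (strictly
#' positive) weights, so adding a differential node always increases the
#' score.
#'
#' @param weights A `weight_vector`; adjusted automatically (with the
#'   default alpha rule) if [adjust_weights()] has not been applied.
#' @param diff_nodes Character vector of differentially affected node ids;
#'   must all be nodes of the weight vector's pathway.
#' @return A `score_result`: list with `pathway_id`, `measure`, `score`,
#'   `diff_nodes` and the indicator map `d` (named 0/1 vector over nodes).
#' @export
#' @examples
#' w <- adjust_weights(weight_vector("demo", c(A = 2, B = 3, C = 5)),
#'                     alpha = 1e-9)
#' pathway_score(w, c("A", "C"))$score  # ~7
pathway_score <- function(weights, diff_nodes) {
  stopifnot(inherits(weights, "weight_vector"))
  if (is.null(weights$adjusted)) weights <- adjust_weights(weights)
  diff_nodes <- unique(as.character(diff_nodes))
  unknown <- setdiff(diff_nodes, names(weights$adjusted))
  if (length(unknown)) {
    stop("differential node(s) not in the pathway: ",
         paste(unknown, collapse = ", "))
  }
  d <- stats::setNames(as.integer(names(weights$adjusted) %in% diff_nodes),
                       names(weights$adjusted))
  structure(
    list(pathway_id = weights$pathway_id, measure = weights$measure,
         score = sum(weights$adjusted * d), diff_nodes = sort(diff_nodes),
         d = d),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> pathway=%s measure=%s score=%.6g (%d differential node(s))\n",
              x$pathway_id, x$measure, x$score, length(x$diff_nodes)))
  invisible(x)
}
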