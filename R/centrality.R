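# Weight-measure registry. Built-in centralities are registered at load
# time (zzz.R); users can plug in their own measures by name.
.weight_registry <- new.env(parent = emptyenv())

#' Register a node-weight measure
#'
#' The enrichment model is agnostic to how node importance is quantified:
#' any function mapping a pathway graph to a non-negative weight per node
#' can be plugged in and then referenced by name everywhere a built-in
#' measure is accepted.
#'
#' @param name Measure name; must not collide with an existing registration.
#' @param fn Function taking a [pathway_graph()] and returning a numeric
#'   vector of non-negative weights named by (exactly) the pathway's node
#'   ids. Output is validated on every use.
#' @return Invisibly, the registered name.
#' @export
#' @examples
#' register_weight_function("constant2", function(p) {
#'   stats::setNames(rep(2, length(p$nodes)), p$nodes)
#' })
#' unregister_weight_function("constant2")
register_weight_function <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.function(fn)) stop("'fn' must be a function(pathway) -> named numeric")
  if (exists(name, envir = .weight_registry, inherits = FALSE)) {
    stop("a weight measure named '", name, "' is already registered")
  }
  assign(name, fn, envir = .weight_registry)
  invisible(name)
}

#' Remove a plugin weight measure from the registry
#'
#' Built-in measures cannot be removed.
#'
#' @param name Registered measure name.
#' @return Invisibly, `TRUE`.
#' @export
unregister_weight_function <- function(name) {
  if (name %in% builtin_measures()) {
    stop("built-in measure '", name, "' cannot be unregistered")
  }
  if (!exists(name, envir = .weight_registry, inherits = FALSE)) {
    stop("no weight measure named '", name, "' is registered")
  }
  rm(list = name, envir = .weight_registry)
  invisible(TRUE)
}

#' List registered weight measures
#' @return Character vector of measure names, built-ins first.
#' @export
registered_measures <- function() {
  all <- ls(.weight_registry)
  c(builtin_measures(), sort(setdiff(all, builtin_measures())))
}

builtin_measures <- function() {
  c("equal.weight", "in.degree", "out.degree", "betweenness",
    "in.reach", "out.reach")
}

register_builtins <- function() {
  builtins <- list(
    equal.weight = function(p) stats::setNames(rep(1, length(p$nodes)), p$nodes),
    in.degree    = function(p) igraph::degree(p$graph, mode = "in", loops = FALSE),
    out.degree   = function(p) igraph::degree(p$graph, mode = "out", loops = FALSE),
    betweenness  = function(p) igraph::betweenness(p$graph, directed = p$directed,
                                                   normalized = FALSE),
    in.reach     = function(p) reach_from_distances(p, mode = "in"),
    out.reach    = function(p) reach_from_distances(p, mode = "out")
  )
  for (nm in names(builtins)) {
    if (!exists(nm, envir = .weight_registry, inherits = FALSE)) {
      assign(nm, builtins[[nm]], envir = .weight_registry)
    }
  }
}

# Largest-reach centrality: the largest finite shortest-path length from
# (out) or to (in) a node, over all other nodes. A node with no reachable
# counterpart in the required direction gets 0, ranking isolated nodes
# lowest while keeping weights finite.
reach_from_distances <- function(p, mode = c("in", "out")) {
  mode <- match.arg(mode)
  dm <- igraph::distances(p$graph, mode = "out")   # dm[i, j] = d(i -> j)
  diag(dm) <- -Inf
  dm[is.infinite(dm) & dm > 0] <- -Inf             # unreachable pairs excluded
  val <- if (mode == "in") apply(dm, 2, max) else apply(dm, 1, max)
  val[!is.finite(val)] <- 0
  stats::setNames(val[p$nodes], p$nodes)
}

#' Compute node weights for a pathway
#'
#' Looks up `measure` in the registry, evaluates it on the pathway, validates
#' the raw weights (non-negative, keyed exactly by the pathway's nodes) and
#' applies the positivity adjustment ([adjust_weights()]).
#'
#' @param pathway A [pathway_graph()].
#' @param measure Measure name; see [registered_measures()]. Built-ins:
#'   `equal.weight`, `in.degree`, `out.degree`, `betweenness` (directed
#'   shortest-path betweenness, unnormalized, endpoints excluded),
#'   `in.reach`, `out.reach` (largest-reach centrality).
#' @return A `weight_vector`: list with `measure`, `pathway_id`, `raw`
#'   (named non-negative numeric), `alpha`, `adjusted` (strictly positive).
#' @export
#' @examples
#' pw <- pathway_graph("chain", c("A", "B", "C"),
#'                     edges = cbind(c("A", "B"), c("B", "C")))
#' compute_weights(pw, "in.degree")$raw
compute_weights <- function(pathway, measure) {
  stopifnot(inherits(pathway, "pathway_graph"))
  if (!exists(measure, envir = .weight_registry, inherits = FALSE)) {
    stop("unknown weight measure '", measure, "'; registered measures: ",
         paste(registered_measures(), collapse = ", "))
  }
  fn <- get(measure, envir = .weight_registry)
  raw <- fn(pathway)
  if (!is.numeric(raw)) {
    stop("measure '", measure, "' returned a non-numeric weight vector")
  }
  if (is.null(names(raw)) || !setequal(names(raw), pathway$nodes) ||
      length(raw) != length(pathway$nodes)) {
    stop("measure '", measure,
         "' must return one weight per pathway node, named by node id")
  }
  raw <- raw[pathway$nodes]
  if (anyNA(raw)) stop("measure '", measure, "' returned NA weights")
  if (any(raw < 0)) {
    stop("measure '", measure, "' returned negative weights; ",
         "raw node weights must be non-negative")
  }
  adjust_weights(weight_vector(measure, raw, pathway_id = pathway$pathway_id))
}

#' Construct a raw weight vector
#'
#' @param measure Measure name (label only; no registry lookup).
#' @param raw Named numeric vector of non-negative node weights.
#' @param pathway_id Optional pathway identifier carried along for reporting.
#' @return A `weight_vector` with `adjusted`/`alpha` unset; see
#'   [adjust_weights()].
#' @export
weight_vector <- function(measure, raw, pathway_id = NA_character_) {
  stopifnot(is.numeric(raw), !is.null(names(raw)))
  structure(list(measure = measure, pathway_id = pathway_id,
                 raw = raw, alpha = NULL, adjusted = NULL),
            class = "weight_vector")
}

#' Positivity adjustment of node weights
#'
#' Centralities can be exactly zero (e.g. betweenness on sparse graphs), but
#' the pathway score needs strictly positive weights so that every
#' differential node contributes. A small constant `alpha` is added to every
#' weight: by default 1/100 of the minimum non-zero raw weight, chosen to
#' perturb the weighting marginally. If all raw weights are zero, `alpha`
#' falls back to 1, degrading the measure to the equal-weight condition.
#'
#' @param w A `weight_vector` (see [weight_vector()]); raw weights must be
#'   non-negative.
#' @param alpha Optional override for the additive constant (positive).
#' @return The weight vector with `alpha` and `adjusted = raw + alpha`
#'   filled in.
#' @export
#' @examples
#' w <- weight_vector("demo", c(A = 0, B = 1, C = 2))
#' adjust_weights(w)$adjusted   # 0.01 1.01 2.01
adjust_weights <- function(w, alpha = NULL) {
  stopifnot(inherits(w, "weight_vector"))
  if (any(w$raw < 0)) stop("raw weights must be non-negative")
  if (is.null(alpha)) {
    nz <- w$raw[w$raw > 0]
    alpha <- if (length(nz)) min(nz) / 100 else 1
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  w$alpha <- alpha
  w$adjusted <- w$raw + alpha
  w
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> measure=%s pathway=%s n=%d alpha=%s\n",
              x$measure, x$pathway_id, length(x$raw),
              if (is.null(x$alpha)) "(unadjusted)" else format(x$alpha)))
  invisible(x)
}

#' Convenience wrappers for the built-in centralities
#'
#' Each returns the adjusted weight vector for its measure; equivalent to
#' `compute_weights(pathway, "<name>")`. `in.degree`/`out.degree` count
#' direct upstream/downstream neighbours; `betweenness` is directed
#' shortest-path betweenness (unnormalized, endpoints excluded);
#' `in.reach`/`out.reach` are the largest finite shortest-path length
#' into/out of each node.
#'
#' @param pathway A [pathway_graph()].
#' @return A `weight_vector`.
#' @name builtin-centralities
NULL

#' @rdname builtin-centralities
#' @export
in_degree <- function(pathway) compute_weights(pathway, "in.degree")

#' @rdname builtin-centralities
#' @export
out_degree <- function(pathway) compute_weights(pathway, "out.degree")

#' @rdname builtin-centralities
#' @export
node_betweenness <- function(pathway) compute_weights(pathway, "betweenness")

#' @rdname builtin-centralities
#' @export
largest_reach_in <- function(pathway) compute_weights(pathway, "in.reach")

#' @rdname builtin-centralities
#' @export
largest_reach_out <- function(pathway) compute_weights(pathway, "out.reach")

#' @rdname builtin-centralities
#' @export
equal_weight <- function(pathway) compute_weights(pathway, "equal.weight")
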