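#' Construct a pathway graph
#'
#' A pathway is represented as a directed network whose basic unit is the
#' *node*, not the gene: a node may be a single protein, a complex or protein
#' family holding several member genes, or a non-gene entity (compound,
#' microRNA) with an empty member set. One gene may belong to several nodes.
#' Non-gene nodes are retained because they contribute to pathway topology
#' even though their abundance is not measured by expression assays.
#'
#' @param pathway_id Single string identifying the pathway; unique within a
#'   catalogue.
#' @param nodes Character vector of node identifiers (unique within the
#'   pathway).
#' @param edges Two-column matrix or data frame of node identifiers
#'   (`from`, `to`). Directed. Self-loops are rejected; parallel edges are
#'   collapsed. May be `NULL`/empty for an edgeless pathway.
#' @param node_type Character vector (recycled) giving the entity type of each
#'   node: one of `"protein"`, `"complex"`, `"family"`, `"compound"`,
#'   `"mirna"`, `"other"`. Metadata only: differential status is decided
#'   solely by member genes.
#' @param members Named list mapping node identifiers to character vectors of
#'   member gene identifiers. Nodes absent from the list carry no genes.
#'   Gene identifiers are opaque, case-sensitive strings.
#' @param directed Logical; pathways are directed by default. The undirected
#'   form is used by the key-node experiment.
#'
#' @return An object of class `pathway_graph` with fields `pathway_id`,
#'   `nodes`, `node_type`, `members`, `edges`, `directed` and an `igraph`
#'   graph in `$graph`.
#' @export
#' @examples
#' pw <- pathway_graph(
#'   "toy", nodes = c("A", "B", "C"),
#'   edges = cbind(from = c("A", "B"), to = c("B", "C")),
#'   node_type = c("complex", "protein", "compound"),
#'   members = list(A = c("g1", "g2"), B = "g1")
#' )
#' pw
pathway_graph <- function(pathway_id, nodes, edges = NULL, node_type = "other",
                          members = list(), directed = TRUE) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L, nzchar(pathway_id))
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) {
    stop("pathway '", pathway_id, "': a pathway must have at least one node")
  }
  if (anyDuplicated(nodes)) {
    stop("pathway '", pathway_id, "': duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  node_type <- as.character(node_type)
  bad_type <- setdiff(node_type, node_types())
  if (length(bad_type)) {
    stop("pathway '", pathway_id, "': unknown node type(s): ",
         paste(bad_type, collapse = ", "))
  }
  node_type <- rep_len(node_type, length(nodes))
  names(node_type) <- nodes

  edges <- normalize_edges(edges)
  if (nrow(edges)) {
    undeclared <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(undeclared)) {
      stop("pathway '", pathway_id, "': edge endpoint(s) not declared as nodes: ",
           paste(undeclared, collapse = ", "))
    }
    if (any(edges$from == edges$to)) {
      stop("pathway '", pathway_id, "': self-loop edges are not allowed")
    }
    edges <- unique(edges)          # collapse parallel edges
    rownames(edges) <- NULL
  }

  if (!is.list(members)) stop("'members' must be a named list of gene vectors")
  if (length(members)) {
    if (is.null(names(members)) || any(!nzchar(names(members)))) {
      stop("'members' must be a named list keyed by node identifier")
    }
    orphan <- setdiff(names(members), nodes)
    if (length(orphan)) {
      stop("pathway '", pathway_id, "': member map names undeclared node(s): ",
           paste(orphan, collapse = ", "))
    }
  }
  mem <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    g <- unique(as.character(members[[v]] %||% character(0)))
    mem[[v]] <- g[nzchar(g)]
  }

  graph <- igraph::graph_from_data_frame(
    edges, directed = directed,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )

  structure(
    list(pathway_id = pathway_id, nodes = nodes, node_type = node_type,
         members = mem, edges = edges, directed = directed, graph = graph),
    class = "pathway_graph"
  )
}

node_types <- function() c("protein", "complex", "family", "compound", "mirna", "other")

normalize_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) stop("'edges' must have exactly two columns (from, to)")
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges
}

#' @export
print.pathway_graph <- function(x, ...) {
  n_genes <- length(pathway_genes(x))
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges (%s), %d distinct genes\n",
              x$pathway_id, length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected", n_genes))
  invisible(x)
}

#' Distinct genes composing a pathway
#'
#' @param pathway A [pathway_graph()].
#' @return Sorted character vector of all gene identifiers appearing in any
#'   node's member set.
#' @export
pathway_genes <- function(pathway) {
  stopifnot(inherits(pathway, "pathway_graph"))
  sort(unique(unlist(pathway$members, use.names = FALSE)))
}

#' Bundle pathways into a catalogue
#'
#' @param pathways List of [pathway_graph()] objects with distinct
#'   `pathway_id`s. Node identifiers are scoped per pathway; two pathways may
#'   reuse the same node id without implying identity.
#' @param name Catalogue label.
#' @return An object of class `pathway_catalogue`: a named, ordered list of
#'   pathways plus a `name` attribute.
#' @export
pathway_catalogue <- function(pathways, name = "catalogue") {
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  stopifnot(is.list(pathways), length(pathways) >= 1L)
  ok <- vapply(pathways, inherits, logical(1), what = "pathway_graph")
  if (!all(ok)) stop("all elements of 'pathways' must be pathway_graph objects")
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate pathway identifiers in catalogue: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(name = name, pathways = stats::setNames(pathways, ids)),
            class = "pathway_catalogue")
}

#' @export
print.pathway_catalogue <- function(x, ...) {
  cat(sprintf("<pathway_catalogue> %s: %d pathway(s)\n", x$name,
              length(x$pathways)))
  invisible(x)
}

#' @export
length.pathway_catalogue <- function(x) length(x$pathways)

#' Differential expression profile
#'
#' Holds the differential gene list and the background universe from which
#' the Bernoulli perturbation rate `p_diff = n_diff / n_bg` is derived.
#'
#' @param diff_genes Character vector of differential gene identifiers; must
#'   be a subset of `background_genes`.
#' @param background_genes Character vector of all measured gene identifiers
#'   (non-empty).
#' @return Object of class `differential_profile`.
#' @export
differential_profile <- function(diff_genes, background_genes) {
  diff_genes <- unique(as.character(diff_genes))
  background_genes <- unique(as.character(background_genes))
  if (length(background_genes) < 1L) {
    stop("background gene universe must contain at least one gene")
  }
  missing <- setdiff(diff_genes, background_genes)
  if (length(missing)) {
    stop("differential genes absent from the background universe: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  structure(list(diff_genes = diff_genes, background_genes = background_genes),
            class = "differential_profile")
}

#' @export
print.differential_profile <- function(x, ...) {
  cat(sprintf("<differential_profile> %d differential of %d background genes (p_diff = %.4g)\n",
              length(x$diff_genes), length(x$background_genes),
              length(x$diff_genes) / length(x$background_genes)))
  invisible(x)
}

#' Map differential genes to differentially affected nodes
#'
#' A node is differentially affected if any of its member genes is
#' differential: one altered gene disrupts every complex or family it sits
#' in, and a multi-gene complex is disrupted by any one altered member.
#' Nodes with no member genes (compounds, microRNAs) are never differential.
#' Pathway genes absent from the background universe stay in the topology but
#' are simply never differential.
#'
#' @param pathway A [pathway_graph()].
#' @param profile A [differential_profile()], or a plain character vector of
#'   differential gene identifiers.
#' @return Sorted character vector of differentially affected node ids.
#' @export
#' @examples
#' pw <- pathway_graph("toy", c("A", "B"),
#'                     members = list(A = c("g1", "g2"), B = "g1"))
#' map_genes_to_nodes(pw, "g1")  # g1 flips both of its host nodes
map_genes_to_nodes <- function(pathway, profile) {
  stopifnot(inherits(pathway, "pathway_graph"))
  diff <- if (inherits(profile, "differential_profile")) {
    profile$diff_genes
  } else {
    as.character(profile)
  }
  if (!length(diff)) return(character(0))
  hit <- vapply(pathway$members, function(g) any(g %in% diff), logical(1))
  sort(pathway$nodes[hit[pathway$nodes]])
}
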