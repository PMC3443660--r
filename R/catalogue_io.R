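#' Read a pathway catalogue from TSV files
#'
#' The catalogue format is three tab-separated files, each with a header
#' line:
#' \describe{
#'   \item{nodes}{`pathway_id<TAB>node_id<TAB>node_type`}
#'   \item{edges}{`pathway_id<TAB>source_node_id<TAB>target_node_id` (directed)}
#'   \item{mapping}{`pathway_id<TAB>node_id<TAB>gene_id`, one row per
#'     gene-in-node}
#' }
#' Nodes with no mapping rows are non-gene nodes (compounds, microRNAs) and
#' are retained. Malformed lines are reported with their line number; edges
#' or mapping rows naming undeclared nodes are consistency errors.
#'
#' @param nodes_path,edges_path,mapping_path File paths.
#' @param name Catalogue label (defaults to the nodes file name).
#' @return A [pathway_catalogue()].
#' @export
read_catalogue <- function(nodes_path, edges_path, mapping_path,
                           name = basename(nodes_path)) {
  nodes_tab <- read_tsv3(nodes_path, c("pathway_id", "node_id", "node_type"))
  edges_tab <- read_tsv3(edges_path, c("pathway_id", "source_node_id", "target_node_id"))
  map_tab <- read_tsv3(mapping_path, c("pathway_id", "node_id", "gene_id"))

  ids <- unique(nodes_tab[[1]])
  pathways <- lapply(ids, function(pid) {
    nd <- nodes_tab[nodes_tab[[1]] == pid, , drop = FALSE]
    if (anyDuplicated(nd[[2]])) {
      stop("catalogue '", name, "', pathway '", pid,
           "': duplicate node declaration: ",
           paste(unique(nd[[2]][duplicated(nd[[2]])]), collapse = ", "))
    }
    ed <- edges_tab[edges_tab[[1]] == pid, c(2, 3), drop = FALSE]
    mp <- map_tab[map_tab[[1]] == pid, , drop = FALSE]
    bad <- setdiff(unique(mp[[2]]), nd[[2]])
    if (length(bad)) {
      stop("catalogue '", name, "', pathway '", pid,
           "': mapping rows reference undeclared node(s): ",
           paste(bad, collapse = ", "))
    }
    members <- if (nrow(mp)) split(mp[[3]], mp[[2]]) else list()
    pathway_graph(pid, nodes = nd[[2]], edges = ed, node_type = nd[[3]],
                  members = members)
  })

  extra <- setdiff(unique(edges_tab[[1]]), ids)
  if (length(extra)) {
    stop("edges file references pathway(s) with no declared nodes: ",
         paste(extra, collapse = ", "))
  }
  extra <- setdiff(unique(map_tab[[1]]), ids)
  if (length(extra)) {
    stop("mapping file references pathway(s) with no declared nodes: ",
         paste(extra, collapse = ", "))
  }
  pathway_catalogue(pathways, name = name)
}

# Strict 3-column TSV reader that reports the offending line number.
read_tsv3 <- function(path, expected_header) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(path, ": empty file (header line required)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) != 3L) {
    stop(path, ", line 1: expected a 3-column tab-separated header")
  }
  body <- lines[-1]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- (seq_along(lines)[-1])[keep]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    bad <- which(nfield != 3L)[1]
    stop(path, ", line ", lineno[bad], ": expected 3 tab-separated fields, found ",
         nfield[bad])
  }
  out <- data.frame(
    a = vapply(parts, `[[`, character(1), 1L),
    b = vapply(parts, `[[`, character(1), 2L),
    c = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  names(out) <- expected_header
  out
}

#' Write a pathway catalogue to TSV files
#'
#' Inverse of [read_catalogue()]; a write followed by a re-read yields an
#' identical catalogue.
#'
#' @param cat A [pathway_catalogue()].
#' @param nodes_path,edges_path,mapping_path Output file paths.
#' @return Invisibly, the catalogue.
#' @export
write_catalogue <- function(cat, nodes_path, edges_path, mapping_path) {
  stopifnot(inherits(cat, "pathway_catalogue"))
  nd <- list(); ed <- list(); mp <- list()
  for (pw in cat$pathways) {
    nd[[length(nd) + 1L]] <- data.frame(
      pathway_id = pw$pathway_id, node_id = pw$nodes,
      node_type = unname(pw$node_type[pw$nodes]), stringsAsFactors = FALSE)
    if (nrow(pw$edges)) {
      ed[[length(ed) + 1L]] <- data.frame(
        pathway_id = pw$pathway_id, source_node_id = pw$edges$from,
        target_node_id = pw$edges$to, stringsAsFactors = FALSE)
    }
    ng <- lengths(pw$members)
    if (any(ng > 0)) {
      mp[[length(mp) + 1L]] <- data.frame(
        pathway_id = pw$pathway_id,
        node_id = rep(names(pw$members), ng),
        gene_id = unlist(pw$members, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  write_tsv <- function(rows, header, path) {
    df <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(data.frame(a = character(0), b = character(0),
                                 c = character(0)), header)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  write_tsv(nd, c("pathway_id", "node_id", "node_type"), nodes_path)
  write_tsv(ed, c("pathway_id", "source_node_id", "target_node_id"), edges_path)
  write_tsv(mp, c("pathway_id", "node_id", "gene_id"), mapping_path)
  invisible(cat)
}

#' Read a gene list file
#'
#' Plain text, one identifier per line; blank lines and `#` comments are
#' ignored. Identifiers are opaque case-sensitive strings.
#'
#' @param path File path.
#' @return Character vector of unique gene identifiers in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Structural summary of a pathway catalogue
#'
#' Summarises how far the catalogue departs from the one-gene-per-node
#' picture assumed by classical over-representation analysis: the
#' distribution of member-gene counts per node, the distribution of
#' host-node counts per gene (counted over all (pathway, node) pairs, since
#' node identity is scoped per pathway), and per-pathway node vs gene
#' counts.
#'
#' @param cat A [pathway_catalogue()].
#' @return A list with elements `node_gene_counts` (integer vector, one per
#'   gene-bearing node), `gene_node_counts` (named integer vector, hosts per
#'   gene), `per_pathway` (data frame: pathway_id, n_nodes, n_edges,
#'   n_genes), `frac_multigene_nodes` and `frac_multinode_genes`.
#' @export
catalogue_summary <- function(cat) {
  stopifnot(inherits(cat, "pathway_catalogue"))
  node_counts <- integer(0)
  gene_hosts <- character(0)
  per <- lapply(cat$pathways, function(pw) {
    ng <- lengths(pw$members)
    data.frame(pathway_id = pw$pathway_id, n_nodes = length(pw$nodes),
               n_edges = nrow(pw$edges), n_genes = length(pathway_genes(pw)),
               stringsAsFactors = FALSE)
  })
  for (pw in cat$pathways) {
    ng <- lengths(pw$members)
    node_counts <- c(node_counts, unname(ng[ng > 0]))
    gene_hosts <- c(gene_hosts, unlist(pw$members, use.names = FALSE))
  }
  gene_node_counts <- if (length(gene_hosts)) table(gene_hosts) else table(character(0))
  gene_node_counts <- stats::setNames(as.integer(gene_node_counts),
                                      names(gene_node_counts))
  list(
    node_gene_counts = node_counts,
    gene_node_counts = gene_node_counts,
    per_pathway = do.call(rbind, c(per, list(make.row.names = FALSE))),
    frac_multigene_nodes = if (length(node_counts)) mean(node_counts > 1) else 0,
    frac_multinode_genes = if (length(gene_node_counts)) mean(gene_node_counts > 1) else 0
  )
}

#' Toy pathway catalogue
#'
#' A small in-code fixture exercising the node-as-unit semantics: a complex
#' whose member genes also appear elsewhere (one gene flips several host
#' nodes), a protein family, and non-gene compound/microRNA nodes that shape
#' the topology but can never be differential.
#'
#' @return A [pathway_catalogue()] with two pathways.
#' @export
toy_catalogue <- function() {
  p1 <- pathway_graph(
    "toy_signal",
    nodes = c("RTK", "CPLX1", "CPLX2", "TF", "CMPD"),
    edges = cbind(from = c("RTK", "RTK", "CPLX1", "CPLX2", "CMPD"),
                  to = c("CPLX1", "CPLX2", "TF", "TF", "RTK")),
    node_type = c("protein", "complex", "complex", "protein", "compound"),
    members = list(RTK = "g1", CPLX1 = c("g2", "g3"), CPLX2 = c("g2", "g4"),
                   TF = "g5")
  )
  p2 <- pathway_graph(
    "toy_cascade",
    nodes = c("FAM", "K1", "K2", "MIR"),
    edges = cbind(from = c("FAM", "K1", "MIR"), to = c("K1", "K2", "K2")),
    node_type = c("family", "protein", "protein", "mirna"),
    members = list(FAM = c("g6", "g7"), K1 = "g8", K2 = "g5")
  )
  pathway_catalogue(list(p1, p2), name = "toy")
}

#' Toy differential profile matching [toy_catalogue()]
#'
#' @return A [differential_profile()] over ten background genes.
#' @export
toy_profile <- function() {
  differential_profile(c("g2", "g5"), paste0("g", 1:10))
}

#' Background universe used by the simulation experiments
#'
#' The simulation study's gene universe: `n_bg` background genes of which
#' `n_diff` are differential, giving a Bernoulli perturbation rate
#' `p_diff = n_diff / n_bg` (0.1 at the defaults).
#'
#' @param n_bg Background size (default 10000).
#' @param n_diff Differential count (default 1000).
#' @return A [differential_profile()].
#' @export
simulation_profile <- function(n_bg = 10000, n_diff = 1000) {
  stopifnot(n_diff <= n_bg, n_bg >= 1)
  bg <- sprintf("gene_%05d", seq_len(n_bg))
  differential_profile(bg[seq_len(n_diff)], bg)
}
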