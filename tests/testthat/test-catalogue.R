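test_that("three-file TSV catalogue round-trips through write and re-read", {
  cat1 <- toy_catalogue()
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv", "map.tsv"))
  write_catalogue(cat1, paths[1], paths[2], paths[3])
  cat2 <- read_catalogue(paths[1], paths[2], paths[3], name = cat1$name)
  expect_identical(names(cat1$pathways), names(cat2$pathways))
  for (id in names(cat1$pathways)) {
    a <- cat1$pathways[[id]]
    b <- cat2$pathways[[id]]
    expect_identical(a$nodes, b$nodes)
    expect_identical(a$node_type, b$node_type)
    expect_identical(a$edges, b$edges)
    expect_identical(lapply(a$members, sort), lapply(b$members, sort))
  }
})

test_that("bundled toy fixture loads with expected structure", {
  f <- function(x) system.file("extdata", x, package = "pathcent")
  cat_ <- read_catalogue(f("toy_nodes.tsv"), f("toy_edges.tsv"),
                         f("toy_mapping.tsv"))
  expect_length(cat_, 2L)
  pw <- cat_$pathways$toy_signal
  expect_length(pw$nodes, 5L)
  expect_equal(nrow(pw$edges), 5L)
  expect_identical(pw$members$CMPD, character(0))  # non-gene node retained
  expect_setequal(pw$members$CPLX1, c("g2", "g3"))
})

test_that("malformed and inconsistent catalogue files are rejected with diagnostics", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "n.tsv")
  edges <- file.path(dir, "e.tsv")
  maps <- file.path(dir, "m.tsv")
  writeLines(c("pathway_id\tnode_id\tnode_type", "p1\tA\tprotein",
               "p1\tB\tprotein"), nodes)
  writeLines("pathway_id\tsource_node_id\ttarget_node_id", edges)
  writeLines("pathway_id\tnode_id\tgene_id", maps)

  # malformed line reports its line number
  writeLines(c("pathway_id\tnode_id\tnode_type", "p1\tA\tprotein",
               "p1\tB"), nodes)
  expect_error(read_catalogue(nodes, edges, maps), "line 3")

  # edge referencing an undeclared node
  writeLines(c("pathway_id\tnode_id\tnode_type", "p1\tA\tprotein",
               "p1\tB\tprotein"), nodes)
  writeLines(c("pathway_id\tsource_node_id\ttarget_node_id", "p1\tA\tZ"), edges)
  expect_error(read_catalogue(nodes, edges, maps), "Z")

  # duplicate node declaration
  writeLines(c("pathway_id\tnode_id\tnode_type", "p1\tA\tprotein",
               "p1\tA\tprotein"), nodes)
  writeLines("pathway_id\tsource_node_id\ttarget_node_id", edges)
  expect_error(read_catalogue(nodes, edges, maps), "duplicate")

  # empty edges file with declared nodes is a valid edgeless pathway
  writeLines(c("pathway_id\tnode_id\tnode_type", "p1\tA\tprotein"), nodes)
  cat_ <- read_catalogue(nodes, edges, maps)
  expect_length(cat_, 1L)
  expect_equal(nrow(cat_$pathways$p1$edges), 0L)
})

test_that("pathway_graph enforces its structural invariants", {
  expect_error(pathway_graph("p", character(0)), "at least one node")
  expect_error(pathway_graph("p", c("A", "A")), "duplicate")
  expect_error(pathway_graph("p", c("A", "B"), edges = cbind("A", "A")),
               "self-loop")
  expect_error(pathway_graph("p", "A", members = list(Z = "g1")), "undeclared")
  # parallel edges collapse on construction
  pw <- pathway_graph("p", c("A", "B"),
                      edges = cbind(c("A", "A"), c("B", "B")))
  expect_equal(nrow(pw$edges), 1L)
})

test_that("gene-to-node mapping follows node-as-unit semantics", {
  pw <- pathway_graph("t", c("A", "B", "C"), node_type = c("complex", "protein", "compound"),
                      members = list(A = c("g1", "g2"), B = "g1"))
  # one altered gene flips every node hosting it
  expect_identical(map_genes_to_nodes(pw, "g1"), c("A", "B"))
  # any one altered member marks the whole complex
  expect_identical(map_genes_to_nodes(pw, "g2"), "A")
  # non-gene nodes are never differential
  expect_false("C" %in% map_genes_to_nodes(pw, c("g1", "g2", "g999")))
  expect_identical(map_genes_to_nodes(pw, character(0)), character(0))
})

test_that("mapping is monotone in the differential gene list", {
  set.seed(11)
  for (rep in 1:20) {
    pw <- random_multigene_pathway(sprintf("r%d", rep))
    genes <- pathway_genes(pw)
    if (!length(genes)) next
    diff1 <- sample(genes, max(1, length(genes) %/% 3))
    diff2 <- union(diff1, sample(genes, 1))
    expect_true(all(map_genes_to_nodes(pw, diff1) %in%
                      map_genes_to_nodes(pw, diff2)))
  }
})

test_that("single-gene-per-node pathways reduce mapping to set intersection", {
  pw <- er_network(30, seed = 5)
  genes <- pathway_genes(pw)
  diff <- sample(genes, 10)
  expect_length(map_genes_to_nodes(pw, diff), 10L)
  # genes outside the pathway are ignored
  expect_length(map_genes_to_nodes(pw, c(diff, "not_a_gene")), 10L)
})

test_that("catalogue summary counts multi-gene nodes and multi-node genes", {
  pw <- pathway_graph("p", c("A", "B"), members = list(A = c("g1", "g2"), B = "g1"))
  s <- catalogue_summary(pathway_catalogue(list(pw)))
  expect_equal(s$frac_multigene_nodes, 0.5)
  expect_equal(s$frac_multinode_genes, 0.5)

  # single-gene distinct nodes: both fractions zero, node count = gene count
  pw2 <- er_network(10, seed = 3)
  s2 <- catalogue_summary(pathway_catalogue(list(pw2)))
  expect_equal(s2$frac_multigene_nodes, 0)
  expect_equal(s2$frac_multinode_genes, 0)
  expect_equal(s2$per_pathway$n_nodes, s2$per_pathway$n_genes)

  # double-counting identity on random catalogues, against a direct tally
  set.seed(21)
  cats <- pathway_catalogue(lapply(1:5, function(i)
    random_multigene_pathway(sprintf("c%d", i))))
  s3 <- catalogue_summary(cats)
  expect_equal(sum(s3$node_gene_counts), sum(s3$gene_node_counts))
  tally <- sum(vapply(cats$pathways,
                      function(p) length(unlist(p$members)), numeric(1)))
  expect_equal(sum(s3$node_gene_counts), tally)
})

test_that("differential profile validates its universe", {
  expect_error(differential_profile("g1", character(0)), "at least one")
  expect_error(differential_profile("g9", c("g1", "g2")), "absent")
  p <- differential_profile(c("g1"), c("g1", "g2"))
  expect_equal(diff_probability(p), 0.5)
})

test_that("gene list reader skips comments and blanks", {
  f <- withr::local_tempfile(lines = c("# header", "g1", "", "g2  ", "g1",
                                       "g3 # trailing"))
  expect_identical(read_gene_list(f), c("g1", "g2", "g3"))
})
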