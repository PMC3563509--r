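test_that("KGML relations map to directed, bidirectional or no edges", {
  doc <- kgml_string(
    entries = list(`1` = "a", `2` = "b"),
    relations = data.frame(entry1 = "1", entry2 = "2",
                           subtype = "activation"))
  pg <- parse_kgml(doc)
  expect_s3_class(pg, "pathway_graph")
  expect_equal(pg$pathway_id, "00001")
  expect_equal(pg$edges$source, "a")
  expect_equal(pg$edges$target, "b")
  expect_true(pg$edges$directed)

  bind <- parse_kgml(kgml_string(
    entries = list(`1` = "a", `2` = "b"),
    relations = data.frame(entry1 = "1", entry2 = "2",
                           subtype = "binding/association")))
  expect_equal(nrow(bind$edges), 1L)
  expect_false(bind$edges$directed)

  none <- parse_kgml(kgml_string(entries = list(`1` = "a", `2` = "b")))
  expect_setequal(none$genes, c("a", "b"))
  expect_equal(nrow(none$edges), 0L)

  ignored <- parse_kgml(kgml_string(
    entries = list(`1` = "a", `2` = "b"),
    relations = data.frame(entry1 = "1", entry2 = "2",
                           subtype = "dissociation")))
  expect_equal(nrow(ignored$edges), 0L)
})

test_that("multi-gene and group entries expand to gene-level edges", {
  multi <- parse_kgml(kgml_string(
    entries = list(`1` = c("a", "b"), `2` = c("c", "d")),
    relations = data.frame(entry1 = "1", entry2 = "2",
                           subtype = "activation")))
  expect_equal(nrow(multi$edges), 4L)  # full bipartite set
  expect_setequal(paste(multi$edges$source, multi$edges$target),
                  c("a c", "a d", "b c", "b d"))

  grp <- parse_kgml(kgml_string(
    entries = list(`1` = "a", `2` = "b", `3` = "c"),
    groups = list(`9` = c("2", "3")),
    relations = data.frame(entry1 = "1", entry2 = "9",
                           subtype = "phosphorylation")))
  expect_setequal(grp$edges$target, c("b", "c"))
  expect_equal(unique(grp$edges$source), "a")

  pc <- parse_kgml(kgml_string(
    entries = list(`1` = "a", `2` = "b"),
    relations = data.frame(entry1 = "1", entry2 = "2",
                           subtype = "activation", type = "PCrel")))
  expect_equal(nrow(pc$edges), 0L)  # compound-mediated links dropped
})

test_that("unknown subtypes warn and malformed XML names the source", {
  doc <- kgml_string(
    entries = list(`1` = "a", `2` = "b"),
    relations = data.frame(entry1 = "1", entry2 = "2",
                           subtype = "mystery"))
  expect_warning(pg <- parse_kgml(doc), "mystery")
  expect_equal(nrow(pg$edges), 0L)   # default policy: ignore
  expect_warning(pg2 <- parse_kgml(doc, unknown_subtype = "directed"),
                 "mystery")
  expect_equal(nrow(pg2$edges), 1L)

  bad <- tempfile(fileext = ".xml")
  writeLines("<pathway><entry", bad)
  expect_error(parse_kgml(bad), "malformed KGML")
  expect_error(parse_kgml(bad), basename(bad))
})

test_that("edge lists group by pathway, deduplicate and share genes", {
  rows <- data.frame(
    pathway_id = c("P1", "P1", "P2", "P1"),
    source = c("a", "b", "b", "a"),
    target = c("b", "c", "d", "b"),
    relation = "activation", stringsAsFactors = FALSE)
  expect_message(graphs <- read_edge_list(rows), "1 duplicate")
  expect_named(graphs, c("P1", "P2"))
  expect_setequal(intersect(graphs$P1$genes, graphs$P2$genes), "b")

  expect_error(read_edge_list(rows[-1]), "pathway_id")
  expect_error(read_edge_list(rows[0, ]), "empty")

  tf <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "pathway_id\tsource\ttarget\trelation",
               "P1\ta\tb\tactivation"), tf)
  expect_equal(read_edge_list(tf)$P1$edges$source, "a")
})

test_that("pooling merges edges, expands undirected ones and zeroes the diagonal", {
  p1 <- pathway_graph("P1", edges = data.frame(
    source = "a", target = "b", relation = "activation", directed = TRUE))
  p2 <- pathway_graph("P2", edges = data.frame(
    source = "b", target = "c", relation = "activation", directed = TRUE))
  pooled <- build_pooled(list(p1, p2))
  expect_setequal(pooled$genes, c("a", "b", "c"))
  A <- pooled$adjacency
  expect_equal(Matrix::nnzero(A), 2)
  expect_true(A["a", "b"] && A["b", "c"])

  bind <- build_pooled(list(pathway_graph("P1", edges = data.frame(
    source = "a", target = "b", relation = "binding/association",
    directed = FALSE))))
  expect_true(bind$adjacency["a", "b"] && bind$adjacency["b", "a"])

  # same edge in two pathways stays boolean, and self edges vanish
  p3 <- pathway_graph("P3", edges = data.frame(
    source = c("a", "a"), target = c("b", "a"),
    relation = "activation", directed = TRUE))
  dup <- build_pooled(list(p1, p3))
  expect_equal(max(dup$adjacency), 1)
  expect_equal(Matrix::nnzero(dup$adjacency), 1)
  expect_true(all(Matrix::diag(dup$adjacency) == 0))
})

test_that("pooling is idempotent under duplication, with zero diagonal on random fixtures", {
  for (s in 1:5) {
    spec <- synthetic_spec(n_pathways = 4, genes_per_pathway = 8,
                           edge_density = 0.3, seed = s)
    paths <- generate_pathways(spec)
    pooled <- build_pooled(paths)
    expect_true(all(Matrix::diag(pooled$adjacency) == 0))
    twice <- build_pooled(c(paths, paths))
    expect_identical(pooled, twice)
    n_bidir <- sum(vapply(paths, function(p) sum(!p$edges$directed),
                          numeric(1)))
    n_edges <- sum(vapply(paths, function(p) nrow(p$edges), numeric(1)))
    expect_lte(Matrix::nnzero(pooled$adjacency), n_edges + n_bidir)
  }
})

test_that("chip restriction deletes rows and columns literally", {
  pooled <- make_pooled(data.frame(source = c("a", "b"),
                                   target = c("b", "c")))
  r <- restrict_to_measured(pooled, c("a", "b"))
  expect_setequal(r$genes, c("a", "b"))
  expect_true(r$adjacency["a", "b"])
  expect_equal(Matrix::nnzero(r$adjacency), 1)  # b->c gone

  # unchanged when everything is measured
  full <- restrict_to_measured(pooled, c("a", "b", "c", "zzz"))
  expect_identical(full$genes, pooled$genes)
  expect_equal(Matrix::nnzero(full$adjacency),
               Matrix::nnzero(pooled$adjacency))

  # no transitive closure through the removed middle gene
  chain <- make_pooled(data.frame(source = c("a", "b"),
                                  target = c("b", "c")))
  rc <- restrict_to_measured(chain, c("a", "c"))
  expect_equal(Matrix::nnzero(rc$adjacency), 0)

  # idempotence
  once <- restrict_to_measured(pooled, c("a", "b"))
  expect_identical(once, restrict_to_measured(once, c("a", "b")))

  expect_error(restrict_to_measured(pooled, "nope"),
               "no pathway gene measured")
})

test_that("pathways losing every measured gene are retained with empty sets", {
  p1 <- pathway_graph("P1", genes = c("a", "b"))
  p2 <- pathway_graph("P2", genes = c("x", "y"))
  r <- restrict_to_measured(build_pooled(list(p1, p2)), c("a", "b"))
  expect_equal(r$membership$P2, character(0))
  expect_named(r$membership, c("P1", "P2"))
})

test_that("GMT export round-trips membership", {
  spec <- synthetic_spec(n_pathways = 3, genes_per_pathway = 6, seed = 2)
  paths <- generate_pathways(spec)
  pooled <- build_pooled(paths)
  tf <- tempfile(fileext = ".gmt")
  write_gmt(pooled, tf)
  back <- read_gmt(tf)
  expect_named(back, names(pooled$membership))
  for (id in names(back)) {
    expect_setequal(back[[id]]$genes, pooled$membership[[id]])
  }
})
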