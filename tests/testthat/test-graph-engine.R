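test_that("self-loops are removed and nothing else", {
  g <- dgraph(c("a", "a", "a", "b"))
  expect_equal(edge_set(remove_self_loops(g)), "a b")

  g2 <- dgraph(c("a", "b", "b", "c"))
  expect_equal(edge_set(remove_self_loops(g2)), edge_set(g2))

  g3 <- igraph::make_empty_graph(directed = TRUE) |>
    igraph::add_vertices(2, name = c("a", "b")) |>
    igraph::add_edges(c("a", "a", "b", "b"))
  out <- remove_self_loops(g3)
  expect_equal(igraph::ecount(out), 0)
  expect_setequal(igraph::V(out)$name, c("a", "b"))
})

test_that("cycle breaking removes the weakest-correlation edge of each cycle", {
  # profiles engineered so |cor| ranks as (a,b) > (b,c) > (c,a)
  x <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(1.1, 2.0, 3.2, 3.9, 5.1, 6.0),
             c = c(2, 1, 4, 2, 6, 9))
  cm <- abs(cor(t(x)))
  stopifnot(cm["c", "a"] < cm["b", "c"], cm["b", "c"] < cm["a", "b"])
  d <- expression_dataset(cbind(x, x + 0.01), rep(c("A", "B"), each = 6))

  g <- dgraph(c("a", "b", "b", "c", "c", "a"))
  out <- break_cycles(g, d)
  expect_true(igraph::is_dag(out))
  expect_equal(edge_set(out), c("a b", "b c"))

  acyclic <- dgraph(c("a", "b", "b", "c"))
  expect_equal(edge_set(break_cycles(acyclic, d)), edge_set(acyclic))
})

test_that("two disjoint 2-cycles lose exactly one edge each", {
  d <- random_expr(c("a", "b", "c", "d"), seed = 42)
  g <- dgraph(c("a", "b", "b", "a", "c", "d", "d", "c"))
  out <- break_cycles(g, d)
  expect_true(igraph::is_dag(out))
  expect_equal(igraph::ecount(out), 2)
  # brute force: every valid resolution keeps one edge per 2-cycle
  kept <- edge_set(out)
  expect_length(intersect(kept, c("a b", "b a")), 1)
  expect_length(intersect(kept, c("c d", "d c")), 1)
  # a 2-cycle is a correlation tie; the lexicographically smaller edge goes
  expect_equal(kept, c("b a", "d c"))
})

test_that("moralization marries parents and drops directions", {
  expect_equal(edge_set(moralize(dgraph(c("a", "c", "b", "c")))),
               c("a b", "a c", "b c"))
  expect_equal(edge_set(moralize(dgraph(c("a", "b", "b", "c")))),
               c("a b", "b c"))
  g3 <- dgraph(c("a", "d", "b", "d", "c", "d"))
  expect_equal(edge_set(moralize(g3)),
               c("a b", "a c", "a d", "b c", "b d", "c d"))
  expect_error(moralize(dgraph(c("a", "b", "b", "a"))), "acyclic")
})

test_that("triangulation fills a 4-cycle with one chord and is idempotent", {
  c4 <- ugraph(c("a", "b", "b", "c", "c", "d", "d", "a"))
  t4 <- triangulate_graph(c4)
  expect_equal(igraph::ecount(t4), 5)
  expect_equal(sum(igraph::E(t4)$fill), 1)
  expect_true(igraph::is_chordal(t4)$chordal)

  # chordal input: no fill, identical edges
  tri <- ugraph(c("a", "b", "b", "c", "a", "c"))
  out <- triangulate_graph(tri)
  expect_equal(edge_set(out), edge_set(tri))
  expect_equal(sum(igraph::E(out)$fill), 0)

  c6 <- ugraph(c("a", "b", "b", "c", "c", "d", "d", "e", "e", "f", "f", "a"))
  t6 <- triangulate_graph(c6)
  expect_true(igraph::is_chordal(t6)$chordal)  # independent oracle
  expect_true(mcs(t6)$chordal)                 # own MCS certificate agrees
  expect_equal(edge_set(triangulate_graph(t6)), edge_set(t6))
})

test_that("maximal cliques of chordal graphs are found", {
  expect_equal(chordal_cliques(ugraph(c("a", "b", "b", "c", "a", "c"))),
               list(c("a", "b", "c")))
  expect_equal(chordal_cliques(ugraph(c("a", "b", "b", "c"))),
               list(c("a", "b"), c("b", "c")))
  g <- ugraph(c("a", "b", "b", "c", "c", "d", "d", "a", "a", "c"))
  expect_equal(chordal_cliques(g), list(c("a", "b", "c"), c("a", "c", "d")))
})

test_that("junction tree separators, roots and leaves are correct", {
  jt <- junction_tree(ugraph(c("a", "b", "b", "c")))
  expect_length(jt$cliques, 2)
  expect_equal(nrow(jt$edges), 1)
  expect_equal(jt$separators[[1]], "b")

  k4 <- ugraph(c("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d"))
  jt1 <- junction_tree(k4)
  expect_length(jt1$cliques, 1)
  expect_equal(nrow(jt1$edges), 0)
  expect_equal(tree_paths(jt1), list("c1"))

  toy <- example_junction_tree()
  expect_equal(toy$jt$root, "c1")
  expect_setequal(jt_leaves(toy$jt), c("c8", "c10", "c12"))
  expect_true(check_rip(toy$jt))
})

test_that("random DAGs survive the full topology pipeline with RIP, chordality and coverage", {
  for (rep in 1:200) {
    dag <- random_dag(20, 0.2, seed = rep)
    mg <- moralize(dag)
    tg <- triangulate_graph(mg)
    expect_true(igraph::is_chordal(tg)$chordal)
    expect_true(mcs(tg)$chordal)
    expect_true(all(edge_set(mg) %in% edge_set(tg)))
    comp <- igraph::components(tg)
    for (k in seq_len(comp$no)) {
      sub <- igraph::induced_subgraph(
        tg, names(comp$membership)[comp$membership == k])
      jt <- junction_tree(sub)
      expect_true(check_rip(jt))
      # coverage: cliques cover vertices and edges
      expect_setequal(unique(unlist(jt$cliques)), igraph::V(sub)$name)
      for (e in edge_set(sub)) {
        uv <- strsplit(e, " ")[[1]]
        expect_true(any(vapply(jt$cliques,
                               function(cl) all(uv %in% cl), TRUE)))
      }
    }
  }
})

test_that("cycle breaking always yields a DAG on random graphs", {
  for (rep in 1:500) {
    set.seed(rep)
    p <- 8
    nodes <- letters[1:p]
    A <- matrix(runif(p * p) < 0.25, p, p)
    diag(A) <- FALSE
    dimnames(A) <- list(nodes, nodes)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    d <- random_expr(nodes, n_per_class = 4, seed = rep + 1000)
    out <- break_cycles(g, d)
    expect_true(igraph::is_dag(out))
    # only edges of the original graph remain
    expect_true(all(edge_set(out) %in% edge_set(g)))
  }
})

test_that("moralizing a v-structure-free DAG is the undirected skeleton", {
  chain <- dgraph(c("a", "b", "b", "c", "c", "d"))
  m1 <- moralize(chain)
  expect_equal(edge_set(m1), c("a b", "b c", "c d"))
  # moral graphs pass through triangulation unchanged when already chordal
  expect_equal(edge_set(triangulate_graph(m1)), edge_set(m1))
})
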