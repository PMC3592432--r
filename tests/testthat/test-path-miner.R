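toy <- example_junction_tree()

test_that("the toy junction tree yields three root-to-leaf paths", {
  paths <- tree_paths(toy$jt)
  expect_length(paths, 3)
  expect_true(all(vapply(paths, function(p) p[1] == "c1", TRUE)))
  expect_setequal(vapply(paths, function(p) p[length(p)], ""),
                  c("c8", "c10", "c12"))
  # star tree: k paths of length 2; chain: one path of full length
  star <- sigpath:::new_junction_tree(
    list(h = c("x", "a"), l1 = c("x", "b"), l2 = c("x", "c"), l3 = c("x", "d")),
    data.frame(from = "h", to = c("l1", "l2", "l3")), root = "h")
  expect_equal(tree_paths(star), list(c("h", "l1"), c("h", "l2"), c("h", "l3")))
  chain <- sigpath:::new_junction_tree(
    lapply(stats::setNames(1:5, paste0("k", 1:5)),
           function(i) c(paste0("g", i), paste0("g", i + 1))),
    data.frame(from = paste0("k", 1:4), to = paste0("k", 2:5)), root = "k1")
  expect_equal(tree_paths(chain), list(paste0("k", 1:5)))
})

test_that("the illustrated path decomposes into four candidate sub-paths", {
  p1 <- paste0("c", 1:8)
  cand <- extract_subpaths(p1, toy$weights, alpha = 0.05, jt = toy$jt)
  expect_length(cand, 4)
  segs <- lapply(cand, `[[`, "cliques")
  has_seg <- function(s) any(vapply(segs, identical, TRUE, s))
  expect_true(has_seg("c1"))
  expect_true(has_seg("c4"))
  expect_true(has_seg(c("c6", "c7")))
  expect_true(has_seg(c("c4", "c5", "c6", "c7")))
  # every candidate: meaningful endpoints, at most one non-meaningful inside
  for (sp in cand) {
    flags <- toy$weights[sp$cliques] < 0.05
    expect_true(flags[1] && flags[length(flags)])
    expect_lte(sum(!flags), 1)
  }
})

test_that("sub-path extraction degenerates correctly", {
  w <- c(a = 0.01, b = 0.02, c = 0.03, d = 0.01, e = 0.04)
  all_m <- extract_subpaths(names(w), w, 0.05)
  expect_length(all_m, 1)
  expect_equal(all_m[[1]]$cliques, names(w))

  w2 <- c(a = 0.01, b = 0.5, c = 0.5, d = 0.01)
  two <- extract_subpaths(names(w2), w2, 0.05)
  expect_length(two, 2)
  expect_equal(lapply(two, `[[`, "cliques"), list("a", "d"))

  w3 <- c(a = 0.5, b = 0.9)
  expect_length(extract_subpaths(names(w3), w3, 0.05), 0)
})

test_that("relevance accumulates 1 - 2w with first-maximum tie-breaking", {
  rv <- relevance(c(0.01, 0.02, 0.5))
  expect_equal(rv$o, c(0.98, 1.94, 1.94))
  expect_equal(rv$r, 1.94)
  expect_equal(rv$m, 2L)

  rv1 <- relevance(0.01)
  expect_equal(rv1$r, 0.98)
  expect_equal(rv1$m, 1L)

  rv0 <- relevance(rep(0.5, 4))
  expect_equal(rv0$r, 0)
  expect_equal(rv0$m, 1L)
})

test_that("standardized relevance divides by the position of the maximum", {
  expect_equal(standardized_relevance(1.94, 2), 0.97)
  expect_equal(standardized_relevance(0.98, 1), 0.98)
  expect_equal(standardized_relevance(1.2, 4), standardized_relevance(1.2, 2) / 2)
})

test_that("relevance ignores cliques appended after the maximum with neutral weights", {
  w <- c(0.01, 0.02)
  base <- relevance(w)
  padded <- relevance(c(w, 0.5, 0.5))
  expect_equal(padded$r, base$r)
  expect_equal(padded$m, base$m)
})

test_that("best sub-path maximizes r* with longer-then-earlier tie-breaks", {
  sp <- function(ids, w, start) sigpath:::new_subpath("p", ids, start, w)
  # equal r*: lengths 3 vs 1 -> longer wins
  a <- sp(c("c1", "c2", "c3"), c(0.1, 0.1, 0.1), 1)   # o=.8,1.6,2.4 r*=.8
  b <- sp("c9", 0.1, 9)                                # r*=0.8
  expect_equal(best_subpath(list(b, a))$cliques, c("c1", "c2", "c3"))
  # equal r* and length -> earlier start wins
  c1 <- sp("c5", 0.2, 5)
  c2 <- sp("c7", 0.2, 7)
  expect_equal(best_subpath(list(c2, c1))$cliques, "c5")
  expect_null(best_subpath(list()))
  one <- sp("c2", 0.3, 2)
  expect_equal(best_subpath(list(one))$cliques, "c2")
})

test_that("dissimilarity is the smaller relative set difference", {
  expect_equal(subpath_dissimilarity(c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(subpath_dissimilarity(c("a", "b"), c("x", "y")), 1)
  A <- paste0("g", 1:10)
  B <- c(paste0("g", 1:8), "h1", "h2")
  expect_equal(subpath_dissimilarity(A, B), 0.2)
  expect_equal(subpath_dissimilarity(B, A), 0.2)  # symmetric
  expect_equal(subpath_dissimilarity(A, A), 0)
  expect_error(subpath_dissimilarity(character(0), A), "empty")
})

test_that("pruning collapses overlapping sub-paths and keeps the best representative", {
  sp <- function(id, genes, w) {
    s <- sigpath:::new_subpath(id, id, 1, w)
    s$genes <- genes
    s
  }
  # identical gene sets always collapse; disjoint never do
  rep1 <- prune_subpaths(list(sp("a", c("x", "y"), 0.01),
                              sp("b", c("x", "y"), 0.04),
                              sp("c", c("p", "q"), 0.02)), t = 0.2)
  expect_length(rep1$representatives, 2)
  # within the collapsed cluster the higher r* (lower w) member is kept
  reps <- vapply(rep1$representatives, `[[`, "", "path")
  expect_setequal(reps, c("a", "c"))

  # all pairwise d > t: identity
  rep2 <- prune_subpaths(list(sp("a", c("x", "y"), 0.01),
                              sp("b", c("u", "v"), 0.02)), t = 0.2)
  expect_length(rep2$representatives, 2)

  rep3 <- prune_subpaths(list(sp("solo", "x", 0.01)), t = 0.2)
  expect_length(rep3$representatives, 1)
})

test_that("mined reports satisfy the structural invariants on random weights", {
  set.seed(99)
  for (rep in 1:50) {
    w <- stats::setNames(runif(12), names(toy$jt$cliques))
    out <- mine_subpaths(toy$jt, w, scoring_policy(alpha = 0.3, t = 0.2))
    for (sp in out$subpaths) {
      flags <- w[sp$cliques] < 0.3
      expect_true(flags[1] && flags[length(flags)])
      expect_lte(sum(!flags), 1)
      expect_lte(sp$m, sp$l)
      expect_equal(sp$r_star, sp$r / sp$m)
    }
    # representatives pairwise more dissimilar than t; clusters cover inputs
    reps <- out$representatives
    if (length(reps) > 1) {
      for (i in seq_len(length(reps) - 1))
        for (j in seq(i + 1, length(reps)))
          expect_gt(subpath_dissimilarity(reps[[i]], reps[[j]]), 0.2)
    }
    expect_setequal(unique(vapply(out$subpaths, `[[`, 0L, "cluster")),
                    seq_along(unique(vapply(out$subpaths, `[[`, 0L, "cluster"))))
    # determinism
    out2 <- mine_subpaths(toy$jt, w, scoring_policy(alpha = 0.3, t = 0.2))
    expect_identical(vapply(out$representatives, `[[`, "", "path"),
                     vapply(out2$representatives, `[[`, "", "path"))
  }
})

test_that("the toy's best sub-paths collapse to two representatives", {
  out <- mine_subpaths(toy$jt, toy$weights)
  expect_length(out$best, 3)      # one winner per path
  expect_length(out$representatives, 2)  # two paths share the same winner
})
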