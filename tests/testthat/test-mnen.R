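test_that("self-influence adds shell index and degree", {
  expect_equal(self_influence(3, 6), 9)
  expect_equal(self_influence(0, 0), 0)
  expect_equal(self_influence(1, 1), 2)
  expect_error(self_influence(4, 3))
})

test_that("gamma term follows the log-damped power form", {
  expect_equal(round(gamma_term(3, 5, 6), 3), 1.137)
  expect_equal(round(gamma_term(2, 3, 6), 4), 1.0567)
  # degree 1 gives exponent 0 regardless of the shell index
  expect_equal(gamma_term(1, 1, 6), 1)
  expect_equal(gamma_term(7, 1, 10), 1)
  # 0^0 convention keeps the term total
  expect_equal(gamma_term(0, 1, 5), 1)
  expect_error(gamma_term(2, 0, 6), "degree")
  expect_error(gamma_term(2, 3, 0), "kmax")
})

test_that("gamma term is >= 1 whenever Ks and d are >= 1", {
  grid <- expand.grid(ks = 1:6, d = 1:10, kmax = c(3, 6, 12))
  vals <- with(grid, gamma_term(ks, d, kmax))
  expect_true(all(vals >= 1))
  at_one <- with(grid, ks == 1 | d == 1)
  expect_true(all((vals == 1) == at_one))
})

test_that("common and exclusive neighborhoods match the worked sets", {
  g <- toy_graph()
  expect_setequal(common_neighbors(g, "v4", "v3"), c("v1", "v2"))
  expect_setequal(exclusive_neighborhood(g, "v4", "v3"),
                  c("v4", "v9", "v10"))
  expect_setequal(exclusive_neighborhood(g, "v4", "v5"), c("v14", "v4"))
  expect_error(exclusive_neighborhood(g, "v4", "v9"), "not adjacent")
  expect_error(common_neighbors(g, "v4", "v4"), "distinct")
})

test_that("common neighbors match a pairwise brute-force scan", {
  g <- random_test_graph(n = 20, p = 0.25, seed = 9)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nms <- rownames(A)
  for (vi in nms[1:8]) {
    for (vj in setdiff(nms[1:8], vi)) {
      expect_setequal(common_neighbors(g, vi, vj),
                      nms[A[vi, ] == 1 & A[vj, ] == 1])
    }
  }
})

test_that("exclusive influence handles empty sums and the focal switch", {
  # path a-b-c: EN(a,b) = {a, c}; dropping the focal leaves only c (d=1)
  g <- read_edgelist(c("a b", "b c"))
  expect_equal(exclusive_influence(g, "a", "b"), 1)
  expect_setequal(exclusive_neighborhood(g, "a", "b"), c("a", "c"))
  # triangle: every neighbor of b other than a is shared, EN \ {a} empty
  tri <- read_edgelist(c("a b", "b c", "c a"))
  expect_setequal(exclusive_neighborhood(tri, "a", "b"), "a")
  expect_equal(exclusive_influence(tri, "a", "b"), 0)
  expect_gt(exclusive_influence(tri, "a", "b", include_focal = TRUE), 0)
})

test_that("relevance is the smoothed common-neighbor weight", {
  g <- toy_graph()
  expect_equal(round(relevance(g, "v4", "v3"), 4), 0.1304)
  # no common neighbors -> 1/n guard
  expect_equal(relevance(g, "v20", "v21"), 1 / 23)
  k5 <- generate_graph("random", n = 5, p = 1, seed = 1)
  expect_equal(relevance(k5, "v1", "v2"), 4 / 5)
})

test_that("neighbor influence compositions are plain arithmetic with guards", {
  expect_equal(neighbor_initial_influence(1.137, 2.113), 3.25)
  expect_equal(round(neighbor_actual_influence(3.25, 3 / 23), 3), 0.424)
  expect_equal(neighbor_actual_influence(2.7, 1), 2.7)
  expect_error(neighbor_initial_influence(-1, 0))
  expect_error(neighbor_actual_influence(1, 0))
})

test_that("breakdowns satisfy the audit identities", {
  g <- random_test_graph(n = 25, p = 0.15, seed = 17)
  fit <- mnen(g)
  for (bd in fit$breakdowns) {
    nb <- bd$neighbors
    expect_equal(nb$ni, nb$gamma + nb$excl)
    expect_equal(nb$pni, nb$ni * nb$h)
    expect_equal(bd$k, bd$si + sum(nb$pni))
    expect_true(all(nb$h > 0 & nb$h <= 1))
  }
  expect_true(all(coef(fit) >= fit$si))
})

test_that("isolated nodes score zero and empty graphs are refused", {
  g <- igraph::add_vertices(toy_graph(), 1)
  igraph::V(g)$name[24] <- "lonely"
  fit <- mnen(g)
  expect_equal(unname(coef(fit)["lonely"]), 0)
  expect_error(mnen(igraph::make_empty_graph(0)), "empty")
  expect_error(mnen_score(toy_graph(), "nope"), "unknown node")
})

test_that("full pipeline matches the brute-force transcription", {
  for (i in 1:100) {
    n <- 6 + (i %% 10)
    g <- random_test_graph(n = n, p = 0.15 + 0.04 * (i %% 6),
                           seed = 3000 + i)
    expect_equal(coef(mnen(g)), oracle_mnen(g), tolerance = 1e-12,
                 info = paste("graph", i))
  }
  # the focal-inclusion switch agrees with the oracle's version too
  g <- random_test_graph(n = 12, p = 0.3, seed = 77)
  expect_equal(coef(mnen(g, include_focal = TRUE)),
               oracle_mnen(g, include_focal = TRUE), tolerance = 1e-12)
})

test_that("scores are invariant under node relabeling", {
  g <- random_test_graph(n = 18, p = 0.2, seed = 21)
  base <- coef(mnen(g))
  set.seed(99)
  perm <- sample(igraph::vcount(g))
  g2 <- g
  igraph::V(g2)$name <- paste0("w", perm)
  relabeled <- coef(mnen(g2))
  mapping <- stats::setNames(paste0("w", perm), igraph::V(g)$name)
  expect_equal(unname(relabeled[mapping[names(base)]]), unname(base),
               tolerance = 1e-12)
  expect_equal(sort(unname(relabeled)), sort(unname(base)),
               tolerance = 1e-12)
})

test_that("ranking orders by score with the identifier tie rule", {
  g <- toy_graph()
  rk <- ranking(mnen(g))
  expect_s3_class(rk, "node_ranking")
  expect_equal(rk$node[1], "v4")
  core_order <- rk$node[rk$node %in% c("v1", "v2", "v3", "v4")]
  expect_equal(core_order, c("v4", "v2", "v3", "v1"))
  expect_true(all(diff(rk$score) <= 0))

  # automorphic twins (leaves of the same star) tie exactly and are
  # ordered by identifier
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:6)
  srk <- ranking(mnen(star))
  leaves <- srk[srk$node != "v1", ]
  expect_equal(length(unique(leaves$score)), 1)
  expect_equal(leaves$node, paste0("v", 2:6))
})

test_that("ranking order matches sorting the oracle's scores", {
  g <- random_test_graph(n = 30, p = 0.12, seed = 55)
  rk <- ranking(mnen(g))
  ok <- oracle_mnen(g)
  expect_equal(rk$node,
               names(ok)[order(-ok, as.numeric(sub("^v", "", names(ok))))])
})

test_that("rankings export as annotated TSV", {
  g <- toy_graph()
  fit <- mnen(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(fit, path, header = "seed: 1")
  lines <- readLines(path)
  expect_true(any(grepl("^# seed: 1", lines)))
  tab <- utils::read.delim(path, comment.char = "#")
  expect_named(tab, c("node", "K", "SI", "PNI_sum", "rank"))
  expect_equal(tab$K, tab$SI + tab$PNI_sum, tolerance = 1e-12)
  expect_equal(tab$node[1], "v4")
})
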