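nt_edge <- function(pre, post, count, nt = "ach") {
  row <- data.frame(pre = pre, post = post, count = count,
                    gaba = 0, ach = 0, glut = 0, oct = 0, ser = 0, da = 0)
  row[[nt]] <- count
  row
}

simple_nodes <- function(ids) data.frame(id = ids, type = "generic",
                                         hemisphere = "left")

test_that("graph construction validates tables and applies the cutoff first", {
  edges <- rbind(nt_edge("a", "b", 15), nt_edge("a", "c", 9),
                 nt_edge("c", "b", 30))
  g <- connectomeGraph(edges, simple_nodes(c("a", "b", "c")), cutoff = 10)
  e <- edgeTable(g)
  expect_equal(nrow(e), 2)              # the 9-synapse edge is dropped
  expect_false(any(e$pre == "a" & e$post == "c"))

  expect_error(connectomeGraph(nt_edge("a", "zz", 15),
                               simple_nodes(c("a", "b"))),
               "unknown node")
  bad <- nt_edge("a", "b", 15); bad$ach <- 10
  expect_error(connectomeGraph(bad, simple_nodes(c("a", "b"))),
               "inconsistent NT counts")

  empty <- connectomeGraph(nt_edge("a", "b", 15)[0, ],
                           simple_nodes(c("a", "b")))
  expect_equal(nrow(edgeTable(empty)), 0)

  # self-loops are dropped
  g2 <- connectomeGraph(rbind(nt_edge("a", "a", 50), nt_edge("a", "b", 50)),
                        simple_nodes(c("a", "b")))
  expect_equal(nrow(edgeTable(g2)), 1)
})

test_that("node metadata round-trips through the CSV interface", {
  nodes <- data.frame(
    id = c("720575940626885124", "720575940628333788", "720575940624977847"),
    type = c("CL062 (AIP, AVLP_pr12)", "CL062 (AIP, AVLP_pr12)",
             "DNpe050 (CL341)"),
    hemisphere = c("left", "right", "left/right"))
  edges <- nt_edge(nodes$id[1], nodes$id[3], 25)
  g <- connectomeGraph(edges, nodes)
  ep <- withr::local_tempfile(fileext = ".csv")
  np <- withr::local_tempfile(fileext = ".csv")
  writeConnectomeCsv(g, ep, np)
  back <- readConnectomeCsv(ep, np)
  expect_equal(nodeTable(back), nodeTable(g))
  expect_equal(edgeTable(back), edgeTable(g))
})

test_that("series weight follows the conductance rule", {
  expect_equal(seriesWeight(30, 60), 20)
  expect_equal(seriesWeight(42, 42), 21)
  expect_equal(seriesWeight(10, 20), seriesWeight(20, 10))
  expect_error(seriesWeight(0, 5), "positive")
  set.seed(71)
  w1 <- runif(200, 0.1, 100); w2 <- runif(200, 0.1, 100)
  expect_true(all(seriesWeight(w1, w2) <= pmin(w1, w2) + 1e-12))
})

test_that("equivalent weight sums direct and one-intermediate paths", {
  # cutoff 5 so the 15/20/5 worked example applies unfiltered
  edges <- rbind(nt_edge("s", "t", 15), nt_edge("s", "m", 20),
                 nt_edge("m", "t", 5))
  g <- connectomeGraph(edges, simple_nodes(c("s", "t", "m")), cutoff = 5)
  expect_equal(equivalentWeight(g, "s", "t"), 15 + 20 * 5 / 25)
  expect_equal(equivalentWeight(g, "s", "t", maxIntermediates = 0), 15)
  expect_equal(equivalentWeight(g, "t", "s"), 0)  # direction respected
  expect_equal(equivalentWeight(g, "s", "t",
                                excludeIntermediates = "m"), 15)
  expect_error(equivalentWeight(g, "s", "s"))
})

test_that("equivalent weights equal exhaustive path enumeration on random graphs", {
  for (seed in 1:12) {
    tabs <- randomGraphTables(n_nodes = sample(5:20, 1), p_edge = 0.25,
                              seed = 700 + seed)
    g <- connectomeGraph(tabs$edges, tabs$nodes, cutoff = 10)
    ids <- nodeTable(g)$id
    pairs <- expand.grid(s = ids[1:4], t = ids[1:4],
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$t, ]
    for (r in seq_len(nrow(pairs))) {
      expect_equal(equivalentWeight(g, pairs$s[r], pairs$t[r]),
                   bruteForceEquivalent(g, pairs$s[r], pairs$t[r]),
                   tolerance = 1e-12)
    }
  }
})

test_that("NT decomposition distributes the series weight and conserves it", {
  # 10 ACh synapses in, 10 out split 6 GABA + 4 Glu
  e2 <- data.frame(pre = "m", post = "t", count = 10, gaba = 6, ach = 0,
                   glut = 4, oct = 0, ser = 0, da = 0)
  edges <- rbind(nt_edge("s", "m", 10), e2)
  g <- connectomeGraph(edges, simple_nodes(c("s", "m", "t")))
  M <- ntEquivalentWeight(g, "s", "t")
  expect_equal(M["ach", "gaba"], 3)
  expect_equal(M["ach", "glut"], 2)
  expect_equal(sum(M), seriesWeight(10, 10))

  # direct edges live on the diagonal
  gd <- connectomeGraph(nt_edge("s", "t", 12, nt = "gaba"),
                        simple_nodes(c("s", "t")))
  Md <- ntEquivalentWeight(gd, "s", "t")
  expect_equal(Md["gaba", "gaba"], 12)
  expect_equal(sum(Md != 0), 1)

  # conservation on random NT splits
  for (seed in 1:5) {
    tabs <- randomGraphTables(10, 0.3, seed = 720 + seed)
    g <- connectomeGraph(tabs$edges, tabs$nodes)
    ids <- nodeTable(g)$id
    for (r in 1:8) {
      st <- sample(ids, 2)
      expect_equal(sum(ntEquivalentWeight(g, st[1], st[2])),
                   equivalentWeight(g, st[1], st[2]), tolerance = 1e-12)
    }
  }
})

test_that("weight matrices assemble pairwise weights with zero diagonal", {
  edges <- rbind(nt_edge("s1", "t1", 40), nt_edge("s2", "m", 30),
                 nt_edge("m", "t1", 60))
  g <- connectomeGraph(edges, simple_nodes(c("s1", "s2", "m", "t1", "t2")))
  ewm <- equivalentWeightMatrix(g, c("s1", "s2"), c("t1", "t2"),
                                ntPaths = TRUE)
  W <- eqWeights(ewm)
  expect_equal(W["s1", "t1"], 40)
  expect_equal(W["s2", "t1"], seriesWeight(30, 60))
  expect_equal(unname(W[, "t2"]), c(0, 0))  # disconnected target column
  # single pair equals the scalar operation
  one <- equivalentWeightMatrix(g, "s2", "t1")
  expect_equal(as.numeric(eqWeights(one)), equivalentWeight(g, "s2", "t1"))
  # overlap: diagonal zero
  sq <- equivalentWeightMatrix(g, c("s1", "t1"), c("s1", "t1"))
  expect_equal(diag(eqWeights(sq)), c(s1 = 0, t1 = 0))
  # NT marginals agree between conventions on totals
  m2 <- ntPathwaySummary(ewm, by = "second")
  m1 <- ntPathwaySummary(ewm, by = "first")
  expect_equal(apply(m2, c(1, 2), sum), W, tolerance = 1e-12)
  expect_equal(apply(m1, c(1, 2), sum), W, tolerance = 1e-12)
})

test_that("adding a path or strengthening an edge never decreases the weight", {
  edges <- rbind(nt_edge("s", "t", 20), nt_edge("s", "m1", 30),
                 nt_edge("m1", "t", 25))
  nodes <- simple_nodes(c("s", "t", "m1", "m2"))
  g0 <- connectomeGraph(edges, nodes)
  w0 <- equivalentWeight(g0, "s", "t")
  # add a parallel path through m2
  g1 <- connectomeGraph(rbind(edges, nt_edge("s", "m2", 15),
                              nt_edge("m2", "t", 15)), nodes)
  expect_gt(equivalentWeight(g1, "s", "t"), w0)
  # strengthen one series edge
  edges2 <- edges; edges2$count[2] <- 50; edges2$ach[2] <- 50
  g2 <- connectomeGraph(edges2, nodes)
  expect_gt(equivalentWeight(g2, "s", "t"), w0)
  # weight never below the direct edge
  expect_gte(w0, 20)
})

test_that("weight matrices round-trip through CSV", {
  tabs <- randomGraphTables(8, 0.4, seed = 77)
  g <- connectomeGraph(tabs$edges, tabs$nodes)
  ids <- nodeTable(g)$id
  ewm <- equivalentWeightMatrix(g, ids[1:3], ids[4:8])
  path <- withr::local_tempfile(fileext = ".csv")
  writeWeightMatrixCsv(ewm, path)
  back <- readWeightMatrixCsv(path)
  expect_equal(eqWeights(back), eqWeights(ewm), tolerance = 1e-9)
})
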