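# helper to build a no-loop graph by hand
gnl <- function(nodes, from, to, w, marg = NULL, pt = NULL, pa = NULL) {
  e <- data.frame(from = from, to = to, weight = w,
                  p_temporal = if (is.null(pt)) rep(0.01, length(w)) else pt,
                  p_association = if (is.null(pa)) rep(0.01, length(w))
                                  else pa,
                  stringsAsFactors = FALSE)
  mutationalGraph(nodes, e,
                  nodeMarginals = if (is.null(marg))
                    setNames(seq(0.9, 0.1, length.out = length(nodes)),
                             nodes) else marg)
}

pfg <- function(nodes, from, to, conf, w = NULL) {
  new("PrimaFacieGraph", nodes = nodes,
      edges = data.frame(from = from, to = to,
                         weight = if (is.null(w)) rep(1, length(from))
                                  else w,
                         p_temporal = 1 - conf, p_association = 1 - conf,
                         confidence = conf, stringsAsFactors = FALSE),
      nodeMarginals = setNames(rep(0.5, length(nodes)), nodes),
      memberMap = list(), params = list())
}

test_that("loop removal deletes only the least confident cycle edges", {
  # acyclic input is untouched
  g0 <- pfg(c("a", "b", "c"), c("a", "b"), c("b", "c"), c(0.9, 0.8))
  out0 <- removeLoops(g0)
  expect_identical(nrow(graphEdges(out0)), 2L)

  # 2-cycle: the lower-confidence direction goes
  g2 <- pfg(c("a", "b"), c("a", "b"), c("b", "a"), c(0.9, 0.4))
  e2 <- graphEdges(removeLoops(g2))
  expect_identical(nrow(e2), 1L)
  expect_identical(e2$from, "a")

  # 3-cycle with distinct confidences: exactly the minimum is removed,
  # which brute force confirms is the unique single-edge fix
  g3 <- pfg(c("a", "b", "c"), c("a", "b", "c"), c("b", "c", "a"),
            c(0.7, 0.5, 0.9))
  e3 <- graphEdges(removeLoops(g3))
  expect_identical(nrow(e3), 2L)
  expect_false(any(e3$from == "b" & e3$to == "c"))
  for (drop in 1:3) {
    keep <- setdiff(1:3, drop)
    expect_true(igraph::is_dag(igraph::graph_from_data_frame(
      graphEdges(g3)[keep, c("from", "to")])))
  }
})

test_that("Edmonds recovers the maximum-weight arborescence", {
  g <- gnl(c("a", "b", "c"), c("a", "a", "b"), c("b", "c", "c"),
           c(0.9, 0.2, 0.5))
  e <- graphEdges(fitEdmonds(g))
  expect_setequal(paste(e$from, e$to), c("a b", "b c"))
  expect_equal(sum(e$weight), 1.4, tolerance = 1e-12)

  # single edge
  g1 <- gnl(c("a", "b"), "a", "b", 0.3)
  expect_identical(nrow(graphEdges(fitEdmonds(g1))), 1L)

  # two components give a two-rooted forest
  g2 <- gnl(c("a", "b", "c", "d"), c("a", "c"), c("b", "d"), c(1, 1))
  fit2 <- fitEdmonds(g2)
  expect_identical(nrow(graphEdges(fit2)), 2L)
  comp <- igraph::components(igraph::graph_from_data_frame(
    graphEdges(fit2)[, c("from", "to")],
    vertices = data.frame(name = graphNodes(fit2))), mode = "weak")
  expect_identical(as.integer(comp$no), 2L)

  # in-degree <= 1 everywhere on a random instance
  set.seed(30)
  rg <- randomWeightedDag(6, 0.6, acyclic = TRUE)
  g6 <- gnl(rg$nodes, rg$edges$from, rg$edges$to, rg$edges$weight)
  fe <- graphEdges(fitEdmonds(g6))
  expect_lte(max(table(fe$to)), 1L)
})

test_that("both branching engines match brute force on cyclic digraphs", {
  # the contraction engines run below the acyclic MutationalGraph
  # container, so they are exercised directly on general digraphs
  set.seed(31)
  for (i in 1:60) {
    rg <- randomWeightedDag(sample(3:6, 1), 0.6)
    if (is.null(rg$edges)) next
    e <- data.frame(from = rg$edges$from, to = rg$edges$to,
                    weight = rg$edges$weight, stringsAsFactors = FALSE)
    virt <- min(c(e$weight, 0)) - 1
    oracle <- bruteForceBranchingWeight(rg$nodes, data.frame(
      from = e$from, to = e$to, w = e$weight), virt)
    for (engine in list(mutgraph:::.chuLiuEdmonds,
                        mutgraph:::.iterativeBranching)) {
      rows <- mutgraph:::.optimumBranchingRows(rg$nodes, e, engine)
      kept <- e[rows, , drop = FALSE]
      got <- sum(kept$weight) + (length(rg$nodes) - nrow(kept)) * virt
      expect_equal(got, oracle, tolerance = 1e-9)
      expect_lte(max(c(0, table(kept$to))), 1L)
      expect_true(nrow(kept) == 0L || igraph::is_dag(
        igraph::graph_from_data_frame(kept[, c("from", "to")])))
    }
  }
  # empty graph -> empty model; chain -> chain
  empty <- mutationalGraph("a")
  expect_identical(nrow(graphEdges(fitGabow(empty))), 0L)
  ch <- gnl(c("a", "b", "c"), c("a", "b"), c("b", "c"), c(1, 1))
  expect_identical(paste(graphEdges(fitGabow(ch))$from,
                         graphEdges(fitGabow(ch))$to), c("a b", "b c"))
})

test_that("Chow-Liu keeps the max-MI skeleton and directs by marginals", {
  # construct data with known dependence structure: z depends on y on x
  set.seed(32)
  m <- 400
  x <- rbinom(m, 1, 0.7)
  y <- ifelse(x == 1, rbinom(m, 1, 0.8), rbinom(m, 1, 0.05))
  z <- ifelse(y == 1, rbinom(m, 1, 0.7), rbinom(m, 1, 0.05))
  d <- GenotypeMatrix(matrix(as.integer(c(x, y, z)), ncol = 3,
                             dimnames = list(NULL, c("x", "y", "z"))))
  st <- pairStatistics(d)
  # complete acyclic candidate graph
  g <- gnl(c("x", "y", "z"), c("x", "x", "y"), c("y", "z", "z"),
           c(1, 1, 1), marg = st$pX)
  fit <- fitChowLiu(d, g)
  e <- graphEdges(fit)
  # skeleton must be the exhaustive max-MI spanning tree
  wmat <- st$mi; diag(wmat) <- 0
  best <- exhaustiveMaxSpanningTreeWeight(wmat)
  expect_equal(sum(e$weight), best, tolerance = 1e-9)
  # directions follow marginal ordering
  for (i in seq_len(nrow(e)))
    expect_gte(st$pX[[e$from[i]]], st$pX[[e$to[i]]])
})

test_that("marginal direction ties are flagged and confluences emerge", {
  marg <- c(x = 0.6, y = 0.6, z = 0.2)
  g <- gnl(c("x", "y", "z"), c("x", "y"), c("z", "z"), c(0.5, 0.4),
           marg = marg)
  fit <- fitPrim(g)
  e <- graphEdges(fit)
  # confluence: both higher-marginal neighbours point into z
  expect_setequal(paste(e$from, e$to), c("x z", "y z"))
  expect_false(any(e$unknown_ordering))

  # equal marginals: flagged unknown ordering, deterministic direction
  g2 <- gnl(c("x", "y"), "x", "y", 0.5, marg = c(x = 0.5, y = 0.5))
  e2 <- graphEdges(fitPrim(g2))
  expect_true(e2$unknown_ordering)
  expect_identical(e2$from, "x")
})

test_that("Prim's skeleton matches Chow-Liu's when weights are the MI", {
  set.seed(33)
  for (i in 1:25) {
    t <- sampleTopology(6, 1)
    d <- sampleSCGenotypes(t, 200)
    st <- pairStatistics(d)
    nodes <- eventNames(d)
    pairs <- t(combn(nodes, 2))
    g <- gnl(nodes, pairs[, 1], pairs[, 2],
             st$mi[pairs], marg = st$pX)
    skChow <- graphEdges(fitChowLiu(d, g))
    skPrim <- graphEdges(fitPrim(g))
    expect_equal(sum(skChow$weight), sum(skPrim$weight), tolerance = 1e-9)
  }
})

test_that("triangle weights 3,2,1 keep the two heaviest undirected edges", {
  g <- gnl(c("a", "b", "c"), c("a", "b", "a"), c("b", "c", "c"),
           c(3, 2, 1), marg = c(a = 0.9, b = 0.5, c = 0.1))
  e <- graphEdges(fitPrim(g))
  expect_setequal(paste(e$from, e$to), c("a b", "b c"))
})

test_that("model likelihood factorises along the graph", {
  set.seed(34)
  v <- matrix(rbinom(200, 1, 0.4), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  d <- GenotypeMatrix(v)
  # edgeless graph: sum of Bernoulli log-likelihoods at the empirical mean
  g0 <- mutationalGraph(colnames(v))
  expected <- sum(vapply(colnames(v), function(j) {
    p <- mean(v[, j]); k <- sum(v[, j]); m <- nrow(v)
    k * log(p) + (m - k) * log(1 - p)
  }, numeric(1)))
  expect_equal(modelLikelihood(g0, d), expected, tolerance = 1e-10)

  # doubling the rows exactly doubles the log-likelihood
  d2 <- GenotypeMatrix(rbind(v, v))
  g1 <- mutationalGraph(colnames(v),
                        data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(modelLikelihood(g1, d2), 2 * modelLikelihood(g1, d),
               tolerance = 1e-10)

  # data generated from a chain: chain model dominates the edgeless one
  set.seed(35)
  dc <- sampleSCGenotypes(chainTopology(4, 0.9, 0.7), 300)
  chain <- mutationalGraph(eventNames(dc), data.frame(
    from = eventNames(dc)[1:3], to = eventNames(dc)[2:4]))
  flat <- mutationalGraph(eventNames(dc))
  expect_gte(modelLikelihood(chain, dc), modelLikelihood(flat, dc))
})

test_that("fitters never invent edges outside the no-loop graph", {
  set.seed(36)
  t <- sampleTopology(8, 1)
  d <- aggregateEvents(sampleSCGenotypes(t, 300))
  pf <- primaFacieGraph(d, B = 50)
  g <- removeLoops(pf)
  allowed <- paste(graphEdges(g)$from, graphEdges(g)$to)
  allowedUndirected <- c(allowed, paste(graphEdges(g)$to,
                                        graphEdges(g)$from))
  for (algo in c("edmonds", "gabow")) {
    fit <- switch(algo, edmonds = fitEdmonds(g), gabow = fitGabow(g))
    expect_true(all(paste(graphEdges(fit)$from, graphEdges(fit)$to)
                    %in% allowed))
  }
  for (fit in list(fitChowLiu(d, g), fitPrim(g))) {
    expect_true(all(paste(graphEdges(fit)$from, graphEdges(fit)$to)
                    %in% allowedUndirected))
  }
})

test_that("disconnected candidate components yield that many trees", {
  set.seed(37)
  t1 <- sampleTopology(4, 1, prefix = "a")
  t2 <- sampleTopology(4, 1, prefix = "b")
  v <- cbind(genotypes(sampleSCGenotypes(t1, 400)),
             genotypes(sampleSCGenotypes(t2, 400)))
  d <- aggregateEvents(GenotypeMatrix(v))
  g <- removeLoops(primaFacieGraph(d, B = 50))
  k <- length(mutgraph:::.weakComponents(graphNodes(g), graphEdges(g)))
  fit <- fitEdmonds(g)
  comp <- igraph::components(igraph::graph_from_data_frame(
    graphEdges(fit)[, c("from", "to")],
    vertices = data.frame(name = graphNodes(fit))), mode = "weak")
  expect_identical(as.integer(comp$no), as.integer(k))
  expect_identical(nrow(graphEdges(fit)),
                   length(graphNodes(fit)) - as.integer(k))
})
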