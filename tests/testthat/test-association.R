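test_that("information measures match their closed forms", {
  # independence
  expect_equal(mutualInformation(0.25, 0.5, 0.5), 0, tolerance = 1e-12)
  expect_equal(pointwiseMutualInformation(0.25, 0.5, 0.5), 0,
               tolerance = 1e-12)
  # x == y with p = 0.5: both are 1 bit
  expect_equal(mutualInformation(0.5, 0.5, 0.5), 1, tolerance = 1e-12)
  expect_equal(pointwiseMutualInformation(0.5, 0.5, 0.5), 1,
               tolerance = 1e-12)
  # nested pair: pmi = log2(0.3 / 0.18)
  expect_equal(pointwiseMutualInformation(0.3, 0.6, 0.3), log2(5 / 3),
               tolerance = 1e-12)
  # zero co-occurrence: -Inf sentinel
  expect_identical(pointwiseMutualInformation(0, 0.5, 0.5), -Inf)
  expect_gte(mutualInformation(0.3, 0.6, 0.3), 0)
})

test_that("probability estimates invert the noise model", {
  d <- nestedPairData(100)
  st <- pairStatistics(d)
  expect_equal(unname(st$pX["x"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(st$pX["y"]), 0.3, tolerance = 1e-12)
  expect_equal(st$pYgX["x", "y"], 0.5, tolerance = 1e-12)
  expect_equal(st$pYgNX["x", "y"], 0, tolerance = 1e-12)

  # an observed frequency equal to fp corrects to a true frequency of 0
  expect_equal(mutgraph:::.correctMarginal(0.005, 0.005, 0.05), 0,
               tolerance = 1e-12)
  # and correction with zero rates is the identity
  p <- seq(0, 1, by = 0.1)
  expect_equal(mutgraph:::.correctMarginal(p, 0, 0), p, tolerance = 1e-12)

  # 2x2 inversion undoes a forward-noised joint exactly
  fp <- 0.02; fn <- 0.2
  true <- c(t11 = 0.3, t10 = 0.25, t01 = 0.15, t00 = 0.3)
  A <- matrix(c(1 - fp, fp, fn, 1 - fn), 2)   # columns: true 0, 1
  # joint table with rows = x in (0,1), columns = y in (0,1)
  Tm <- matrix(c(true["t00"], true["t10"], true["t01"], true["t11"]), 2)
  Om <- A %*% Tm %*% t(A)
  got <- mutgraph:::.correctJoint(Om[2, 2], Om[2, 1], Om[1, 2], Om[1, 1],
                                  fp, fn)
  expect_equal(got$t11, unname(true["t11"]), tolerance = 1e-10)
  expect_equal(got$t01, unname(true["t01"]), tolerance = 1e-10)
  expect_error(pairStatistics(GenotypeMatrix(matrix(c(1L, NA), 2, 1))),
               "NA")
})

test_that("Suppes screening accepts nested pairs and rejects unorderable ones", {
  d <- nestedPairData(100)
  set.seed(20)
  res <- suppesTest(d, "x", "y", B = 100)
  expect_true(res$passed)
  expect_lt(res$p_temporal, 0.05)
  expect_lt(res$p_association, 0.05)

  # identical columns: temporal condition cannot hold
  v <- genotypes(d)
  dd <- GenotypeMatrix(cbind(v[, "x", drop = FALSE],
                             x2 = v[, "x"]))
  set.seed(21)
  res2 <- suppesTest(dd, "x", "x2", B = 100)
  expect_false(res2$passed)
  expect_gte(res2$p_temporal, 0.05)

  # independent Bernoulli columns: association fails in >= 85% of datasets
  set.seed(22)
  fails <- replicate(40, {
    v <- matrix(rbinom(2000, 1, 0.5), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
    r <- suppesTest(GenotypeMatrix(v), "x", "y", B = 50)
    r$p_association >= 0.05
  })
  expect_gte(mean(fails), 0.85)
})

test_that("events occurring in the same samples are merged before inference", {
  v <- matrix(c(1L, 1L, 0L, 0L,   # x1
                1L, 1L, 0L, 0L,   # x2
                1L, 0L, 0L, 0L,   # x3
                1L, 1L, 0L, 0L),  # x4
              nrow = 4, dimnames = list(paste0("s", 1:4),
                                        c("x1", "x2", "x3", "x4")))
  agg <- aggregateEvents(GenotypeMatrix(v))
  expect_identical(nEvents(agg), 2L)
  mm <- memberMap(agg)
  merged <- mm[[which(lengths(mm) == 3L)]]
  expect_setequal(merged, c("x1", "x2", "x4"))

  # all-distinct input is untouched
  v2 <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(nEvents(aggregateEvents(GenotypeMatrix(v2))), 2L)

  # two all-zero columns merge; NA is a distinct symbol
  v3 <- matrix(c(0L, 0L, 0L, 0L, NA, 0L), nrow = 2,
               dimnames = list(NULL, c("z1", "z2", "z3")))
  agg3 <- aggregateEvents(GenotypeMatrix(v3))
  expect_identical(nEvents(agg3), 2L)
  expect_setequal(memberMap(agg3)[[1]], c("z1", "z2"))
})

test_that("the prima facie graph keeps true orderings and little else", {
  # chain with nested marginals: all ancestor -> descendant pairs pass
  set.seed(23)
  d <- sampleSCGenotypes(chainTopology(3, 0.95, 0.6), 500)
  pf <- primaFacieGraph(d, B = 100)
  keys <- paste(graphEdges(pf)$from, graphEdges(pf)$to)
  expect_true(all(c("c01 c02", "c02 c03", "c01 c03") %in% keys))
  expect_s4_class(pf, "PrimaFacieGraph")
  expect_true(all(graphEdges(pf)$confidence >= 0 &
                    graphEdges(pf)$confidence <= 1))

  # single column: empty graph
  pf1 <- primaFacieGraph(GenotypeMatrix(matrix(c(1L, 0L), 2, 1)), B = 10)
  expect_identical(nrow(graphEdges(pf1)), 0L)

  # independent columns: type-I edge rate bounded near 2 * alpha
  set.seed(24)
  rates <- replicate(20, {
    v <- matrix(rbinom(6 * 300, 1, runif(6, 0.2, 0.8)[rep(1:6, each = 300)]),
                nrow = 300)
    pf <- primaFacieGraph(GenotypeMatrix(v), B = 50)
    nrow(graphEdges(pf)) / (6 * 5)
  })
  expect_lte(mean(rates), 2 * 0.05 + 3 * sd(rates) / sqrt(length(rates)))
})

test_that("pmi weights carry the -Inf sentinel for never co-occurring pairs", {
  v <- matrix(c(1L, 1L, 0L, 0L,
                0L, 0L, 1L, 0L), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  st <- pairStatistics(GenotypeMatrix(v))
  expect_identical(st$pmi["a", "b"], -Inf)
})
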