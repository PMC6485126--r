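test_that("sampled topologies are forests with the requested roots", {
  set.seed(10)
  t <- sampleTopology(20, 3)
  expect_identical(length(rootNodes(t)), 3L)
  expect_identical(nrow(trueEdges(t)), 17L)
  expect_error(sampleTopology(3, 5), "q <= n")

  t1 <- sampleTopology(1, 1)
  expect_identical(rootNodes(t1), t1@nodes)

  # every draw of (n=5, q=1) is a connected tree with 4 edges
  set.seed(11)
  for (i in 1:1000) {
    tt <- sampleTopology(5, 1)
    expect_identical(length(rootNodes(tt)), 1L)
    expect_identical(nrow(trueEdges(tt)), 4L)
  }
})

test_that("single-cell genotypes respect heredity and exclusivity", {
  # deterministic cases: all probabilities 1
  chain <- topology(c(a = NA, b = "a", c = "b"))
  set.seed(1)
  d <- sampleSCGenotypes(chain, 20)
  expect_true(all(genotypes(d) == 1L))

  one <- topology(c(a = NA))
  expect_true(all(genotypes(sampleSCGenotypes(one, 15)) == 1L))

  # star: children mutually exclusive in every sampled cell
  star <- topology(c(r = NA, b = "r", c = "r"),
                   c(r = 1, b = 0.7, c = 0.4))
  set.seed(2)
  v <- genotypes(sampleSCGenotypes(star, 10000))
  expect_true(all(v[, "b"] + v[, "c"] <= 1L))

  # heredity on a random forest: child = 1 implies parent = 1, row-wise
  set.seed(3)
  t <- sampleTopology(12, 2)
  v <- genotypes(sampleSCGenotypes(t, 2000))
  p <- parentMap(t)
  for (ch in names(p)[!is.na(p)])
    expect_true(all(v[, ch] <= v[, p[[ch]]]))
})

test_that("bulk pooling applies the presence threshold per region", {
  # all pooled cells identical: region profile equals the genotype
  chain <- topology(c(a = NA, b = "a"))
  set.seed(4)
  d <- poolBulk(chain, 6, cellsPerRegion = 10, threshold = 0.5)
  expect_true(all(genotypes(d) == 1L))
  expect_identical(dataKind(d), "multi_region")

  # threshold rule is strict: k/n > threshold
  expect_identical(as.integer(0.1 > 0.2), 0L)  # 1 of 10 at threshold 0.2
  expect_identical(as.integer(0.3 > 0.2), 1L)  # 3 of 10 at threshold 0.2
  # exercised through pooling with an event carried by a known fraction:
  # a root with probability 0 never passes any threshold
  silent <- topology(c(a = NA), c(a = 0))
  expect_true(all(genotypes(poolBulk(silent, 4, 10, 0.2)) == 0L))
})

test_that("noise injection flips entries at the specified rates", {
  v <- matrix(0L, 100, 10)
  d <- GenotypeMatrix(v)
  expect_identical(genotypes(injectNoise(d, noiseRates(0, 0))), genotypes(d))

  # all-zero matrix with fp -> 1 everywhere (rate arbitrarily close to 1)
  set.seed(6)
  flipped <- genotypes(injectNoise(d, noiseRates(0.999, 0)))
  expect_gt(mean(flipped), 0.99)

  # flip fraction matches the rate within a 99% binomial interval
  ones <- GenotypeMatrix(matrix(1L, 1000, 100))
  set.seed(7)
  out <- genotypes(injectNoise(ones, noiseRates(0, 0.05)))
  expect_lt(abs(mean(out == 0L) - 0.05), 0.003)

  # NA entries are untouched
  vna <- matrix(c(1L, NA, 0L, NA), 2)
  set.seed(8)
  outNA <- genotypes(injectNoise(GenotypeMatrix(vna), noiseRates(0.4, 0.4)))
  expect_identical(unname(is.na(outNA)), is.na(vna))
})

test_that("missing-data injection is exact and uniform", {
  d <- GenotypeMatrix(matrix(1L, 75, 11))
  expect_identical(genotypes(injectMissing(d, 0)), genotypes(d))
  set.seed(9)
  expect_identical(sum(is.na(genotypes(injectMissing(d, 0.4)))), 330L)

  # positions cover all cells approximately uniformly (chi-square)
  small <- GenotypeMatrix(matrix(1L, 5, 4))
  set.seed(10)
  counts <- matrix(0, 5, 4)
  for (i in 1:1000)
    counts <- counts + is.na(genotypes(injectMissing(small, 0.25)))
  # each cell hit ~ 1000 * 5/20 = 250 times
  chisq <- sum((counts - 250)^2 / 250)
  expect_lt(chisq, qchisq(0.999, df = 19))
})

test_that("confounder columns use biases from the observed marginals", {
  d <- GenotypeMatrix(matrix(1L, 50, 1))
  set.seed(11)
  out <- addConfounders(d, 3)
  expect_identical(nEvents(out), 4L)
  expect_true(all(genotypes(out)[, 2:4] == 1L))  # only available bias is 1

  # default count is ~10% of n
  d20 <- GenotypeMatrix(matrix(rbinom(200, 1, 0.5), 10, 20))
  set.seed(12)
  expect_identical(nEvents(addConfounders(d20)), 22L)
})

test_that("generators are bit-reproducible under a fixed seed", {
  run <- function() {
    set.seed(99)
    sim <- simulateDataset(n = 8, q = 2, m = 30, noise = noiseRates(0.01, 0.1),
                           missingRate = 0.1, nConfounders = 1)
    list(parentMap(sim$topology), genotypes(sim$dataset))
  }
  expect_identical(run(), run())
})

test_that("topologies round-trip through their text format", {
  set.seed(13)
  t <- sampleTopology(9, 2)
  f <- tempfile(fileext = ".tsv")
  writeTopology(t, f)
  t2 <- readTopology(f)
  expect_identical(parentMap(t2), parentMap(t))
  expect_equal(nodeProb(t2), nodeProb(t), tolerance = 1e-9)
})
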