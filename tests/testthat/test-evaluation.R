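alloc <- function(...) {
  v <- c(...)
  EnzymeAllocation(v, total = sum(v))
}

test_that("pairing intersects supports above the usage floor", {
  a <- alloc(P1 = 1e-3, P2 = 2e-3, P3 = 3e-3, P4 = 4e-3, P5 = 5e-3)
  pv <- pairAllocations(a, a)
  expect_equal(pv@nPairs, 5L)
  expect_equal(pv@x, pv@y)

  b <- alloc(Q1 = 1e-3, Q2 = 2e-3)
  expect_error(pairAllocations(a, b), class = "parrot_overlap")

  # overlap in 3 of 5 ids, with one of them zero-valued in the
  # prediction: 3 candidate pairs, 1 dropped at the floor
  pred <- alloc(P1 = 1e-3, P2 = 2e-3, P3 = 0, X1 = 1e-3, X2 = 1e-3)
  base <- alloc(P1 = 2e-3, P2 = 1e-3, P3 = 5e-4, Y1 = 1e-3, Y2 = 1e-3)
  pv2 <- pairAllocations(pred, base)
  expect_equal(pv2@nPairs, 2L)
  expect_equal(pv2@nDroppedZero, 1L)
  expect_setequal(pv2@ids, c("P1", "P2"))
})

test_that("pearson matches the covariance formula and its invariances", {
  a <- alloc(P1 = 1e-3, P2 = 2e-3, P3 = 3e-3)
  expect_equal(pairedPearson(pairAllocations(a, a)), 1)
  # reverse-ordered linear transform: r = -1
  rev <- EnzymeAllocation(c(P1 = 3e-3, P2 = 2e-3, P3 = 1e-3),
                          total = 6e-3)
  pv <- pairAllocations(
    alloc(P1 = 10^0, P2 = 10^1, P3 = 10^2),
    alloc(P1 = 10^2, P2 = 10^1, P3 = 10^0))
  expect_equal(pairedPearson(pv), -1)
  # direct formula oracle on x = (0,1,2), y = (0,1,3)
  pv2 <- new("PairedLogVectors", ids = c("a", "b", "c"),
             x = c(0, 1, 2), y = c(0, 1, 3), nPairs = 3L,
             nDroppedZero = 0L)
  x <- pv2@x; y <- pv2@y
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pairedPearson(pv2), oracle)
  # invariant under positive affine transforms of either vector
  pv3 <- pv2; pv3@y <- 2 * pv2@y + 5
  expect_equal(pairedPearson(pv3), pairedPearson(pv2))
  # zero variance is undefined
  pvz <- new("PairedLogVectors", ids = c("a", "b"), x = c(1, 1),
             y = c(1, 2), nPairs = 2L, nDroppedZero = 0L)
  expect_error(pairedPearson(pvz), class = "parrot_degenerate")
})

test_that("rmdse is the root median of squared log gaps", {
  a <- alloc(P1 = 1e-3, P2 = 2e-3, P3 = 3e-3)
  expect_equal(pairedRmdse(pairAllocations(a, a)), 0)
  # predictions exactly 10x the baseline: every log10 gap is 1
  ten <- EnzymeAllocation(a@values * 10, total = sum(a@values) * 10)
  expect_equal(pairedRmdse(pairAllocations(ten, a)), 1)
  # hand-computed median of gaps (0.1, 0.3, 0.5)
  pv <- new("PairedLogVectors", ids = c("a", "b", "c"),
            x = c(0.1, 0.3, 0.5), y = c(0, 0, 0), nPairs = 3L,
            nDroppedZero = 0L)
  expect_equal(pairedRmdse(pv), sqrt(0.09))
  # even count: midpoint-mean median; depends only on gaps
  pv4 <- new("PairedLogVectors", ids = letters[1:4],
             x = c(0.1, 0.2, 0.4, 0.8), y = rep(0, 4), nPairs = 4L,
             nDroppedZero = 0L)
  expect_equal(pairedRmdse(pv4), sqrt((0.04 + 0.16) / 2))
  shift <- pv4; shift@x <- pv4@x + 3; shift@y <- pv4@y + 3
  expect_equal(pairedRmdse(shift), pairedRmdse(pv4))
})

test_that("pairwise Wilcoxon with Bonferroni matches enumeration", {
  # identical score lists: p = 1
  same <- list(m1 = c(1, 2, 3, 4), m2 = c(1, 2, 3, 4))
  expect_equal(compareMethods(same)["m1", "m2"], 1)
  # complete separation of n = 3 vs n = 3: the exact two-sided rank-sum
  # p is 2 / choose(6, 3) = 0.1 (enumeration over all 20 assignments)
  sep <- list(m1 = c(1, 2, 3), m2 = c(10, 20, 30))
  expect_equal(compareMethods(sep)["m1", "m2"], 2 / choose(6, 3))
  # three methods: 3 pairwise tests, each raw p multiplied by 3, cap 1
  three <- list(a = c(1, 2, 3), b = c(10, 20, 30), c = c(1.5, 2.5, 3.5))
  P <- compareMethods(three)
  expect_equal(P["a", "b"], min(1, 3 * 2 / choose(6, 3)))
  expect_equal(P["a", "c"], 1)  # raw p 0.7 -> capped
  # symmetry and undefined diagonal
  expect_equal(P, t(P))
  expect_true(all(is.na(diag(P))))
  expect_error(compareMethods(list(a = 1:3, b = 1:4)),
               class = "parrot_alignment")
})

test_that("the lambda sweep scores the grid and prefers small ties", {
  toy <- generateToyPcgem(ToySpec(seed = 61))
  sim <- simulateCondition(toy, perturbation = "scale_uptake",
                           noiseSigma = 0.1)
  am <- applyCondition(sim$model, sim$cond)$model
  bm <- benchmarkCondition(toy, sim, methods = "LP1")
  estot <- conditionEnzymeTotal(sim$cond, am)
  # baseline equal to the lambda = 0 solution: r = 1 is unbeatable and
  # ties resolve toward the smallest lambda
  lp20 <- solveParrot(am, "LP2", reference = bm$eRef, estot = estot,
                      vref = bm$vRef, lambda = 0)
  selfBase <- predictedAllocation(lp20)
  sw <- sweepLambda(am, "LP2", reference = bm$eRef, estot = estot,
                    baseline = selfBase, vref = bm$vRef,
                    grid = seq(0, 1, by = 0.1))
  expect_equal(sw$optimal, 0)
  expect_equal(nrow(sw$curve), 11L)
  expect_equal(sw$curve$pearson[1L], 1, tolerance = 1e-9)
  # restricting the grid to 0.1..1 echoes the second scenario
  sw2 <- sweepLambda(am, "LP2", reference = bm$eRef, estot = estot,
                     baseline = selfBase, vref = bm$vRef,
                     grid = seq(0.1, 1, by = 0.1))
  expect_equal(sw2$optimal, 0.1)
  # argmax agrees with exhaustive re-scoring of the curve
  sw3 <- sweepLambda(am, "LP2", reference = bm$eRef, estot = estot,
                     baseline = bm$baseline, vref = bm$vRef,
                     grid = seq(0, 1, by = 0.1))
  ok <- !is.na(sw3$curve$pearson)
  best <- sw3$curve$lambda[ok][which.max(sw3$curve$pearson[ok])]
  expect_equal(sw3$optimal, best)
})
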