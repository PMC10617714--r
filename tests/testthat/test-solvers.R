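# Distance variants, benchmarks and null model.  The heavier
# oracle-equivalence sweep lives in test-acceptance.R; here the solvers
# are checked against closed forms and small brute-force searches.

test_that("a feasible reference is returned unchanged at zero distance", {
  fx <- fixtureSuite()$chain3
  for (variant in c("LP1", "QP1", "LP2", "QP2")) {
    res <- solveParrot(fx$model, variant, reference = fx$eref,
                       estot = fx$estot, vref = fx$vref, lambda = 0)
    expect_equal(solveStatus(res), "optimal")
    expect_lt(objectiveValue(res), 1e-6)
    pred <- predictedAllocation(res)@values[names(fx$eref@values)]
    expect_equal(pred / fx$estot,
                 fx$eref@values / allocationTotal(fx$eref),
                 tolerance = 1e-6)
  }
})

test_that("lambda = 0 reduces the two-term variants to the one-term ones", {
  for (fx in fixtureSuite()[c("branch", "toy1")]) {
    lp1 <- solveParrot(fx$model, "LP1", reference = fx$eref,
                       estot = fx$estot)
    lp2 <- solveParrot(fx$model, "LP2", reference = fx$eref,
                       estot = fx$estot, vref = fx$vref, lambda = 0)
    expect_equal(objectiveValue(lp2), objectiveValue(lp1),
                 tolerance = 1e-6)
    expect_equal(predictedAllocation(lp2)@values,
                 predictedAllocation(lp1)@values, tolerance = 1e-6)
    qp1 <- solveParrot(fx$model, "QP1", reference = fx$eref,
                       estot = fx$estot)
    qp2 <- solveParrot(fx$model, "QP2", reference = fx$eref,
                       estot = fx$estot, vref = fx$vref, lambda = 0)
    expect_equal(objectiveValue(qp2), objectiveValue(qp1),
                 tolerance = 1e-6)
    expect_equal(predictedAllocation(qp2)@values,
                 predictedAllocation(qp1)@values, tolerance = 1e-6)
  }
})

test_that("a blocked branch forces reallocation matching brute force", {
  # reference built on the branch model, then route B blocked; all flux
  # must move to the (worse) A branch
  m <- branchModel(c(100, 400))
  wm <- makeIrreversible(withGrowth(m, 0.95, 1.05))
  u <- .usageAt(wm, 1)                 # reference uses only route B
  eref <- EnzymeAllocation(u$usage[u$usage > 0], total = sum(u$usage))
  estot <- 0.0105                       # enough for the 4x worse route
  blocked <- wm
  blocked@ub[match("rB", blocked@reactions)] <- 0
  res <- solveParrot(blocked, "LP1", reference = eref, estot = estot)
  expect_equal(solveStatus(res), "optimal")
  # brute force: mu in the growth interval, eb the normalized EB value;
  # the EA coupling forces ea >= mu/100/estot and the budget ea+eb = 1
  a <- unname(eref@values["EB"] / allocationTotal(eref))  # = 1
  grid <- expand.grid(mu = seq(0.95, 1.05, by = 0.001),
                      eb = seq(0, 1, by = 0.0001))
  feas <- grid$mu / 100 / estot + grid$eb <= 1 + 1e-12
  best <- min(abs(a - grid$eb)[feas])
  # closed form: shave EB by exactly the EA requirement at mu_lo
  expect_equal(objectiveValue(res), 0.95 / 100 / estot,
               tolerance = 1e-6)
  # the grid search cannot beat the LP optimum (resolution 1e-4)
  expect_lte(objectiveValue(res), best + 1e-12)
  expect_lt(best - objectiveValue(res), 2e-4)
  # the A enzyme must carry the full rerouted flux
  pred <- predictedAllocation(res)@values
  expect_gte(unname(pred["EA"]), 0.95 / 100 - 1e-9)
})

test_that("pFBA minimizes total flux and reports usage as allocation", {
  m <- chainModel(c(100, 200, 400))
  cm <- makeIrreversible(withGrowth(m, 1, 1))
  res <- solvePfba(cm, estot = 1)
  expect_equal(solveStatus(res), "optimal")
  # forced chain at flux 1: 3 internal reactions + uptake + biomass
  expect_equal(objectiveValue(res), 5, tolerance = 1e-9)
  expect_equal(predictedAllocation(res)@values,
               c(E1 = 1 / 100, E2 = 1 / 200, E3 = 1 / 400),
               tolerance = 1e-9)
})

test_that("pFBA prefers the shorter route irrespective of kcat", {
  # route A: two reactions with excellent kcats; route B: one reaction
  # with a poor kcat; flux-parsimony must still pick B
  mets <- c("A", "X", "B")
  rxns <- c("upt", "rA1", "rA2", "rB", "bio")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "upt"] <- 1
  S["A", c("rA1", "rB")] <- -1
  S["X", "rA1"] <- 1; S["X", "rA2"] <- -1
  S["B", c("rA2", "rB")] <- 1
  S["B", "bio"] <- -1
  m <- EnzymeConstrainedModel(
    metabolites = mets, reactions = rxns, S = S,
    lb = rep(0, 5), ub = c(10, rep(1000, 4)),
    biomassRxn = "bio", enzymes = c("eA1", "eA2", "eB"),
    kcat = data.frame(enzyme = c("eA1", "eA2", "eB"),
                      reaction = c("rA1", "rA2", "rB"),
                      kcat = c(1e5, 1e5, 100)))
  res <- solvePfba(withGrowth(m, 1, 1), estot = 1)
  # brute force over the route split
  split <- seq(0, 1, by = 0.01)   # share through A
  tot <- 2 + split * 2 + (1 - split) * 1  # upt + bio + route reactions
  expect_equal(objectiveValue(res), min(tot), tolerance = 1e-9)
  expect_equal(unname(fluxes(res)["rB"]), 1, tolerance = 1e-9)
  # EsKcat minimizes total *catalysed* flux (E * kcat = v at the
  # optimum), so it also prefers the one-reaction route, but exchange
  # and biomass fluxes drop out of its objective
  ek <- solvePfbaEsKcat(withGrowth(m, 1, 1), estot = 1)
  expect_equal(unname(fluxes(ek)["rB"]), 1, tolerance = 1e-8)
  expect_equal(objectiveValue(ek),
               min(split * 2 + (1 - split)), tolerance = 1e-7)
})

test_that("EsKcat equals total catalysed flux on forced chains", {
  m <- chainModel(c(100, 200, 400))
  cm <- withGrowth(m, 1, 1)
  ek <- solvePfbaEsKcat(cm, estot = 1)
  # binding E_i = v/kcat_i makes E * kcat = v for every catalysed pair
  expect_equal(objectiveValue(ek), 3, tolerance = 1e-8)
})

test_that("a closed model yields the all-zero solution", {
  m <- chainModel(c(100, 200, 400), uptakeUb = 0)
  cm <- withGrowth(m, 0, 0)
  res <- solvePfba(cm, estot = 1)
  expect_equal(solveStatus(res), "optimal")
  expect_equal(objectiveValue(res), 0, tolerance = 1e-12)
  expect_true(all(abs(fluxes(res)) < 1e-12))
  expect_true(all(predictedAllocation(res)@values < 1e-12))
})

test_that("the null model aggregates kcats per enzyme by rule", {
  m <- chainModel(c(3600, 200, 400))
  expect_equal(unname(nullAllocation(m)@values["E1"]), 3600)
  # enzyme catalysing two reactions
  m2 <- branchModel(c(100, 400))
  m2@kcat[1, match("rB", m2@reactions)] <- 500  # EA also catalyses rB
  expect_equal(unname(nullAllocation(m2, rule = "max")@values["EA"]), 500)
  expect_equal(unname(nullAllocation(m2, rule = "mean")@values["EA"]), 300)
  expect_equal(unname(nullAllocation(m2, rule = "first")@values["EA"]), 100)
})

test_that("the null model decorrelates from kcat-independent allocations", {
  # planted allocations drawn independently of kcat: |r| must stay low
  nlow <- 0L
  for (s in 1:100) {
    set.seed(s)
    k <- exp(runif(50, log(100), log(1e5)))
    planted <- 10^rnorm(50, -4, 0.8)
    r <- cor(log10(k), log10(planted))
    if (abs(r) < 0.5) nlow <- nlow + 1L
  }
  expect_gte(nlow, 90L)
})

test_that("allocation distances are invariant to reference rescaling", {
  fx <- fixtureSuite()$toy1
  scaled <- EnzymeAllocation(fx$eref@values * 7,
                             total = allocationTotal(fx$eref) * 7)
  for (variant in c("LP1", "QP1")) {
    r1 <- solveParrot(fx$model, variant, reference = fx$eref,
                      estot = fx$estot)
    r2 <- solveParrot(fx$model, variant, reference = scaled,
                      estot = fx$estot)
    expect_equal(objectiveValue(r1), objectiveValue(r2),
                 tolerance = 1e-8)
    expect_equal(predictedAllocation(r1)@values,
                 predictedAllocation(r2)@values, tolerance = 1e-7)
  }
})

test_that("optimal solves satisfy the feasibility contract", {
  fxs <- fixtureSuite()[c("chain3", "branch", "toy1", "toy4")]
  for (fx in fxs) {
    res <- solveParrot(fx$model, "LP1", reference = fx$eref,
                       estot = fx$estot)
    rr <- solutionResiduals(fx$model, res)
    scale <- max(1, max(abs(res@fluxIrrev)))
    expect_lt(rr$stoich / scale, 1e-6)
    expect_lt(rr$coupling / max(res@allocation@total, 1e-9), 1e-6)
    # distance variants hold the total as an equality
    expect_lt(abs(sum(res@allocation@values) - fx$estot) / fx$estot,
              1e-6)
    mu <- unname(res@fluxIrrev[biomassReaction(fx$model)])
    expect_gte(mu, 0.95 * fx$mu - 1e-9)
    expect_lte(mu, 1.05 * fx$mu + 1e-9)
  }
})

test_that("infeasible conditions surface as infeasible results", {
  m <- chainModel(c(100, 200, 400), uptakeUb = 0.1)
  cm <- withGrowth(m, 1, 1.05)   # uptake cannot support the growth
  fx <- fixtureSuite()$chain3
  res <- solveParrot(cm, "LP1", reference = fx$eref, estot = 1)
  expect_equal(solveStatus(res), "infeasible")
})
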