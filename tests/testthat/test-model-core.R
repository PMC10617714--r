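test_that("constructor enforces model invariants", {
  m <- chainModel()
  expect_true(validObject(m))
  expect_equal(dim(stoichMatrix(m)),
               c(length(metaboliteIds(m)), length(reactionIds(m))))
  expect_error(EnzymeConstrainedModel(
    metabolites = "A", reactions = "r", S = matrix(1, 1, 1),
    lb = 1, ub = 0, biomassRxn = "r"), "lb > ub")
  expect_error(EnzymeConstrainedModel(
    metabolites = "A", reactions = "r", S = matrix(1, 1, 1),
    biomassRxn = "nope"), "biomassRxn")
  expect_error(EnzymeConstrainedModel(
    metabolites = "A", reactions = "r", S = matrix(1, 1, 1),
    biomassRxn = "r", enzymes = "E",
    kcat = data.frame(enzyme = "E", reaction = "r", kcat = -5)),
    "kcat")
})

test_that("native toy JSON round-trip is lossless", {
  toy <- generateToyPcgem(ToySpec(nLinear = 3L, reversibleFraction = 0.5,
                                  seed = 11))
  m <- toy$model
  path <- tempfile(fileext = ".json")
  writeToyModel(m, path)
  m2 <- readToyModel(path)
  expect_identical(reactionIds(m2), reactionIds(m))
  expect_identical(metaboliteIds(m2), metaboliteIds(m))
  expect_equal(as.matrix(stoichMatrix(m2)), as.matrix(stoichMatrix(m)))
  expect_equal(m2@lb, m@lb)
  expect_equal(m2@ub, m@ub)
  expect_equal(as.matrix(kcatMatrix(m2)), as.matrix(kcatMatrix(m)))
  expect_equal(poolTotal(m2), poolTotal(m))
  expect_equal(enzymeBounds(m2), enzymeBounds(m))
})

test_that("GECKO SBML import decodes the pseudo-metabolite encoding", {
  # hand-written minimal GECKO-dialect file: one enzyme with
  # stoichiometry 1/3600 on its pseudo-metabolite row
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1">
<model id="mini">
<listOfParameters>
  <parameter id="lb0" value="0" constant="true"/>
  <parameter id="ub10" value="10" constant="true"/>
  <parameter id="ub1000" value="1000" constant="true"/>
  <parameter id="pool" value="0.05" constant="true"/>
</listOfParameters>
<listOfSpecies>
  <species id="A"/><species id="B"/>
  <species id="prot_P1"/><species id="prot_pool"/>
</listOfSpecies>
<listOfReactions>
  <reaction id="upt" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
  </reaction>
  <reaction id="R1" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
    <listOfReactants>
      <speciesReference species="A" stoichiometry="1"/>
      <speciesReference species="prot_P1" stoichiometry="0.000277777777777778"/>
    </listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
  </reaction>
  <reaction id="biomass" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
  </reaction>
  <reaction id="draw_prot_P1" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="prot_pool" stoichiometry="40"/></listOfReactants>
    <listOfProducts><speciesReference species="prot_P1" stoichiometry="1"/></listOfProducts>
  </reaction>
  <reaction id="prot_pool_exchange" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="pool">
    <listOfProducts><speciesReference species="prot_pool" stoichiometry="1"/></listOfProducts>
  </reaction>
</listOfReactions>
</model>
</sbml>'
  path <- tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- importGeckoSBML(path)
  expect_setequal(metaboliteIds(m), c("A", "B"))
  expect_setequal(reactionIds(m), c("upt", "R1", "biomass"))
  expect_identical(enzymeIds(m), "P1")
  expect_equal(kcatMatrix(m)["P1", "R1"], 3600, tolerance = 1e-12)
  expect_equal(poolTotal(m), 0.05)
  expect_equal(unname(m@enzymeMw["P1"]), 40)
  expect_equal(biomassReaction(m), "biomass")

  # enzyme metabolite produced by a non-usage reaction is not GECKO
  bad <- sub('<listOfReactants>\n      <speciesReference species="A" stoichiometry="1"/>\n      <speciesReference species="prot_P1" stoichiometry="0.000277777777777778"/>\n    </listOfReactants>',
             '<listOfProducts><speciesReference species="prot_P1" stoichiometry="1"/></listOfProducts>',
             sbml, fixed = TRUE)
  writeLines(bad, path)
  expect_error(importGeckoSBML(path), class = "parrot_dialect")

  # missing biomass reaction
  nobio <- gsub("biomass", "demandX", sbml, fixed = TRUE)
  writeLines(nobio, path)
  expect_error(importGeckoSBML(path), class = "parrot_structure")
})

test_that("model without enzyme rows imports as a plain FBA model", {
  m0 <- chainModel()
  m0@enzymes <- character(); m0@enzymeUb <- numeric()
  m0@enzymeMw <- numeric()
  m0@kcat <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                  x = numeric(),
                                  dims = c(0L, length(m0@reactions)))
  path <- tempfile(fileext = ".xml")
  exportGeckoSBML(m0, path)
  m <- importGeckoSBML(path, biomassRxn = "bio")
  expect_length(enzymeIds(m), 0L)
  expect_equal(length(kcatMatrix(m)@x), 0L)
  fba <- solveFBA(withGrowth(m, 0, 1000))
  expect_equal(solveStatus(fba), "optimal")
  expect_equal(objectiveValue(fba), 10, tolerance = 1e-9)  # uptake-limited
})

test_that("GECKO SBML export -> import round-trips a synthetic model", {
  toy <- generateToyPcgem(ToySpec(nLinear = 2L, seed = 21))
  m <- toy$model
  path <- tempfile(fileext = ".xml")
  exportGeckoSBML(m, path)
  m2 <- importGeckoSBML(path, biomassRxn = "bio")
  expect_setequal(reactionIds(m2), reactionIds(m))
  ord <- match(reactionIds(m), reactionIds(m2))
  expect_equal(as.matrix(stoichMatrix(m2))[metaboliteIds(m), ord],
               as.matrix(stoichMatrix(m)))
  expect_equal(m2@lb[ord], m@lb)
  expect_equal(m2@ub[ord], m@ub)
  expect_equal(as.matrix(kcatMatrix(m2))[enzymeIds(m), ord],
               as.matrix(kcatMatrix(m)), tolerance = 1e-12)
  expect_equal(poolTotal(m2), poolTotal(m))
})

test_that("makeIrreversible splits reversible reactions and keeps FBA", {
  m <- chainModel()
  m@lb[3] <- -10; m@reversible[3] <- TRUE   # make r2 reversible
  wm <- makeIrreversible(m)
  expect_true(all(wm@lb >= 0))
  expect_true("r2_REV" %in% reactionIds(wm))
  j <- match(c("r2", "r2_REV"), reactionIds(wm))
  expect_equal(wm@ub[j], c(1000, 10))
  # kcat duplicated onto both directions
  expect_equal(kcatMatrix(wm)["E2", "r2"], 200)
  expect_equal(kcatMatrix(wm)["E2", "r2_REV"], 200)
  # idempotent on already-irreversible models
  wm2 <- makeIrreversible(wm)
  expect_identical(reactionIds(wm2), reactionIds(wm))
  expect_identical(wm2@revMap$sign, rep(1, length(reactionIds(wm))))
})

test_that("splitting preserves maximal growth on seeded toys", {
  for (s in 31:33) {
    toy <- generateToyPcgem(ToySpec(nLinear = 3L,
                                    reversibleFraction = 0.6, seed = s))
    m <- withGrowth(toy$model, 0, 1000)
    f1 <- solveFBA(m, estot = poolTotal(m))
    f2 <- solveFBA(makeIrreversible(m), estot = poolTotal(m))
    expect_equal(objectiveValue(f1), objectiveValue(f2),
                 tolerance = 1e-8)
    # net flux of the split solve is feasible in the original model
    v <- fluxes(f2)[reactionIds(m)]
    expect_lt(max(abs(as.numeric(stoichMatrix(m) %*% v))), 1e-8)
    expect_true(all(v >= m@lb - 1e-8 & v <= m@ub + 1e-8))
  }
})

test_that("applyCondition imposes bounds without relaxation when feasible", {
  m <- chainModel(kcats = c(100, 200, 400))
  cond <- ConditionConstraints(mu = 0.1, uptakeBounds = c(upt = 10),
                               enzymeTotal = 1)
  out <- applyCondition(m, cond)
  expect_equal(nrow(out$relaxation), 0L)
  jb <- match("bio", reactionIds(out$model))
  expect_equal(out$model@lb[jb], 0.095)
  expect_equal(out$model@ub[jb], 0.105)
  expect_equal(out$model@ub[match("upt", reactionIds(out$model))], 10)
})

test_that("growth flexibility absorbs a 5% shortfall without relaxation", {
  # uptake bound caps max growth at exactly 0.095 = mu * (1 - flex)
  m <- chainModel()
  cond <- ConditionConstraints(mu = 0.1, uptakeBounds = c(upt = 0.095),
                               enzymeTotal = 1, growthFlex = 0.05)
  out <- applyCondition(m, cond)
  expect_equal(nrow(out$relaxation), 0L)
  expect_equal(out$maxGrowth, 0.095, tolerance = 1e-9)
})

test_that("multiplicative relaxation count follows the closed form", {
  # uptake bound forces max growth mu/2; growthFlex 0 so the bound must
  # grow by a factor 2: ceil(log(2)/log(1.01)) rounds of 1% steps
  m <- chainModel()
  cond <- ConditionConstraints(mu = 0.1, uptakeBounds = c(upt = 0.05),
                               enzymeTotal = 1, growthFlex = 0,
                               boundFlexStep = 0.01)
  out <- applyCondition(m, cond)
  expect_equal(nrow(out$relaxation), ceiling(log(2) / log(1.01)))
  # bounds were only relaxed, never tightened, across rounds
  expect_true(all(diff(out$relaxation$factor) > 0))
  expect_true(all(diff(out$relaxation$maxGrowth) >= -1e-12))
  expect_gte(out$maxGrowth, 0.1 - 1e-9)
})

test_that("infeasible conditions fail with the relaxation log attached", {
  m <- chainModel()
  cond <- ConditionConstraints(mu = 0.1, uptakeBounds = c(upt = 0.05),
                               enzymeTotal = 1, growthFlex = 0,
                               maxFlexRounds = 5L)
  err <- tryCatch(applyCondition(m, cond), error = identity)
  expect_s3_class(err, "parrot_infeasible")
  expect_equal(nrow(err$relaxation), 5L)
})

test_that("condition YAML round-trips", {
  cond <- ConditionConstraints(mu = 0.23, uptakeBounds = c(upt = 3.2),
                               proteinContent = 0.4, enzymeTotal = 0.01,
                               growthFlex = 0.1, label = "c1")
  path <- tempfile(fileext = ".yml")
  writeCondition(cond, path)
  c2 <- readCondition(path)
  expect_equal(c2@mu, 0.23)
  expect_equal(c2@uptakeBounds, c(upt = 3.2))
  expect_equal(c2@growthFlex, 0.1)
  expect_equal(c2@label, "c1")
})

test_that("enzyme totals derive from protein content by the mass rule", {
  toy <- generateToyPcgem(ToySpec(seed = 5))
  cond <- ConditionConstraints(mu = 0.4, proteinContent = 0.2)
  mw <- mean(toy$model@enzymeMw)
  expect_equal(conditionEnzymeTotal(cond, toy$model),
               0.2 * 0.5 * 0.5 / mw)
  cond2 <- ConditionConstraints(mu = 0.4, enzymeTotal = 0.01)
  expect_equal(conditionEnzymeTotal(cond2), 0.01)
  expect_error(conditionEnzymeTotal(ConditionConstraints(mu = 1)),
               "neither")
})
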