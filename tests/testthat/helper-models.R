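# Hand-built fixture models (constructed in code; no stored data).

# Linear chain: upt -> A1 -> ... -> biomass, one enzyme per internal step.
chainModel <- function(kcats = c(100, 200, 400), uptakeUb = 10,
                       biomassUb = 1000) {
  n <- length(kcats)
  mets <- paste0("A", seq_len(n + 1) - 1L)
  rxns <- c("upt", paste0("r", seq_len(n)), "bio")
  S <- matrix(0, n + 1, n + 2, dimnames = list(mets, rxns))
  S["A0", "upt"] <- 1
  for (i in seq_len(n)) {
    S[i, i + 1L] <- -1
    S[i + 1L, i + 1L] <- 1
  }
  S[n + 1L, "bio"] <- -1
  EnzymeConstrainedModel(
    metabolites = mets, reactions = rxns, S = S,
    lb = rep(0, n + 2), ub = c(uptakeUb, rep(1000, n), biomassUb),
    biomassRxn = "bio",
    enzymes = paste0("E", seq_len(n)),
    kcat = data.frame(enzyme = paste0("E", seq_len(n)),
                      reaction = paste0("r", seq_len(n)),
                      kcat = kcats))
}

# Two parallel single-reaction routes A -> B with different kcats.
branchModel <- function(kcats = c(100, 400), uptakeUb = 10) {
  mets <- c("A", "B")
  rxns <- c("upt", "rA", "rB", "bio")
  S <- matrix(0, 2, 4, dimnames = list(mets, rxns))
  S["A", "upt"] <- 1
  S["A", c("rA", "rB")] <- -1
  S["B", c("rA", "rB")] <- 1
  S["B", "bio"] <- -1
  EnzymeConstrainedModel(
    metabolites = mets, reactions = rxns, S = S,
    lb = rep(0, 4), ub = c(uptakeUb, 1000, 1000, 1000),
    biomassRxn = "bio", enzymes = c("EA", "EB"),
    kcat = data.frame(enzyme = c("EA", "EB"),
                      reaction = c("rA", "rB"), kcat = kcats))
}

# fix biomass flux to an interval
withGrowth <- function(model, lo, hi = lo) {
  j <- match(model@biomassRxn, model@reactions)
  model@lb[j] <- lo; model@ub[j] <- hi
  model
}

# a varied fixture suite of condition-constrained toy models (<= 10
# reactions each) with a reference allocation for the distance variants
# (memoized: several test files share it)
fixtureSuite <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- .buildFixtureSuite()
    cache
  }
})

.buildFixtureSuite <- function() {
  fixtures <- list()
  add <- function(model, mu, label) {
    wm <- makeIrreversible(withGrowth(model, 0.95 * mu, 1.05 * mu))
    u <- .usageAt(wm, mu)
    fixtures[[label]] <<- list(
      model = wm, mu = mu,
      eref = EnzymeAllocation(u$usage[u$usage > 0], total = sum(u$usage),
                              label = label),
      vref = u$flux, estot = 1.15 * sum(u$usage))
  }
  add(chainModel(c(100, 200, 400)), 1, "chain3")
  add(chainModel(c(50, 5000)), 2, "chain2")
  add(chainModel(c(3600, 360, 36, 3600)), 0.5, "chain4")
  add(branchModel(c(100, 400)), 1, "branch")
  add(branchModel(c(2000, 150), uptakeUb = 3), 1.5, "branch2")
  for (s in 1:5) {
    toy <- generateToyPcgem(ToySpec(nLinear = 2L + (s %% 3), nBranches = 2L,
                                    reversibleFraction = 0.3 * (s %% 2),
                                    muTrue = 0.4, seed = 100L + s))
    m <- applyCondition(
      toy$model,
      ConditionConstraints(mu = toy$truth$mu,
                           enzymeTotal = toy$model@poolTotal))$model
    wm <- makeIrreversible(m)
    tr <- toy$truth$allocation@values
    fixtures[[paste0("toy", s)]] <- list(
      model = wm, mu = toy$truth$mu,
      eref = EnzymeAllocation(tr[tr > 1e-12], total = sum(tr),
                              label = paste0("toy", s)),
      vref = toy$truth$fluxIrrev, estot = toy$model@poolTotal)
  }
  fixtures
}

# max-growth flux and usage at a fixed growth rate (for reference builds)
.usageAt <- function(wm, mu) {
  m2 <- withGrowth(wm, mu)
  p <- parrot:::.assembleBase(m2)
  obj <- rep(0, p$n); obj[p$ie] <- 1
  sol <- parrot:::.solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub)
  stopifnot(sol$status == "optimal")
  v <- sol$x[p$iv]
  list(flux = stats::setNames(v, m2@reactions),
       usage = parrot:::.usageFromFlux(m2, v))
}
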