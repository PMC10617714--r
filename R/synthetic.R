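## Seeded generator of toy protein-constrained models with planted
## allocations, and simulation of reference/alternative condition pairs
## with lognormal measurement noise.

#' Specification of a toy protein-constrained model
#'
#' The generated network is a substrate uptake feeding a linear chain of
#' `nLinear` metabolic steps, each catalysed by `nBranches` parallel
#' isozyme reactions with independently sampled turnover numbers, ending
#' in a biomass pseudo-reaction.  Parallel isozymes at every step give the
#' network genuine allocation freedom: the minimal-enzyme ground truth
#' routes each step's flux through the kcat-best isozyme, while
#' flux-parsimony is indifferent between them.
#'
#' @slot nLinear chain length (number of enzymatic steps).
#' @slot nBranches parallel isozyme routes per step.
#' @slot reversibleFraction fraction of step reactions marked reversible.
#' @slot kcatRange kcat sampling range (h\eqn{^{-1}}), log-uniform.
#' @slot muTrue planted growth rate (h\eqn{^{-1}}).
#' @slot noiseSigma lognormal measurement noise sd (log10 units).
#' @slot capFraction intrinsic expression-capacity bound per isozyme,
#'   as a fraction of the planted flux a single isozyme can carry
#'   (default 0.7); values >= 1 disable the caps.  With caps below 1 the
#'   minimal-enzyme ground truth must co-express isozymes, emulating the
#'   distributed isozyme usage of measured proteomes.
#' @slot seed integer seed; generation is deterministic given the seed.
#' @export
setClass("ToySpec",
  representation(nLinear = "integer", nBranches = "integer",
                 reversibleFraction = "numeric", kcatRange = "numeric",
                 muTrue = "numeric", noiseSigma = "numeric",
                 capFraction = "numeric", seed = "integer"))

setValidity("ToySpec", function(object) {
  msg <- character()
  if (object@nLinear < 1L) msg <- c(msg, "nLinear must be >= 1")
  if (object@nBranches < 1L) msg <- c(msg, "nBranches must be >= 1")
  if (length(object@kcatRange) != 2L || any(object@kcatRange <= 0) ||
      diff(object@kcatRange) < 0)
    msg <- c(msg, "kcatRange must be two positive increasing values")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@muTrue <= 0) msg <- c(msg, "muTrue must be > 0")
  if (object@reversibleFraction < 0 || object@reversibleFraction > 1)
    msg <- c(msg, "reversibleFraction must be in [0, 1]")
  if (object@capFraction <= 0)
    msg <- c(msg, "capFraction must be positive")
  if (object@capFraction < 1 &&
      object@nBranches * object@capFraction < 1.05)
    msg <- c(msg, "nBranches * capFraction must exceed 1.05 so the planted growth is feasible under the capacity caps")
  if (length(msg)) msg else TRUE
})

#' @rdname ToySpec-class
#' @param nLinear,nBranches,reversibleFraction,kcatRange,muTrue,noiseSigma,capFraction,seed
#'   see the class slots.
#' @export
ToySpec <- function(nLinear = 6L, nBranches = 2L, reversibleFraction = 0,
                    kcatRange = c(1e2, 1e5), muTrue = 0.4,
                    noiseSigma = 0.2,
                    capFraction = if (nBranches >= 2L) 0.7 else Inf,
                    seed = 1L) {
  new("ToySpec", nLinear = as.integer(nLinear),
      nBranches = as.integer(nBranches),
      reversibleFraction = reversibleFraction,
      kcatRange = as.numeric(kcatRange), muTrue = muTrue,
      noiseSigma = noiseSigma, capFraction = capFraction,
      seed = as.integer(seed))
}

setMethod("show", "ToySpec", function(object) {
  cat(sprintf("ToySpec: %d steps x %d isozymes, kcat %g-%g /h, mu %g /h, sigma %g, seed %d\n",
              object@nLinear, object@nBranches, object@kcatRange[1L],
              object@kcatRange[2L], object@muTrue, object@noiseSigma,
              object@seed))
  invisible(NULL)
})

## evaluate expr under a local RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a toy protein-constrained model with a planted allocation
#'
#' Builds the network described in [ToySpec-class], samples kcats
#' (log-uniform) and molecular weights, and computes the 1-norm-minimal
#' enzyme allocation supporting `muTrue` as the ground truth.  Generation
#' is deterministic given the spec's seed.  The model's pool total is set
#' to 1.2 times the planted total (a modest proteome reserve).
#'
#' @param spec a [ToySpec-class].
#' @param kcats optional named vector overriding sampled kcats (by
#'   reaction id).
#' @return a list with `model` (an [EnzymeConstrainedModel-class]),
#'   `truth` (list with `flux` net fluxes, `fluxIrrev`, `allocation` an
#'   [EnzymeAllocation-class], `mu`), and `spec`.
#' @export
generateToyPcgem <- function(spec, kcats = NULL) {
  stopifnot(is(spec, "ToySpec"))
  validObject(spec)
  nL <- spec@nLinear; nB <- spec@nBranches
  mets <- paste0("M", 0:nL)
  rid <- "upt"; lb <- 0; ub <- 2.5 * spec@muTrue
  tripI <- 1L; tripJ <- 1L; tripX <- 1          # upt: -> M0
  enz <- character(); kcEnz <- character(); kcRxn <- character()
  .withSeed(spec@seed, {
    for (s in seq_len(nL)) {
      for (b in seq_len(nB)) {
        r <- sprintf("R%d_%d", s, b); e <- sprintf("P%d_%d", s, b)
        rid <- c(rid, r); enz <- c(enz, e)
        kcEnz <- c(kcEnz, e); kcRxn <- c(kcRxn, r)
        revr <- stats::runif(1) < spec@reversibleFraction
        lb <- c(lb, if (revr) -1000 else 0); ub <- c(ub, 1000)
        j <- length(rid)
        tripI <- c(tripI, s, s + 1L); tripJ <- c(tripJ, j, j)
        tripX <- c(tripX, -1, 1)                # M_{s-1} -> M_s
      }
    }
    rid <- c(rid, "bio"); lb <- c(lb, 0); ub <- c(ub, 1000)
    tripI <- c(tripI, nL + 1L); tripJ <- c(tripJ, length(rid))
    tripX <- c(tripX, -1)                       # bio: M_nL ->
    kv <- exp(stats::runif(length(kcEnz), log(spec@kcatRange[1L]),
                           log(spec@kcatRange[2L])))
    mw <- exp(stats::rnorm(length(enz), log(40), 0.25))
  })
  names(kv) <- kcRxn
  if (!is.null(kcats)) {
    hit <- intersect(names(kcats), names(kv))
    kv[hit] <- kcats[hit]
  }
  S <- Matrix::sparseMatrix(i = tripI, j = tripJ, x = tripX,
                            dims = c(length(mets), length(rid)),
                            dimnames = list(mets, rid))
  eub <- if (is.finite(spec@capFraction) && spec@capFraction < 1)
    spec@capFraction * spec@muTrue / unname(kv)   # abundance cap per isozyme
  else rep(Inf, length(enz))
  model <- EnzymeConstrainedModel(
    metabolites = mets, reactions = rid, S = S, lb = lb, ub = ub,
    biomassRxn = "bio", enzymes = enz,
    kcat = data.frame(enzyme = kcEnz, reaction = kcRxn,
                      kcat = unname(kv), stringsAsFactors = FALSE),
    enzymeMw = stats::setNames(mw, enz),
    enzymeUb = stats::setNames(eub, enz))
  ## planted ground truth: minimal total enzyme supporting muTrue exactly
  fixed <- model
  jb <- match("bio", fixed@reactions)
  fixed@lb[jb] <- spec@muTrue; fixed@ub[jb] <- spec@muTrue
  wm <- makeIrreversible(fixed)
  p <- .assembleBase(wm)
  obj <- rep(0, p$n); obj[p$ie] <- 1
  sol <- .solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub)
  if (sol$status != "optimal")
    stop(errorCondition(
      paste("toy spec yields no feasible growth at muTrue:", sol$status),
      class = c("parrot_generation", "error")))
  v <- sol$x[p$iv]
  u <- .usageFromFlux(wm, v)
  truth <- list(flux = .netFlux(wm, v),
                fluxIrrev = stats::setNames(v, wm@reactions),
                allocation = EnzymeAllocation(u, total = sum(u),
                                              label = "truth"),
                mu = spec@muTrue)
  model@poolTotal <- 1.2 * sum(u)
  list(model = model, truth = truth, spec = spec)
}

## 1-norm-minimal allocation of a condition-constrained model (no
## proteomics): used for the adversarial simulation mode.
.minEnzymeAllocation <- function(condModel, Etot) {
  wm <- if (.isIrreversible(condModel)) condModel
        else makeIrreversible(condModel)
  p <- .assembleBase(wm, Etot = Etot, poolSense = "le")
  obj <- rep(0, p$n); obj[p$ie] <- p$Escale
  sol <- .solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub)
  if (sol$status != "optimal")
    stop(errorCondition(paste("adversarial re-optimization", sol$status),
                        class = c("parrot_infeasible", "error")))
  stats::setNames(sol$x[p$ie] * p$Escale, wm@enzymes)
}

#' Simulate a reference/alternative condition pair
#'
#' Perturbs the generated model, recomputes the alternative-condition
#' ground truth, and produces noisy synthetic proteomics for both
#' conditions.  Reference proteomics are the planted allocation times
#' lognormal noise \eqn{10^{\sigma z}} with per-enzyme standard normal
#' draws \eqn{z} (so different noise levels at the same seed share
#' draws).  The alternative truth is recomputed under the perturbed
#' constraints either by minimal adjustment from the (noise-free)
#' reference truth (`mode = "aligned"`, the hypothesis under which
#' distance minimization is exact) or by independent 1-norm
#' re-optimization (`mode = "adversarial"`).
#'
#' Perturbations: `"block_branch"` closes the truth-used isozyme of the
#' first chain step (requires `nBranches >= 2`); `"scale_uptake"`
#' multiplies the uptake bound by `factor` (default 0.5); `"shift_kcat"`
#' multiplies the kcats of all truth-used isozymes by `factor`
#' (default 0.25).  The alternative growth rate is the perturbed model's
#' maximal growth under the reference enzyme budget, capped at `muTrue`.
#'
#' @param toy the list returned by [generateToyPcgem()].
#' @param perturbation `"block_branch"`, `"scale_uptake"` or
#'   `"shift_kcat"`.
#' @param noiseSigma lognormal noise sd in log10 units (defaults to the
#'   spec's).
#' @param seed noise seed (defaults to the spec's seed).
#' @param mode `"aligned"` or `"adversarial"` (see Details).
#' @param factor perturbation strength (see Details).
#' @param growthFlex growth-rate flexibility of the simulated condition.
#' @return a list with `model` (the perturbed
#'   [EnzymeConstrainedModel-class]), `cond`
#'   (a [ConditionConstraints-class]), `refProteomics` and
#'   `altProteomics` (data.frames), `altTruth`
#'   (an [EnzymeAllocation-class]), and `mode`/`perturbation` echoes.
#' @export
simulateCondition <- function(toy,
                              perturbation = c("block_branch",
                                               "scale_uptake",
                                               "shift_kcat"),
                              noiseSigma = NULL, seed = NULL,
                              mode = c("aligned", "adversarial"),
                              factor = NULL, growthFlex = 0.05) {
  perturbation <- match.arg(perturbation)
  mode <- match.arg(mode)
  model <- toy$model; truth <- toy$truth; spec <- toy$spec
  if (is.null(noiseSigma)) noiseSigma <- spec@noiseSigma
  if (is.null(seed)) seed <- spec@seed
  floor <- 1e-12
  EtotRef <- sum(truth$allocation@values)
  ## the simulated cell's protein budget includes the proteome reserve
  EtotAlt <- if (is.finite(model@poolTotal)) model@poolTotal
             else 1.2 * EtotRef
  refSup <- truth$allocation@values[truth$allocation@values > floor]
  refAlloc <- EnzymeAllocation(refSup, total = sum(refSup),
                               label = "reference_truth")
  usedRxn <- intersect(names(truth$fluxIrrev)[truth$fluxIrrev > 1e-9],
                       model@reactions)
  usedEnzRxn <- usedRxn[Matrix::colSums(
    model@kcat[, usedRxn, drop = FALSE] != 0) > 0]
  pm <- model
  if (perturbation == "block_branch") {
    rxStep1 <- grep("^R1_", model@reactions, value = TRUE)
    if (length(rxStep1) < 2L)
      stop(errorCondition(
        "block_branch requires nBranches >= 2 (no alternative route)",
        class = c("parrot_generation", "error")))
    ## close the dominant truth-carrying isozyme of the first step
    fl <- vapply(rxStep1, function(r)
      sum(truth$fluxIrrev[startsWith(names(truth$fluxIrrev), r)]), 0)
    block <- rxStep1[which.max(fl)]
    j <- match(block, pm@reactions)
    pm@ub[j] <- 0; pm@lb[j] <- pmin(pm@lb[j], 0)
  } else if (perturbation == "scale_uptake") {
    if (is.null(factor)) factor <- 0.38
    j <- match("upt", pm@reactions)
    pm@ub[j] <- pm@ub[j] * factor
  } else {
    if (is.null(factor)) factor <- 0.25
    js <- match(intersect(usedEnzRxn, pm@reactions), pm@reactions)
    pm@kcat[, js] <- pm@kcat[, js] * factor
    pm@kcat <- Matrix::drop0(pm@kcat)
  }
  mg <- .maxGrowth(pm, Etot = EtotAlt)
  if (mg$status != "optimal" || mg$mu < 1e-9)
    stop(errorCondition("perturbation makes growth infeasible",
                        class = c("parrot_generation", "error")))
  muAlt <- min(truth$mu, mg$mu)
  mwMean <- mean(model@enzymeMw, na.rm = TRUE)
  cond <- ConditionConstraints(
    mu = muAlt,
    uptakeBounds = c(upt = pm@ub[match("upt", pm@reactions)]),
    proteinContent = EtotAlt * mwMean,
    enzymeTotal = EtotAlt, growthFlex = growthFlex,
    label = paste0(perturbation, "_s", seed))
  condModel <- applyCondition(pm, cond)$model
  if (mode == "aligned") {
    res <- solveParrot(condModel, "LP1", reference = refAlloc,
                       estot = EtotAlt)
    if (res@status != "optimal")
      stop(errorCondition("aligned alternative truth infeasible",
                          class = c("parrot_generation", "error")))
    altValues <- res@allocation@values
  } else {
    altValues <- .minEnzymeAllocation(condModel, EtotAlt)
  }
  altTruth <- EnzymeAllocation(altValues[altValues > floor],
                               total = EtotAlt, label = "alt_truth")
  nRef <- length(refSup); nAlt <- length(altTruth@values)
  noise <- .withSeed(seed, {
    list(ref = stats::rnorm(nRef), alt = stats::rnorm(nAlt))
  })
  refProt <- proteomicsTable(names(refSup),
                             refSup * 10^(noiseSigma * noise$ref),
                             condition = "reference")
  altProt <- proteomicsTable(names(altTruth@values),
                             altTruth@values * 10^(noiseSigma * noise$alt),
                             condition = cond@label)
  list(model = pm, cond = cond, refProteomics = refProt,
       altProteomics = altProt, altTruth = altTruth,
       mode = mode, perturbation = perturbation,
       noiseSigma = noiseSigma, seed = seed)
}

#' Run the full prediction benchmark on one simulated condition pair
#'
#' Executes the complete workflow on a toy model and a simulated
#' condition pair: condition-constrains the reference model, flexibilizes
#' the reference proteomics into \eqn{E_{ref}}, builds the baseline from
#' the alternative proteomics, runs the requested prediction methods on
#' the (batch) alternative-condition model, and scores each prediction
#' against the baseline by log10 Pearson correlation and RMdSE.
#'
#' @param toy list from [generateToyPcgem()].
#' @param sim list from [simulateCondition()].
#' @param methods subset of `c("LP1","QP1","LP2","QP2","PFBA","ESKCAT",
#'   "NULL")`.
#' @param lambda flux-distance weight used for LP2/QP2.
#' @param norm baseline norm (1 or 2).
#' @param floor usage floor for pairing.
#' @return a list with `scores` (data.frame: `method`, `pearson`,
#'   `rmdse`, `nPairs`), `baseline`, `eRef`, `vRef`, and `predictions`
#'   (named list of [EnzymeAllocation-class]).
#' @export
benchmarkCondition <- function(toy, sim,
                               methods = c("LP1", "PFBA", "ESKCAT",
                                           "NULL"),
                               lambda = 0.1, norm = 1, floor = 1e-12) {
  model <- toy$model; truth <- toy$truth
  EtotRef <- sum(truth$allocation@values)
  refCond <- ConditionConstraints(
    mu = truth$mu,
    uptakeBounds = stats::setNames(
      model@ub[match(names(sim$cond@uptakeBounds), model@reactions)],
      names(sim$cond@uptakeBounds)),
    enzymeTotal = EtotRef, growthFlex = sim$cond@growthFlex,
    label = "reference")
  refModel <- applyCondition(model, refCond)$model
  fx <- flexibilize(refModel, sim$refProteomics, muTarget = truth$mu,
                    growthFlex = refCond@growthFlex)
  altModel <- applyCondition(sim$model, sim$cond)$model
  baseline <- computeBaseline(altModel, sim$altProteomics, sim$cond,
                              norm = norm, floor = floor)
  estot <- conditionEnzymeTotal(sim$cond, altModel)
  predict1 <- function(method) {
    switch(method,
      LP1 = , QP1 = predictedAllocation(
        solveParrot(altModel, method, reference = fx$eRef,
                    estot = estot)),
      LP2 = , QP2 = predictedAllocation(
        solveParrot(altModel, method, reference = fx$eRef,
                    estot = estot, vref = fx$vRef, lambda = lambda)),
      PFBA = predictedAllocation(solvePfba(altModel, estot = estot)),
      ESKCAT = predictedAllocation(
        solvePfbaEsKcat(altModel, estot = estot)),
      "NULL" = nullAllocation(altModel),
      stop("unknown method: ", method))
  }
  predictions <- lapply(stats::setNames(methods, methods), predict1)
  scores <- do.call(rbind, lapply(methods, function(m) {
    sc <- tryCatch({
      pv <- pairAllocations(predictions[[m]], baseline, floor = floor)
      data.frame(method = m, pearson = pairedPearson(pv),
                 rmdse = pairedRmdse(pv), nPairs = pv@nPairs,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(method = m, pearson = NA_real_, rmdse = NA_real_,
                 nPairs = 0L, stringsAsFactors = FALSE))
    sc
  }))
  list(scores = scores, baseline = baseline, eRef = fx$eRef,
       vRef = fx$vRef, predictions = predictions)
}
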