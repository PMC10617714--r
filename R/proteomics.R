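## Proteomics integration: flexibilization of measured enzyme bounds and
## construction of the experimental baseline allocation.

#' Integrate and flexibilize reference proteomics
#'
#' Imposes measured abundances as per-enzyme upper bounds and iteratively
#' releases the bounds that most limit growth until the model can reach the
#' target growth rate.  A measured enzyme's bound is the minimum of its
#' measurement and any pre-existing capacity bound of the model.  In each
#' iteration the maximum-growth LP (under the enzyme pool `pool`) is
#' solved; among the measured bounds that are binding at the optimum, the
#' one whose relaxation yields the largest growth gain (finite-difference
#' sensitivity; ties broken lexicographically by enzyme id) is released to
#' the pool-limited regime (its pre-measurement bound) and recorded.
#' Enzymes without a measured value draw freely from the pool.
#'
#' The returned reference allocation keeps the original measured values for
#' enzymes untouched by flexibilization and uses the usage at the final
#' optimum for released enzymes.
#'
#' @param model an [EnzymeConstrainedModel-class], typically already
#'   condition-constrained for the reference condition.
#' @param prot proteomics table (see [proteomicsTable()]) or a named
#'   abundance vector (mmol/gDW).
#' @param muTarget target growth rate (h\eqn{^{-1}}).
#' @param growthFlex fractional tolerance: flexibilization stops once the
#'   maximal growth reaches `muTarget * (1 - growthFlex)`.
#' @param pool total enzyme pool bound applied during the maximum-growth
#'   solves (mmol/gDW); defaults to the model's pool total (`NA` drops
#'   it).
#' @param fdStep relative step of the finite-difference sensitivity.
#' @param slack tiny relative headroom added to the measured bounds so a
#'   measurement equal to the minimal supporting abundance does not
#'   create a knife-edge feasible set.
#' @return a list with elements `model` (bounds integrated and relaxed),
#'   `eRef` (the reference [EnzymeAllocation-class]), `report`
#'   (a [FlexibilizationReport-class]), `vRef` (named flux vector of the
#'   final maximum-growth optimum on the irreversible model, for use as a
#'   reference flux distribution), and `muAchieved`.
#' @export
flexibilize <- function(model, prot, muTarget, growthFlex = 0.05,
                        pool = poolTotal(model), fdStep = 1e-3,
                        slack = 1e-6) {
  meas <- if (is.data.frame(prot)) .proteomicsVector(prot) else prot
  ids <- intersect(names(meas), model@enzymes)
  if (!length(ids))
    stop("no measured protein maps to a model enzyme")
  meas <- meas[ids]
  intrinsic <- enzymeBounds(model)          # pre-existing capacity bounds
  eb <- intrinsic
  ## the tiny relative slack keeps the integrated model numerically
  ## feasible when measurements coincide exactly with the minimal
  ## supporting allocation (knife-edge feasible set)
  eb[ids] <- pmin(meas * (1 + slack), intrinsic[ids])
  enzymeBounds(model) <- eb
  target <- muTarget * (1 - growthFlex)
  ## reachable at all? (all measured bounds released to intrinsic/pool)
  free <- model
  enzymeBounds(free) <- intrinsic
  mgFree <- .maxGrowth(free, Etot = pool)
  if (mgFree$status != "optimal" || mgFree$mu < target - 1e-9)
    stop(errorCondition(
      sprintf("target growth %.4g unreachable even with all measured enzyme bounds released (max %.4g); growth is limited by non-measurement constraints",
              muTarget, if (mgFree$status == "optimal") mgFree$mu
              else NA_real_),
      class = c("parrot_infeasible", "error")))
  bounded <- sort(ids)
  released <- character()
  steps <- data.frame(enzyme = character(), original = numeric(),
                      relaxed = numeric(), iteration = integer(),
                      stringsAsFactors = FALSE)
  it <- 0L
  repeat {
    mg <- .maxGrowth(model, Etot = pool)
    if (mg$status == "optimal" && mg$mu >= target - 1e-9) break
    it <- it + 1L
    ## measured bounds binding at the optimum (or infeasible: all bounds)
    eb <- enzymeBounds(model)
    binding <- if (mg$status == "optimal") {
      E <- mg$x[mg$prob$ie] * mg$prob$Escale
      names(E) <- mg$model@enzymes
      bounded[E[bounded] >= eb[bounded] * (1 - 1e-6) - 1e-12]
    } else bounded
    if (!length(binding)) binding <- bounded
    gain <- vapply(binding, function(id) {
      probe <- model
      pb <- enzymeBounds(probe)
      pb[id] <- min(pb[id] * (1 + fdStep) + 1e-9, intrinsic[id])
      enzymeBounds(probe) <- pb
      mg2 <- .maxGrowth(probe, Etot = pool)
      if (mg2$status != "optimal") return(-Inf)
      mg2$mu - (if (mg$status == "optimal") mg$mu else 0)
    }, 0)
    pick <- binding[order(-gain, binding)][1L]
    eb[pick] <- intrinsic[pick]
    enzymeBounds(model) <- eb
    bounded <- setdiff(bounded, pick)
    released <- c(released, pick)
    steps <- rbind(steps, data.frame(
      enzyme = pick, original = unname(meas[pick]),
      relaxed = NA_real_, iteration = it, stringsAsFactors = FALSE))
    if (it > length(ids)) break   # safety; cannot release more than ids
  }
  mg <- .maxGrowth(model, Etot = pool)
  usage <- .usageFromFlux(mg$model, mg$x[mg$prob$iv])
  eRef <- meas
  if (length(released)) {
    eRef[released] <- pmax(usage[released], meas[released])
    steps$relaxed <- pmax(usage[steps$enzyme], steps$original)
  }
  list(model = model,
       eRef = EnzymeAllocation(eRef, total = sum(eRef),
                               label = "reference"),
       report = new("FlexibilizationReport", steps = steps,
                    muAchieved = mg$mu),
       vRef = stats::setNames(mg$x[mg$prob$iv], mg$model@reactions),
       muAchieved = mg$mu)
}

#' Construct the experimental baseline allocation
#'
#' Re-projects measured alternative-condition proteomics through the model:
#' the measurements are integrated as per-enzyme upper bounds (flexibilized
#' against the condition's growth rate first, see [flexibilize()]), and the
#' norm-minimal total allocation consistent with the condition's
#' constraints is computed —
#' \eqn{\min \|E\|_1} (`norm = 1`) or \eqn{\min \|E\|_2^2} (`norm = 2`)
#' subject to steady state, bounds, kcat coupling, the growth interval and
#' the enzyme pool.  The result is the comparison baseline: the enzyme
#' levels that actually carry flux, to which predictions can be fairly
#' compared.
#'
#' @param model a condition-constrained [EnzymeConstrainedModel-class]
#'   (see [applyCondition()]).
#' @param protAlt proteomics of the alternative condition (table or named
#'   vector, mmol/gDW).
#' @param cond the alternative condition's [ConditionConstraints-class].
#' @param norm 1 (Manhattan, default) or 2 (squared Euclidean).
#' @param floor usage floor defining membership of the returned allocation
#'   (mmol/gDW).
#' @param backend solver backend override.
#' @return an [EnzymeAllocation-class] restricted to enzymes with usage
#'   above `floor`; its declared total is the condition's Etot.
#' @export
computeBaseline <- function(model, protAlt, cond, norm = 1,
                            floor = 1e-12, backend = NULL) {
  stopifnot(norm %in% c(1, 2))
  Etot <- conditionEnzymeTotal(cond, model)
  fx <- flexibilize(model, protAlt, muTarget = cond@mu,
                    growthFlex = cond@growthFlex, pool = Etot)
  model <- fx$model
  wm <- if (.isIrreversible(model)) model else makeIrreversible(model)
  p <- .assembleBase(wm, Etot = Etot, poolSense = "le")
  obj <- rep(0, p$n); Q <- NULL
  if (norm == 1) {
    obj[p$ie] <- p$Escale
  } else {
    Q <- rep(0, p$n)
    Q[p$ie] <- 2 * p$Escale^2
  }
  sol <- .solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub, Q = Q,
                   backend = backend)
  if (sol$status != "optimal")
    stop(errorCondition(
      paste("baseline problem", sol$status,
            if (!is.null(sol$message)) paste0("(", sol$message, ")")),
      class = c("parrot_infeasible", "error")))
  E <- stats::setNames(sol$x[p$ie] * p$Escale, wm@enzymes)
  keep <- E > floor
  EnzymeAllocation(E[keep], total = Etot,
                   label = sprintf("baseline_norm%d", norm))
}
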