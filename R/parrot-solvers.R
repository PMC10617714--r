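## The PARROT optimization variants, the pFBA benchmarks and the kcat null
## model.  All problems share the constraint set: steady state (N v = 0),
## flux bounds with the biomass flux confined to the condition's growth
## interval, per-enzyme kcat capacity coupling, and the total-enzyme
## constraint.  The distance variants (LP1/QP1/LP2/QP2) fix the total as an
## equality (the allocation-fraction normalization requires it); the
## minimization benchmarks (pFBA, EsKcat, baselines) treat it as a pool
## upper bound, where an equality would make their objectives vacuous.

## enzyme usage implied by a flux vector: u_i = sum_j v_j / kcat_ij
.usageFromFlux <- function(model, v) {
  u <- numeric(length(model@enzymes))
  sp <- Matrix::summary(model@kcat)
  if (nrow(sp)) {
    add <- tapply(v[sp$j] / sp$x, sp$i, sum)
    u[as.integer(names(add))] <- as.numeric(add)
  }
  stats::setNames(u, model@enzymes)
}

.emptyResult <- function(variant, lambda, status, message = NULL) {
  new("SolveResult", flux = numeric(), fluxIrrev = numeric(),
      allocation = EnzymeAllocation(stats::setNames(numeric(), character()),
                                    total = 0, label = variant),
      objective = NA_real_, status = status, variant = variant,
      lambda = lambda, components = list(message = message))
}

.mkResult <- function(wm, x, p, variant, lambda, objective, components,
                      estot, allocation = NULL) {
  v <- x[p$iv]
  E <- x[p$ie] * p$Escale
  if (is.null(allocation))
    allocation <- EnzymeAllocation(
      stats::setNames(E, wm@enzymes),
      total = max(estot, sum(E)), label = variant)
  components$biomass <- wm@biomassRxn
  new("SolveResult",
      flux = .netFlux(wm, v),
      fluxIrrev = stats::setNames(v, wm@reactions),
      allocation = allocation, objective = objective,
      status = "optimal", variant = variant, lambda = lambda,
      components = components)
}

#' Predict an alternative condition's enzyme allocation
#'
#' Solves one of the four minimal-adjustment allocation problems.  Writing
#' \eqn{e = E_s / E_{s,tot}} and \eqn{a = E_{ref} / E_{ref,tot}} for the
#' allocation fractions on the reference support, the variants minimize
#' \describe{
#'   \item{LP1}{\eqn{\|a - e\|_1} (Manhattan distance of allocations),}
#'   \item{QP1}{\eqn{\|a - e\|_2^2} (squared Euclidean distance),}
#'   \item{LP2}{\eqn{\|a - e\|_1 + \lambda \|v_{ref} - v\|_1},}
#'   \item{QP2}{\eqn{\|a - e\|_2^2 + \lambda \|v_{ref} - v\|_2^2},}
#' }
#' subject to steady state, flux bounds (the biomass flux is expected to be
#' bounded to the condition's growth interval already, see
#' [applyCondition()]), kcat capacity coupling, and
#' \eqn{\sum E_s = E_{s,tot}}.  The Euclidean variants are convex quadratic
#' programs in the usual minimization-of-adjustment (MOMA) sense, i.e. the
#' squared norm is minimized; reported objective values follow the same
#' convention.
#'
#' By default the distance is summed over the enzymes present in the
#' reference allocation: model enzymes without a measured reference value
#' are free, pool-limited variables excluded from the distance
#' (`distanceSupport = "reference"`).  `distanceSupport = "all"` includes
#' them with reference 0.
#'
#' @param model a condition-constrained [EnzymeConstrainedModel-class]
#'   (biomass flux bounds set to the growth interval).
#' @param variant `"LP1"`, `"QP1"`, `"LP2"` or `"QP2"`.
#' @param reference the reference allocation \eqn{E_{ref}}
#'   ([EnzymeAllocation-class]).
#' @param estot total enzyme \eqn{E_{s,tot}} of the alternative condition
#'   (mmol/gDW); a fixed parameter, typically derived from the condition's
#'   measured protein content.
#' @param refTotal \eqn{E_{ref,tot}}; defaults to the reference
#'   allocation's declared total.
#' @param vref named reference flux vector (required when `lambda > 0`);
#'   names are matched against the reactions of the irreversible working
#'   model, missing entries are treated as 0.
#' @param lambda flux-distance weight \eqn{\lambda \in [0,1]} (LP2/QP2).
#' @param distanceSupport `"reference"` or `"all"` (see Details).
#' @param backend solver backend override (see package internals).
#' @return a [SolveResult-class]; its `components` slot carries the
#'   Manhattan and Euclidean enzyme- and flux-distance terms of the
#'   optimum.
#' @examples
#' toy <- generateToyPcgem(ToySpec(seed = 1))
#' cond <- ConditionConstraints(mu = toy$truth$mu, growthFlex = 0.05,
#'                              enzymeTotal = sum(toy$truth$allocation@values))
#' m <- applyCondition(toy$model, cond)$model
#' res <- solveParrot(m, "LP1", reference = toy$truth$allocation,
#'                    estot = cond@enzymeTotal)
#' res
#' @export
solveParrot <- function(model, variant = c("LP1", "QP1", "LP2", "QP2"),
                        reference, estot,
                        refTotal = allocationTotal(reference),
                        vref = NULL, lambda = 0,
                        distanceSupport = c("reference", "all"),
                        backend = NULL) {
  variant <- match.arg(variant)
  distanceSupport <- match.arg(distanceSupport)
  stopifnot(is(reference, "EnzymeAllocation"),
            is.finite(estot), estot > 0,
            is.finite(refTotal), refTotal > 0,
            lambda >= 0, lambda <= 1)
  twoTerm <- variant %in% c("LP2", "QP2")
  if (!twoTerm) lambda <- 0
  if (lambda > 0 && is.null(vref))
    stop("vref is required when lambda > 0")
  quadratic <- variant %in% c("QP1", "QP2")
  wm <- if (.isIrreversible(model)) model else makeIrreversible(model)
  p <- .assembleBase(wm, Etot = estot, poolSense = "eq")
  nr <- length(wm@reactions); ne <- length(wm@enzymes)
  sup <- if (distanceSupport == "reference")
    match(intersect(names(reference@values), wm@enzymes), wm@enzymes)
  else seq_len(ne)
  if (!length(sup))
    stop("no reference enzyme maps to a model enzyme")
  a <- stats::setNames(rep(0, length(sup)), wm@enzymes[sup])
  hit <- intersect(names(reference@values), names(a))
  a[hit] <- reference@values[hit] / refTotal
  vr <- rep(0, nr)
  if (!is.null(vref)) {
    hitv <- intersect(names(vref), wm@reactions)
    vr[match(hitv, wm@reactions)] <- vref[hitv]
  }
  n0 <- p$n
  obj <- rep(0, n0); Q <- rep(0, n0)
  Aeq <- p$Aeq; beq <- p$beq; Ain <- p$Ain; bin <- p$bin
  lb <- p$lb; ub <- p$ub
  constant <- 0
  if (quadratic) {
    Q[p$ie[sup]] <- 2
    obj[p$ie[sup]] <- -2 * a
    constant <- sum(a^2)
    if (lambda > 0) {
      Q[p$iv] <- Q[p$iv] + 2 * lambda
      obj[p$iv] <- obj[p$iv] - 2 * lambda * vr
      constant <- constant + lambda * sum(vr^2)
    }
  } else {
    ## |a_i - e_i| via t_i >= +/- (e_i - a_i)
    k <- length(sup)
    T1 <- matrix(0, k, n0); T1[cbind(seq_len(k), p$ie[sup])] <- 1
    Taux <- -diag(k)
    Ain2 <- rbind(cbind(T1, Taux), cbind(-T1, Taux))
    bin2 <- c(a, -a)
    Ain <- rbind(cbind(Ain, matrix(0, nrow(Ain), k)), Ain2)
    bin <- c(bin, bin2)
    Aeq <- cbind(Aeq, matrix(0, nrow(Aeq), k))
    obj <- c(obj, rep(1, k)); Q <- c(Q, rep(0, k))
    lb <- c(lb, rep(0, k)); ub <- c(ub, rep(Inf, k))
    if (lambda > 0) {
      ## lambda * |vref_j - v_j| via s_j
      n1 <- length(obj)
      S1 <- matrix(0, nr, n1); S1[cbind(seq_len(nr), p$iv)] <- 1
      Saux <- -diag(nr)
      Ain <- rbind(cbind(Ain, matrix(0, nrow(Ain), nr)),
                   cbind(S1, Saux), cbind(-S1, Saux))
      bin <- c(bin, vr, -vr)
      Aeq <- cbind(Aeq, matrix(0, nrow(Aeq), nr))
      obj <- c(obj, rep(lambda, nr)); Q <- c(Q, rep(0, nr))
      lb <- c(lb, rep(0, nr)); ub <- c(ub, rep(Inf, nr))
    }
  }
  sol <- .solveQLP(obj, Aeq, beq, Ain, bin, lb, ub,
                   Q = if (quadratic) Q else NULL, backend = backend)
  if (sol$status != "optimal")
    return(.emptyResult(variant, lambda, sol$status, sol$message))
  x <- sol$x
  e <- x[p$ie]
  v <- x[p$iv]
  dE <- a - e[sup]; dV <- vr - v
  comp <- list(enzDist1 = sum(abs(dE)), enzDist2 = sum(dE^2),
               fluxDist1 = sum(abs(dV)), fluxDist2 = sum(dV^2),
               support = wm@enzymes[sup],
               growthInterval = c(lb[p$biomassCol], ub[p$biomassCol]),
               estot = estot, refTotal = refTotal)
  objective <- switch(variant,
    LP1 = comp$enzDist1,
    QP1 = comp$enzDist2,
    LP2 = comp$enzDist1 + lambda * comp$fluxDist1,
    QP2 = comp$enzDist2 + lambda * comp$fluxDist2)
  .mkResult(wm, x[seq_len(p$n)], p, variant,
            if (twoTerm) lambda else NA_real_, objective, comp, estot)
}

#' Parsimonious FBA benchmark
#'
#' Minimizes the total flux \eqn{\sum_j v_j} of the irreversible model at
#' the condition's growth interval, subject to the same stoichiometric,
#' bound, kcat-capacity and enzyme-pool constraints as the allocation
#' variants (the total-enzyme constraint acts as a pool upper bound here).
#' The reported allocation is the minimal enzyme level supporting the
#' optimal flux, \eqn{E_i = \sum_j v_j / kcat_{ij}}.
#'
#' @inheritParams solveParrot
#' @param estot enzyme pool bound (mmol/gDW); `NA` drops the pool
#'   constraint.
#' @return a [SolveResult-class] with `variant = "PFBA"`.
#' @export
solvePfba <- function(model, estot = poolTotal(model), backend = NULL) {
  wm <- if (.isIrreversible(model)) model else makeIrreversible(model)
  p <- .assembleBase(wm, Etot = estot, poolSense = "le")
  obj <- rep(0, p$n); obj[p$iv] <- 1
  sol <- .solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub,
                   backend = backend)
  if (sol$status != "optimal")
    return(.emptyResult("PFBA", NA_real_, sol$status, sol$message))
  v <- sol$x[p$iv]
  u <- .usageFromFlux(wm, v)
  alloc <- EnzymeAllocation(u, total = max(if (is.finite(estot)) estot
                                           else 0, sum(u)), label = "PFBA")
  .mkResult(wm, sol$x, p, "PFBA", NA_real_, sum(v),
            list(totalFlux = sum(v)),
            if (is.finite(estot)) estot else sum(u), allocation = alloc)
}

#' Enzyme-weighted parsimonious benchmark
#'
#' Minimizes \eqn{\sum_{i,j} E_i \, kcat_{ij}} over catalysed
#' (enzyme, reaction) pairs under the same constraints as [solvePfba()].
#'
#' @inheritParams solvePfba
#' @return a [SolveResult-class] with `variant = "ESKCAT"`.
#' @export
solvePfbaEsKcat <- function(model, estot = poolTotal(model),
                            backend = NULL) {
  wm <- if (.isIrreversible(model)) model else makeIrreversible(model)
  p <- .assembleBase(wm, Etot = estot, poolSense = "le")
  w <- Matrix::rowSums(wm@kcat)          # sum_j kcat_ij per enzyme
  obj <- rep(0, p$n); obj[p$ie] <- as.numeric(w) * p$Escale
  sol <- .solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub,
                   backend = backend)
  if (sol$status != "optimal")
    return(.emptyResult("ESKCAT", NA_real_, sol$status, sol$message))
  E <- sol$x[p$ie] * p$Escale
  .mkResult(wm, sol$x, p, "ESKCAT", NA_real_, sum(obj * sol$x),
            list(), if (is.finite(estot)) estot else sum(E))
}

#' Plain growth maximization (FBA)
#'
#' Maximizes the biomass flux under the model's current bounds, kcat
#' coupling, and (optionally) the enzyme pool.  Used for feasibility
#' probing and as a reference solve.
#'
#' @inheritParams solvePfba
#' @return a [SolveResult-class] with `variant = "FBA"`; the objective is
#'   the maximal growth rate.
#' @export
solveFBA <- function(model, estot = poolTotal(model)) {
  mg <- .maxGrowth(model, Etot = estot)
  if (mg$status != "optimal")
    return(.emptyResult("FBA", NA_real_, mg$status))
  wm <- mg$model; p <- mg$prob
  u <- .usageFromFlux(wm, mg$x[p$iv])
  alloc <- EnzymeAllocation(u, total = max(if (is.finite(estot)) estot
                                           else 0, sum(u)), label = "FBA")
  .mkResult(wm, mg$x, p, "FBA", NA_real_, mg$mu,
            list(), if (is.finite(estot)) estot else sum(u),
            allocation = alloc)
}

#' kcat null model
#'
#' Negative-control allocation that uses turnover numbers directly as
#' pseudo-abundances: each enzyme's value is an aggregate of its kcats
#' (h\eqn{^{-1}}), by default the maximum over its reactions.  This is not
#' a feasible allocation of any model; it only serves to measure how much
#' of a correlation is attributable to kcat values alone.
#'
#' @param model an [EnzymeConstrainedModel-class] with a non-empty kcat
#'   map.
#' @param rule aggregation over an enzyme's reactions: `"max"` (default),
#'   `"mean"`, or `"first"` (first catalysed reaction in model order).
#' @return an [EnzymeAllocation-class] over the enzymes with kcat entries.
#' @export
nullAllocation <- function(model, rule = c("max", "mean", "first")) {
  rule <- match.arg(rule)
  sp <- Matrix::summary(model@kcat)
  if (!nrow(sp)) stop("model has no kcat entries")
  f <- switch(rule, max = max, mean = mean,
              first = function(x) x[1L])
  sp <- sp[order(sp$i, sp$j), ]
  val <- tapply(sp$x, sp$i, f)
  values <- stats::setNames(as.numeric(val),
                            model@enzymes[as.integer(names(val))])
  EnzymeAllocation(values, total = sum(values), label = "NULL")
}

#' Residuals of a solve against the model constraints
#'
#' Convenience check of the feasibility contract of an optimal
#' [SolveResult-class]: maximum absolute stoichiometric residual
#' \eqn{|Nv|}, maximum kcat-capacity violation, the total-enzyme residual,
#' and the biomass flux.
#'
#' @param model the (condition-constrained) model the problem was solved
#'   on.
#' @param result an optimal [SolveResult-class].
#' @return a list with `stoich`, `coupling`, `poolResidual`, `growth`.
#' @export
solutionResiduals <- function(model, result) {
  wm <- if (.isIrreversible(model)) model else makeIrreversible(model)
  v <- result@fluxIrrev[wm@reactions]
  E <- rep(0, length(wm@enzymes))
  hit <- intersect(names(result@allocation@values), wm@enzymes)
  E[match(hit, wm@enzymes)] <- result@allocation@values[hit]
  u <- .usageFromFlux(wm, v)
  list(stoich = max(abs(as.numeric(wm@S %*% v)), 0),
       coupling = max(u - E, 0),
       poolResidual = sum(E) - result@allocation@total,
       growth = unname(v[match(wm@biomassRxn, wm@reactions)]))
}
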