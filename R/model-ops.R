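#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound is split into a forward copy
#' (original id, bounds `[0, ub]`) and a backward copy (id suffixed
#' `"_REV"`, bounds `[0, -lb]`, negated stoichiometry).  kcat entries of the
#' original reaction are duplicated onto both directions.  The mapping back
#' to the original reactions is retained in the model's `revMap` slot and
#' used by the solvers to report net fluxes.
#'
#' Splitting does not change the feasible space of net fluxes: any split
#' flux yields a feasible net flux of the original model and vice versa.
#'
#' @param model an [EnzymeConstrainedModel-class].
#' @return an irreversible [EnzymeConstrainedModel-class].
#' @export
makeIrreversible <- function(model) {
  rev <- which(model@lb < 0)
  if (!length(rev)) {
    model@revMap <- data.frame(reaction = model@reactions,
                               original = model@reactions,
                               sign = 1, stringsAsFactors = FALSE)
    model@reversible <- rep(FALSE, length(model@reactions))
    return(model)
  }
  ids <- model@reactions
  origIdx <- integer(); sgn <- numeric()
  newid <- character(); lb <- numeric(); ub <- numeric()
  for (j in seq_along(ids)) {
    fwd <- model@ub[j] > 0 || model@lb[j] >= 0
    if (fwd) {
      origIdx <- c(origIdx, j); sgn <- c(sgn, 1)
      newid <- c(newid, ids[j])
      lb <- c(lb, max(model@lb[j], 0)); ub <- c(ub, max(model@ub[j], 0))
    }
    if (model@lb[j] < 0) {
      origIdx <- c(origIdx, j); sgn <- c(sgn, -1)
      newid <- c(newid, paste0(ids[j], "_REV"))
      lb <- c(lb, max(-model@ub[j], 0)); ub <- c(ub, -model@lb[j])
    }
  }
  S2 <- model@S[, origIdx, drop = FALSE] %*% Matrix::Diagonal(x = sgn)
  K2 <- model@kcat[, origIdx, drop = FALSE]
  orig <- ids[origIdx]
  out <- EnzymeConstrainedModel(
    metabolites = model@metabolites, reactions = newid,
    S = S2, lb = lb, ub = ub, reversible = rep(FALSE, length(newid)),
    biomassRxn = model@biomassRxn, enzymes = model@enzymes,
    kcat = K2, poolTotal = model@poolTotal,
    enzymeMw = if (length(model@enzymeMw) == length(model@enzymes))
      stats::setNames(model@enzymeMw, model@enzymes) else numeric(),
    enzymeUb = stats::setNames(model@enzymeUb, model@enzymes))
  out@revMap <- data.frame(reaction = newid, original = orig, sign = sgn,
                           stringsAsFactors = FALSE)
  out
}

.isIrreversible <- function(model) all(model@lb >= 0)

## Net fluxes on original reaction ids from an irreversible flux vector.
.netFlux <- function(model, v) {
  if (is.null(model@revMap))
    return(stats::setNames(v, model@reactions))
  rm <- model@revMap
  net <- tapply(v[match(rm$reaction, model@reactions)] * rm$sign,
                rm$original, sum)
  out <- as.numeric(net)
  names(out) <- names(net)
  ## keep original ordering where possible
  ord <- unique(rm$original)
  out[ord]
}

## ------------------------------------------------------------------------
## Constraint assembly.  Variables are x = [v (reactions), e (enzymes)]
## with e the allocation fraction E / Escale, Escale = Etot when finite.
## Constraints: S v = 0; enzyme capacity sum_j v_j / kcat_ij <= Escale e_i;
## optional pool row sum(E) {=,<=} Etot; flux and abundance bounds.
.assembleBase <- function(model, Etot = NA_real_,
                          poolSense = c("le", "eq"),
                          muInterval = NULL,
                          subsetPool = NULL) {
  poolSense <- match.arg(poolSense)
  if (!.isIrreversible(model))
    stop("internal: model must be irreversible at assembly")
  nr <- length(model@reactions); ne <- length(model@enzymes)
  n <- nr + ne
  iv <- seq_len(nr); ie <- nr + seq_len(ne)
  Escale <- if (is.finite(Etot) && Etot > 0) Etot else 1
  Aeq <- cbind(as.matrix(model@S), matrix(0, length(model@metabolites), ne))
  beq <- rep(0, length(model@metabolites))
  Ain <- matrix(0, 0, n); bin <- numeric()
  ## enzyme capacity rows
  K <- model@kcat
  hasK <- which(Matrix::rowSums(K != 0) > 0)
  if (length(hasK)) {
    Cv <- matrix(0, length(hasK), nr)
    for (r in seq_along(hasK)) {
      i <- hasK[r]
      js <- which(K[i, ] != 0)
      Cv[r, js] <- 1 / K[i, js]
    }
    Ce <- matrix(0, length(hasK), ne)
    Ce[cbind(seq_along(hasK), hasK)] <- -Escale
    Ain <- rbind(Ain, cbind(Cv, Ce)); bin <- c(bin, rep(0, length(hasK)))
  }
  ## pool constraint
  if (is.finite(Etot)) {
    row <- c(rep(0, nr), rep(Escale, ne))
    if (poolSense == "eq") {
      Aeq <- rbind(Aeq, row); beq <- c(beq, Etot)
    } else {
      Ain <- rbind(Ain, row); bin <- c(bin, Etot)
    }
  }
  ## optional extra pool over a subset of enzymes (residual pool for
  ## enzymes without a measured bound)
  if (!is.null(subsetPool) && length(subsetPool$ids) &&
      is.finite(subsetPool$total)) {
    row <- rep(0, n)
    row[nr + match(subsetPool$ids, model@enzymes)] <- Escale
    Ain <- rbind(Ain, row); bin <- c(bin, subsetPool$total)
  }
  lb <- c(model@lb, rep(0, ne))
  ub <- c(model@ub, model@enzymeUb / Escale)
  if (!is.null(muInterval)) {
    jb <- match(model@biomassRxn, model@reactions)
    lb[jb] <- max(lb[jb], muInterval[1L])
    ub[jb] <- min(ub[jb], muInterval[2L])
  }
  list(n = n, iv = iv, ie = ie, Aeq = Aeq, beq = beq,
       Ain = Ain, bin = bin, lb = lb, ub = ub, Escale = Escale,
       biomassCol = match(model@biomassRxn, model@reactions))
}

## Maximum-growth LP under current bounds (and optional pools).
.maxGrowth <- function(model, Etot = NA_real_, subsetPool = NULL) {
  wm <- if (.isIrreversible(model)) model else makeIrreversible(model)
  p <- .assembleBase(wm, Etot = Etot, poolSense = "le",
                     subsetPool = subsetPool)
  obj <- rep(0, p$n); obj[p$biomassCol] <- -1
  sol <- .solveQLP(obj, p$Aeq, p$beq, p$Ain, p$bin, p$lb, p$ub)
  if (sol$status != "optimal")
    return(list(status = sol$status, mu = NA_real_, x = NULL,
                model = wm, prob = p))
  list(status = "optimal", mu = sol$x[p$biomassCol], x = sol$x,
       model = wm, prob = p)
}

#' Derive the condition's total enzyme pool
#'
#' Returns the condition's `enzymeTotal` when set; otherwise derives a molar
#' pool from the measured protein content with the standard mass-fraction
#' rule Etot = Ptot * f * sigma / MW, where `f` is the enzyme mass fraction
#' of total protein, `sigma` the average saturation, and MW the mean enzyme
#' molecular weight of the model (g/mmol).
#'
#' @param cond a [ConditionConstraints-class].
#' @param model optional [EnzymeConstrainedModel-class] supplying molecular
#'   weights.
#' @param massFraction,saturation rule parameters (defaults 0.5 and 0.5).
#' @return Etot in mmol/gDW.
#' @export
conditionEnzymeTotal <- function(cond, model = NULL, massFraction = 0.5,
                                 saturation = 0.5) {
  if (is.finite(cond@enzymeTotal)) return(cond@enzymeTotal)
  if (!is.finite(cond@proteinContent))
    stop("condition has neither enzymeTotal nor proteinContent")
  if (is.null(model) || !length(model@enzymeMw) ||
      all(is.na(model@enzymeMw)))
    stop("deriving Etot from protein content requires enzyme molecular weights")
  mw <- mean(model@enzymeMw, na.rm = TRUE)
  cond@proteinContent * massFraction * saturation / mw
}

#' Constrain a model with a condition's physiology
#'
#' Applies the measured uptake bounds, constrains the biomass flux to the
#' interval \eqn{[\mu(1-f), \mu(1+f)]}, and sets the enzyme pool from the
#' condition.  If the constrained model cannot reach the lower end of the
#' growth interval, all condition uptake bounds are relaxed multiplicatively
#' by `boundFlexStep` per round until it can (or `maxFlexRounds` is
#' reached, in which case an error of class `parrot_infeasible` carrying the
#' relaxation log is signalled).  Bounds are only ever relaxed, never
#' tightened, across rounds.
#'
#' @param model an [EnzymeConstrainedModel-class]; uptake reaction ids in
#'   `cond` must exist in the model.
#' @param cond a [ConditionConstraints-class].
#' @return a list with elements `model` (the constrained model),
#'   `relaxation` (data.frame log, one row per relaxation round: `round`,
#'   `factor`, `maxGrowth`), and `maxGrowth` (growth reached).
#' @export
applyCondition <- function(model, cond) {
  upt <- cond@uptakeBounds
  bad <- setdiff(names(upt), model@reactions)
  if (length(bad))
    stop("uptake reactions not in model: ", paste(bad, collapse = ", "))
  j <- match(names(upt), model@reactions)
  model@ub[j] <- unname(upt)
  model@lb[j] <- pmin(model@lb[j], model@ub[j])
  muLo <- cond@mu * (1 - cond@growthFlex)
  muHi <- cond@mu * (1 + cond@growthFlex)
  jb <- match(model@biomassRxn, model@reactions)
  model@lb[jb] <- muLo
  model@ub[jb] <- muHi
  ## the pool slot is the physical bound on total enzyme (reserve
  ## included); only fill it from the condition when the model has none
  Etot <- tryCatch(conditionEnzymeTotal(cond, model),
                   error = function(e) NA_real_)
  if (!is.finite(model@poolTotal) && is.finite(Etot))
    model@poolTotal <- Etot
  log <- data.frame(round = integer(), factor = numeric(),
                    maxGrowth = numeric())
  ## feasibility check on a probe with a free biomass upper bound
  probe <- model; probe@lb[jb] <- 0; probe@ub[jb] <- muHi
  mg <- .maxGrowth(probe, Etot = model@poolTotal)
  reached <- function(mg) mg$status == "optimal" && mg$mu >= muLo - 1e-9
  round <- 0L
  while (!reached(mg) && round < cond@maxFlexRounds && length(upt)) {
    round <- round + 1L
    fac <- (1 + cond@boundFlexStep)^round
    probe@ub[j] <- unname(upt) * fac
    mg <- .maxGrowth(probe, Etot = model@poolTotal)
    log <- rbind(log, data.frame(round = round, factor = fac,
                                 maxGrowth = if (mg$status == "optimal")
                                   mg$mu else NA_real_))
  }
  if (!reached(mg))
    stop(errorCondition(
      sprintf("condition '%s' infeasible after %d relaxation rounds (max growth %.4g < %.4g)",
              cond@label, round,
              if (mg$status == "optimal") mg$mu else NA_real_, muLo),
      class = c("parrot_infeasible", "error"),
      call = sys.call(-1), relaxation = log))
  if (round > 0L) {
    model@ub[j] <- unname(upt) * (1 + cond@boundFlexStep)^round
    model@lb[j] <- pmin(model@lb[j], model@ub[j])
  }
  list(model = model, relaxation = log, maxGrowth = mg$mu)
}
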