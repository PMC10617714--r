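#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Protein-constrained metabolic model
#'
#' In-memory representation of a protein-constrained genome-scale metabolic
#' model (pcGEM) in the explicit form: a stoichiometric matrix over true
#' metabolites, per-reaction flux bounds, and a separate sparse map of
#' turnover numbers kcat (h\eqn{^{-1}}) linking enzymes to the reactions they
#' catalyse.  Enzyme abundances are model variables, not pseudo-metabolites;
#' the GECKO pseudo-metabolite encoding is translated into this form on
#' import (see [importGeckoSBML()]).
#'
#' The capacity constraint follows the GECKO convention: for every enzyme
#' \eqn{i}, \eqn{\sum_j v_j / kcat_{ij} \le E_i} over the reactions \eqn{j}
#' it catalyses, so a reaction requiring several enzymes (a complex) draws on
#' each subunit at its own kcat, and the single-enzyme case reduces to
#' \eqn{v_j \le kcat_{ij} E_i}.
#'
#' @slot metabolites character vector of metabolite identifiers (rows of `S`).
#' @slot reactions character vector of reaction identifiers (columns of `S`).
#' @slot S sparse stoichiometric matrix (metabolites x reactions).
#' @slot lb,ub numeric flux bounds per reaction (mmol/gDW/h).
#' @slot reversible logical per reaction.
#' @slot biomassRxn identifier of the biomass pseudo-reaction.
#' @slot enzymes character vector of enzyme (protein) identifiers.
#' @slot kcat sparse matrix (enzymes x reactions) of turnover numbers in
#'   h\eqn{^{-1}}; a zero entry means the enzyme does not catalyse the
#'   reaction.
#' @slot poolTotal optional total enzyme pool (mmol/gDW); `NA` if unset.
#' @slot enzymeMw optional named molecular weights (g/mmol).
#' @slot enzymeUb per-enzyme abundance upper bounds (mmol/gDW), `Inf` when
#'   unconstrained; set by proteomics integration.
#' @slot revMap `NULL`, or a data.frame with columns `reaction`, `original`,
#'   `sign` mapping reactions of an irreversibilised model back to the
#'   original reactions (see [makeIrreversible()]).
#'
#' @seealso [EnzymeConstrainedModel()] for the constructor,
#'   [readToyModel()], [importGeckoSBML()].
#' @export
setClass("EnzymeConstrainedModel",
  representation(
    metabolites = "character",
    reactions   = "character",
    S           = "dgCMatrix",
    lb          = "numeric",
    ub          = "numeric",
    reversible  = "logical",
    biomassRxn  = "character",
    enzymes     = "character",
    kcat        = "dgCMatrix",
    poolTotal   = "numeric",
    enzymeMw    = "numeric",
    enzymeUb    = "numeric",
    revMap      = "data.frameOrNULL"
  )
)

setValidity("EnzymeConstrainedModel", function(object) {
  msg <- character()
  nm <- length(object@metabolites); nr <- length(object@reactions)
  ne <- length(object@enzymes)
  if (!all(dim(object@S) == c(nm, nr)))
    msg <- c(msg, sprintf("S must be %d x %d, got %d x %d",
                          nm, nr, nrow(object@S), ncol(object@S)))
  if (anyDuplicated(object@reactions))
    msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(object@metabolites))
    msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(object@enzymes))
    msg <- c(msg, "duplicated enzyme ids")
  if (length(object@lb) != nr || length(object@ub) != nr ||
      length(object@reversible) != nr)
    msg <- c(msg, "lb, ub, reversible must have one entry per reaction")
  else {
    if (any(object@lb > object@ub + 1e-12))
      msg <- c(msg, "lb > ub for some reaction")
    if (any(!object@reversible & object@lb < -1e-12))
      msg <- c(msg, "irreversible reaction with negative lower bound")
  }
  if (length(object@biomassRxn) != 1L ||
      !(object@biomassRxn %in% object@reactions))
    msg <- c(msg, "biomassRxn must name one existing reaction")
  if (!all(dim(object@kcat) == c(ne, nr)))
    msg <- c(msg, "kcat must be enzymes x reactions")
  else if (length(object@kcat@x) && any(object@kcat@x <= 0))
    msg <- c(msg, "all stored kcat values must be > 0")
  if (length(object@enzymeUb) != ne)
    msg <- c(msg, "enzymeUb must have one entry per enzyme")
  else if (any(object@enzymeUb < 0, na.rm = TRUE))
    msg <- c(msg, "enzymeUb must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Physiological constraints of a growth condition
#'
#' Measured physiology of one growth condition: specific growth rate,
#' nutrient uptake bounds, total protein content and the flexibility policy
#' used when the measurements over-constrain the model.  The growth rate is
#' imposed as the symmetric interval
#' \eqn{[\mu(1-f), \mu(1+f)]} with flexibility \eqn{f} (`growthFlex`,
#' default 0.05); when even that is infeasible, uptake bounds are relaxed
#' multiplicatively in `boundFlexStep` increments (default 1\%) until the
#' growth rate is achieved.
#'
#' @slot mu specific growth rate (h\eqn{^{-1}}).
#' @slot uptakeBounds named numeric, maximum uptake flux per uptake reaction
#'   (mmol/gDW/h).
#' @slot proteinContent total protein (g protein/gDW); may be `NA`.
#' @slot enzymeTotal total enzyme pool Etot for this condition (mmol/gDW);
#'   if `NA` it is derived from `proteinContent` (see
#'   [conditionEnzymeTotal()]).
#' @slot growthFlex fractional tolerance on `mu` (default 0.05).
#' @slot boundFlexStep fractional increment for relaxing uptake bounds
#'   (default 0.01).
#' @slot maxFlexRounds cap on relaxation iterations (default 200).
#' @slot label condition label.
#' @export
setClass("ConditionConstraints",
  representation(
    mu             = "numeric",
    uptakeBounds   = "numeric",
    proteinContent = "numeric",
    enzymeTotal    = "numeric",
    growthFlex     = "numeric",
    boundFlexStep  = "numeric",
    maxFlexRounds  = "integer",
    label          = "character"
  )
)

setValidity("ConditionConstraints", function(object) {
  msg <- character()
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    msg <- c(msg, "mu must be a single positive number")
  if (object@growthFlex < 0 || object@growthFlex >= 1)
    msg <- c(msg, "growthFlex must be in [0, 1)")
  if (object@boundFlexStep <= 0 || object@boundFlexStep > 1)
    msg <- c(msg, "boundFlexStep must be in (0, 1]")
  if (length(object@uptakeBounds) &&
      (is.null(names(object@uptakeBounds)) ||
       any(!nzchar(names(object@uptakeBounds)))))
    msg <- c(msg, "uptakeBounds must be named by reaction id")
  if (any(object@uptakeBounds < 0, na.rm = TRUE))
    msg <- c(msg, "uptakeBounds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-enzyme abundance allocation
#'
#' A named non-negative vector of enzyme abundances (mmol/gDW) together with
#' the declared total enzyme pool it belongs to.  Used for reference
#' allocations built from proteomics, for baselines, and for predictions.
#'
#' @slot values named numeric, abundance per enzyme (mmol/gDW).
#' @slot total declared total Etot (mmol/gDW); the sum of `values` never
#'   exceeds it (beyond 1e-6 relative slack).
#' @slot label provenance tag.
#' @export
setClass("EnzymeAllocation",
  representation(values = "numeric", total = "numeric", label = "character")
)

setValidity("EnzymeAllocation", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
    msg <- c(msg, "values must be named by enzyme id")
  if (anyDuplicated(names(v)))
    msg <- c(msg, "duplicated enzyme ids")
  if (any(v < -1e-9))
    msg <- c(msg, "abundances must be non-negative")
  if (length(object@total) != 1L || !is.finite(object@total))
    msg <- c(msg, "total must be a single finite number")
  else if (sum(pmax(v, 0)) > object@total * (1 + 1e-6) + 1e-12)
    msg <- c(msg, "sum of values exceeds declared total")
  if (length(msg)) msg else TRUE
})

#' Result of one allocation-prediction solve
#'
#' @slot flux named net flux vector on the original reaction ids
#'   (mmol/gDW/h).
#' @slot fluxIrrev named flux vector on the irreversible working model.
#' @slot allocation predicted [EnzymeAllocation].
#' @slot objective objective value at the optimum (see the solver help pages
#'   for the exact functional form per variant).
#' @slot status one of `"optimal"`, `"infeasible"`, `"numeric_failure"`.
#' @slot variant the problem solved (`"LP1"`, `"QP1"`, `"LP2"`, `"QP2"`,
#'   `"PFBA"`, `"ESKCAT"`, `"BASELINE1"`, `"BASELINE2"`, `"FBA"`).
#' @slot lambda the flux-distance weight used (`NA` when not applicable).
#' @slot components list of diagnostic components of the optimum, e.g.
#'   `enzDist` and `fluxDist` for the two-term variants, and the growth
#'   interval imposed.
#' @export
setClass("SolveResult",
  representation(
    flux       = "numeric",
    fluxIrrev  = "numeric",
    allocation = "EnzymeAllocation",
    objective  = "numeric",
    status     = "character",
    variant    = "character",
    lambda     = "numeric",
    components = "list"
  )
)

#' Audit trail of proteomics flexibilization
#'
#' Ordered record of the measured enzyme bounds released while raising the
#' model's maximum growth to the target rate, one enzyme per iteration.
#'
#' @slot steps data.frame with columns `enzyme`, `original`, `relaxed`,
#'   `iteration`; `relaxed >= original` for every row.
#' @slot muAchieved maximum growth rate after the final release.
#' @export
setClass("FlexibilizationReport",
  representation(steps = "data.frame", muAchieved = "numeric")
)

setValidity("FlexibilizationReport", function(object) {
  st <- object@steps
  need <- c("enzyme", "original", "relaxed", "iteration")
  if (!all(need %in% names(st)))
    return("steps must have columns enzyme, original, relaxed, iteration")
  if (nrow(st) && any(st$relaxed < st$original - 1e-12))
    return("relaxed abundance below original for some enzyme")
  TRUE
})

#' Aligned log10 abundance vectors of two allocations
#'
#' @slot ids shared enzyme identifiers.
#' @slot x,y log10 abundances of the two allocations on the shared support.
#' @slot nPairs number of pairs.
#' @slot nDroppedZero enzymes present in both allocations but at or below
#'   the usage floor in at least one, hence excluded.
#' @export
setClass("PairedLogVectors",
  representation(ids = "character", x = "numeric", y = "numeric",
                 nPairs = "integer", nDroppedZero = "integer")
)

setValidity("PairedLogVectors", function(object) {
  if (length(object@x) != length(object@y) ||
      length(object@x) != length(object@ids))
    return("ids, x and y must have equal length")
  if (object@nPairs != length(object@x))
    return("nPairs inconsistent with vector length")
  TRUE
})
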