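## Constructors -----------------------------------------------------------

#' Construct a protein-constrained model
#'
#' Builds an [EnzymeConstrainedModel-class] from its components.  `kcat` may
#' be given either as an enzymes x reactions matrix (dense or sparse; zero =
#' not catalysed) or as a data.frame with columns `enzyme`, `reaction`,
#' `kcat` (h\eqn{^{-1}}).
#'
#' @param metabolites,reactions,enzymes identifier vectors.
#' @param S stoichiometric matrix (metabolites x reactions).
#' @param lb,ub flux bounds (mmol/gDW/h); recycled defaults 0 / 1000.
#' @param reversible logical per reaction; default `lb < 0`.
#' @param biomassRxn id of the biomass pseudo-reaction.
#' @param kcat turnover numbers, see Details.
#' @param poolTotal optional enzyme pool bound Etot (mmol/gDW).
#' @param enzymeMw optional named molecular weights (g/mmol).
#' @param enzymeUb optional named per-enzyme abundance upper bounds.
#' @return an [EnzymeConstrainedModel-class].
#' @examples
#' m <- EnzymeConstrainedModel(
#'   metabolites = "A",
#'   reactions = c("up", "r1", "bio"),
#'   S = matrix(c(1, -1, -1), 1, 3,
#'              dimnames = list("A", c("up", "r1", "bio"))),
#'   ub = c(10, 1000, 1000), biomassRxn = "bio",
#'   enzymes = "P1",
#'   kcat = data.frame(enzyme = "P1", reaction = "r1", kcat = 3600))
#' m
#' @export
EnzymeConstrainedModel <- function(metabolites, reactions, S,
                                   lb = NULL, ub = NULL, reversible = NULL,
                                   biomassRxn, enzymes = character(),
                                   kcat = NULL, poolTotal = NA_real_,
                                   enzymeMw = numeric(),
                                   enzymeUb = NULL) {
  nr <- length(reactions)
  if (is.null(lb)) lb <- rep(0, nr)
  if (is.null(ub)) ub <- rep(1000, nr)
  lb <- rep_len(as.numeric(lb), nr); ub <- rep_len(as.numeric(ub), nr)
  if (is.null(reversible)) reversible <- lb < 0
  S <- as(as(as(Matrix::Matrix(S, sparse = TRUE), "dMatrix"),
             "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites, reactions)
  kcat <- .asKcatMatrix(kcat, enzymes, reactions)
  if (is.null(enzymeUb)) enzymeUb <- rep(Inf, length(enzymes))
  else if (!is.null(names(enzymeUb))) {
    full <- rep(Inf, length(enzymes)); names(full) <- enzymes
    full[names(enzymeUb)] <- enzymeUb
    enzymeUb <- unname(full)
  }
  if (length(enzymeMw) && !is.null(names(enzymeMw))) {
    full <- rep(NA_real_, length(enzymes)); names(full) <- enzymes
    full[intersect(names(enzymeMw), enzymes)] <-
      enzymeMw[intersect(names(enzymeMw), enzymes)]
    enzymeMw <- full
  } else if (length(enzymeMw) != length(enzymes)) {
    enzymeMw <- stats::setNames(rep(NA_real_, length(enzymes)), enzymes)
  }
  new("EnzymeConstrainedModel",
      metabolites = as.character(metabolites),
      reactions = as.character(reactions), S = S,
      lb = lb, ub = ub, reversible = as.logical(reversible),
      biomassRxn = biomassRxn, enzymes = as.character(enzymes),
      kcat = kcat, poolTotal = as.numeric(poolTotal)[1L],
      enzymeMw = enzymeMw, enzymeUb = as.numeric(enzymeUb),
      revMap = NULL)
}

.asKcatMatrix <- function(kcat, enzymes, reactions) {
  ne <- length(enzymes); nr <- length(reactions)
  if (is.null(kcat)) {
    k <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(ne, nr))
  } else if (is.data.frame(kcat)) {
    i <- match(kcat$enzyme, enzymes); j <- match(kcat$reaction, reactions)
    if (anyNA(i) || anyNA(j))
      stop("kcat table references unknown enzyme or reaction ids")
    k <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(kcat$kcat),
                              dims = c(ne, nr))
  } else {
    k <- as(as(as(Matrix::Matrix(kcat, sparse = TRUE), "dMatrix"),
               "generalMatrix"), "CsparseMatrix")
    stopifnot(all(dim(k) == c(ne, nr)))
  }
  k <- as(as(Matrix::drop0(k), "generalMatrix"), "CsparseMatrix")
  dimnames(k) <- list(enzymes, reactions)
  k
}

#' Construct condition constraints
#'
#' @param mu measured specific growth rate (h\eqn{^{-1}}).
#' @param uptakeBounds named numeric of maximum uptake fluxes (mmol/gDW/h).
#' @param proteinContent total protein (g/gDW), optional.
#' @param enzymeTotal total enzyme pool Etot (mmol/gDW); if `NA`, derived
#'   from `proteinContent` on demand (see [conditionEnzymeTotal()]).
#' @param growthFlex fractional growth-rate tolerance (default 0.05).
#' @param boundFlexStep fractional uptake-bound relaxation step
#'   (default 0.01).
#' @param maxFlexRounds maximum relaxation rounds (default 200).
#' @param label condition label.
#' @return a [ConditionConstraints-class].
#' @export
ConditionConstraints <- function(mu, uptakeBounds = numeric(),
                                 proteinContent = NA_real_,
                                 enzymeTotal = NA_real_,
                                 growthFlex = 0.05, boundFlexStep = 0.01,
                                 maxFlexRounds = 200L, label = "condition") {
  new("ConditionConstraints", mu = as.numeric(mu),
      uptakeBounds = uptakeBounds,
      proteinContent = as.numeric(proteinContent)[1L],
      enzymeTotal = as.numeric(enzymeTotal)[1L],
      growthFlex = growthFlex, boundFlexStep = boundFlexStep,
      maxFlexRounds = as.integer(maxFlexRounds), label = label)
}

#' Construct an enzyme allocation
#'
#' @param values named numeric, abundance per enzyme (mmol/gDW).
#' @param total declared total Etot; defaults to `sum(values)`.
#' @param label provenance tag.
#' @return an [EnzymeAllocation-class].
#' @export
EnzymeAllocation <- function(values, total = sum(values),
                             label = "allocation") {
  new("EnzymeAllocation", values = values, total = as.numeric(total)[1L],
      label = label)
}

## Accessors ---------------------------------------------------------------

#' @rdname EnzymeConstrainedModel-class
#' @aliases metaboliteIds reactionIds enzymeIds stoichMatrix kcatMatrix
#'   biomassReaction fluxBounds poolTotal poolTotal<- enzymeBounds
#'   enzymeBounds<-
#' @export
setMethod("metaboliteIds", "EnzymeConstrainedModel",
          function(x) x@metabolites)

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("reactionIds", "EnzymeConstrainedModel", function(x) x@reactions)

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("enzymeIds", "EnzymeConstrainedModel", function(x) x@enzymes)

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("stoichMatrix", "EnzymeConstrainedModel", function(x) x@S)

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("kcatMatrix", "EnzymeConstrainedModel", function(x) x@kcat)

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("biomassReaction", "EnzymeConstrainedModel",
          function(x) x@biomassRxn)

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("fluxBounds", "EnzymeConstrainedModel", function(x) {
  cbind(lb = stats::setNames(x@lb, x@reactions), ub = x@ub)
})

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("poolTotal", "EnzymeConstrainedModel", function(x) x@poolTotal)

#' @rdname EnzymeConstrainedModel-class
#' @export
setReplaceMethod("poolTotal", "EnzymeConstrainedModel", function(x, value) {
  x@poolTotal <- as.numeric(value)[1L]
  validObject(x); x
})

#' @rdname EnzymeConstrainedModel-class
#' @export
setMethod("enzymeBounds", "EnzymeConstrainedModel",
          function(x) stats::setNames(x@enzymeUb, x@enzymes))

#' @rdname EnzymeConstrainedModel-class
#' @export
setReplaceMethod("enzymeBounds", "EnzymeConstrainedModel",
function(x, value) {
  if (is.null(names(value))) {
    stopifnot(length(value) == length(x@enzymes))
    x@enzymeUb <- as.numeric(value)
  } else {
    ub <- stats::setNames(x@enzymeUb, x@enzymes)
    bad <- setdiff(names(value), x@enzymes)
    if (length(bad))
      stop("unknown enzyme ids: ", paste(bad, collapse = ", "))
    ub[names(value)] <- value
    x@enzymeUb <- unname(ub)
  }
  validObject(x); x
})

#' @rdname EnzymeAllocation-class
#' @aliases allocationValues allocationTotal
#' @export
setMethod("allocationValues", "EnzymeAllocation", function(x) x@values)

#' @rdname EnzymeAllocation-class
#' @export
setMethod("allocationTotal", "EnzymeAllocation", function(x) x@total)

#' @rdname SolveResult-class
#' @aliases predictedAllocation fluxes objectiveValue solveStatus
#' @export
setMethod("predictedAllocation", "SolveResult", function(x) x@allocation)

#' @rdname SolveResult-class
#' @export
setMethod("fluxes", "SolveResult", function(x) x@flux)

#' @rdname SolveResult-class
#' @export
setMethod("objectiveValue", "SolveResult", function(x) x@objective)

#' @rdname SolveResult-class
#' @export
setMethod("solveStatus", "SolveResult", function(x) x@status)

## show methods ------------------------------------------------------------

setMethod("show", "EnzymeConstrainedModel", function(object) {
  cat("EnzymeConstrainedModel:",
      length(object@metabolites), "metabolites,",
      length(object@reactions), "reactions,",
      length(object@enzymes), "enzymes\n")
  cat("  biomass reaction:", object@biomassRxn, "\n")
  cat("  kcat entries:", length(object@kcat@x),
      if (is.finite(object@poolTotal))
        sprintf("| pool total: %.4g mmol/gDW", object@poolTotal)
      else "| pool total: unset", "\n")
  nrev <- sum(object@reversible)
  if (nrev) cat("  reversible reactions:", nrev, "\n")
  if (!is.null(object@revMap))
    cat("  irreversibilised from", length(unique(object@revMap$original)),
        "original reactions\n")
  invisible(NULL)
})

setMethod("show", "ConditionConstraints", function(object) {
  cat(sprintf("ConditionConstraints '%s': mu = %.4g /h (flex %.0f%%)\n",
              object@label, object@mu, 100 * object@growthFlex))
  if (length(object@uptakeBounds))
    cat("  uptake bounds:",
        paste(sprintf("%s <= %.4g", names(object@uptakeBounds),
                      object@uptakeBounds), collapse = ", "), "\n")
  cat(sprintf("  enzyme total: %s mmol/gDW | protein: %s g/gDW\n",
              format(object@enzymeTotal), format(object@proteinContent)))
  invisible(NULL)
})

setMethod("show", "EnzymeAllocation", function(object) {
  v <- object@values
  cat(sprintf("EnzymeAllocation '%s': %d enzymes, sum %.4g of total %.4g mmol/gDW\n",
              object@label, length(v), sum(v), object@total))
  if (length(v)) {
    head <- utils::head(sort(v, decreasing = TRUE), 5L)
    cat("  top:", paste(sprintf("%s=%.3g", names(head), head),
                        collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "SolveResult", function(object) {
  cat(sprintf("SolveResult [%s%s]: status %s, objective %.6g\n",
              object@variant,
              if (is.finite(object@lambda))
                sprintf(", lambda=%.2f", object@lambda) else "",
              object@status, object@objective))
  if (object@status == "optimal")
    cat(sprintf("  %d enzymes above floor, growth %.4g /h\n",
                sum(object@allocation@values > 1e-12),
                unname(object@flux[object@components$biomass %||%
                                     names(object@flux)[1L]])))
  invisible(NULL)
})

setMethod("show", "FlexibilizationReport", function(object) {
  cat(sprintf("FlexibilizationReport: %d enzymes released, mu achieved %.4g /h\n",
              nrow(object@steps), object@muAchieved))
  if (nrow(object@steps)) print(object@steps)
  invisible(NULL)
})

setMethod("show", "PairedLogVectors", function(object) {
  cat(sprintf("PairedLogVectors: %d pairs (%d dropped at usage floor)\n",
              object@nPairs, object@nDroppedZero))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
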