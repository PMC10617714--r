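## Comparison of predicted allocations against baselines: log10 pairing,
## Pearson correlation, root-median-square error, pairwise Wilcoxon
## rank-sum tests with Bonferroni correction, and lambda sweeps.

#' Pair two allocations on their shared support
#'
#' Aligns a predicted and a baseline allocation on the intersection of
#' enzymes whose abundance exceeds the usage floor in both, and returns
#' the log10-transformed vectors.  Enzymes present in both allocations but
#' at or below the floor in at least one are counted as dropped.
#'
#' @param pred,base [EnzymeAllocation-class] objects.
#' @param floor usage floor (mmol/gDW), must be > 0.
#' @return a [PairedLogVectors-class].
#' @export
pairAllocations <- function(pred, base, floor = 1e-12) {
  stopifnot(floor > 0)
  shared <- intersect(names(pred@values), names(base@values))
  ok <- pred@values[shared] > floor & base@values[shared] > floor
  ids <- shared[ok]
  if (length(ids) < 2L)
    stop(errorCondition(
      sprintf("insufficient overlap: %d enzymes above floor shared",
              length(ids)),
      class = c("parrot_overlap", "error")))
  new("PairedLogVectors", ids = ids,
      x = log10(unname(pred@values[ids])),
      y = log10(unname(base@values[ids])),
      nPairs = length(ids), nDroppedZero = sum(!ok))
}

#' Pearson correlation of paired log abundances
#'
#' @param pv a [PairedLogVectors-class].
#' @return Pearson r.
#' @export
pairedPearson <- function(pv) {
  if (pv@nPairs < 2L) stop("need at least 2 pairs")
  if (stats::sd(pv@x) == 0 || stats::sd(pv@y) == 0)
    stop(errorCondition("zero variance: correlation undefined",
                        class = c("parrot_degenerate", "error")))
  stats::cor(pv@x, pv@y)
}

#' Root-median-square error of paired log abundances
#'
#' \eqn{\sqrt{\mathrm{median}_i (x_i - y_i)^2}}; the median of an even
#' count is the midpoint mean.  Depends only on the per-pair differences.
#'
#' @param pv a [PairedLogVectors-class].
#' @return RMdSE in log10 units.
#' @export
pairedRmdse <- function(pv) {
  if (pv@nPairs < 1L) stop("need at least 1 pair")
  sqrt(stats::median((pv@x - pv@y)^2))
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Compares per-condition score lists (e.g. Pearson correlations of each
#' method across conditions) between all pairs of methods with the
#' two-sided Wilcoxon rank-sum (Mann-Whitney) test: exact when both groups
#' have fewer than 10 scores, normal approximation with continuity
#' correction otherwise.  Raw p-values are multiplied by the number of
#' method pairs and capped at 1.
#'
#' @param scores named list of numeric vectors, one per method, all of the
#'   same length (>= 3 conditions) and condition order.
#' @return a symmetric matrix of adjusted p-values with `NA` on the
#'   diagonal.
#' @export
compareMethods <- function(scores) {
  stopifnot(is.list(scores), length(scores) >= 2L,
            !is.null(names(scores)))
  ns <- lengths(scores)
  if (length(unique(ns)) != 1L)
    stop(errorCondition("methods have unequal numbers of conditions",
                        class = c("parrot_alignment", "error")))
  if (ns[1L] < 3L) stop("need scores for at least 3 conditions")
  m <- length(scores)
  pairs <- utils::combn(m, 2L)
  npairs <- ncol(pairs)
  P <- matrix(NA_real_, m, m, dimnames = list(names(scores),
                                              names(scores)))
  for (k in seq_len(npairs)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    a <- scores[[i]]; b <- scores[[j]]
    exact <- max(length(a), length(b)) < 10L
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
    P[i, j] <- P[j, i] <- min(1, p * npairs)
  }
  P
}

#' Sweep the flux-distance weight lambda
#'
#' Solves an LP2 or QP2 variant at each lambda of a grid, scores each
#' prediction against the baseline by the Pearson correlation of
#' log10 abundances, and returns the lambda with the highest correlation
#' (ties resolved toward the smallest lambda) together with the full
#' curve.  Infeasible grid points are flagged and excluded from the
#' argmax.
#'
#' @inheritParams solveParrot
#' @param baseline the baseline [EnzymeAllocation-class] to score against.
#' @param grid lambda values in `[0, 1]`.
#' @param floor usage floor for pairing.
#' @return a list with `optimal` (the argmax lambda), `curve` (data.frame
#'   `lambda`, `pearson`, `rmdse`, `nPairs`, `status`), and `results`
#'   (the per-lambda [SolveResult-class] objects).
#' @export
sweepLambda <- function(model, variant = c("LP2", "QP2"), reference,
                        estot, baseline, grid = seq(0, 1, by = 0.1),
                        vref = NULL,
                        refTotal = allocationTotal(reference),
                        floor = 1e-12, distanceSupport = "reference") {
  variant <- match.arg(variant)
  stopifnot(length(grid) >= 1L, all(grid >= 0 & grid <= 1))
  rows <- vector("list", length(grid))
  results <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    res <- solveParrot(model, variant, reference = reference,
                       estot = estot, refTotal = refTotal, vref = vref,
                       lambda = grid[k],
                       distanceSupport = distanceSupport)
    results[[k]] <- res
    if (res@status == "optimal") {
      sc <- tryCatch({
        pv <- pairAllocations(res@allocation, baseline, floor = floor)
        list(r = pairedPearson(pv), e = pairedRmdse(pv), n = pv@nPairs)
      }, error = function(e) list(r = NA_real_, e = NA_real_, n = 0L))
      rows[[k]] <- data.frame(lambda = grid[k], pearson = sc$r,
                              rmdse = sc$e, nPairs = sc$n,
                              status = res@status)
    } else {
      rows[[k]] <- data.frame(lambda = grid[k], pearson = NA_real_,
                              rmdse = NA_real_, nPairs = 0L,
                              status = res@status)
    }
  }
  curve <- do.call(rbind, rows)
  ok <- !is.na(curve$pearson)
  if (!any(ok))
    stop(errorCondition("no feasible lambda in the grid",
                        class = c("parrot_infeasible", "error")))
  best <- which(ok)[order(-curve$pearson[ok], curve$lambda[ok])][1L]
  list(optimal = curve$lambda[best], curve = curve, results = results)
}
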