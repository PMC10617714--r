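## Internal linear/quadratic programming layer.
##
## All allocation problems in this package reduce to
##   min  c'x + 0.5 * x' diag(Q) x
##   s.t. Aeq x = beq,  Ain x <= bin,  lb <= x <= ub
## with a diagonal (possibly zero) quadratic part, because every objective
## used here is separable.  Pure LPs are solved exactly with the two-phase
## simplex of boot::simplex; quadratic problems go through
## quadprog::solve.QP with a tiny ridge on zero-curvature variables so the
## Hessian is positive definite.  Problems are assembled in scaled enzyme
## variables (allocation fractions) upstream, which keeps both solvers
## well-conditioned.

.QLP_RIDGE <- 1e-9

.solveQLP <- function(obj, Aeq, beq, Ain, bin, lb, ub, Q = NULL,
                      backend = NULL) {
  n <- length(obj)
  Aeq <- .denseMat(Aeq, n); Ain <- .denseMat(Ain, n)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  if (is.null(backend)) backend <- if (is.null(Q)) "simplex" else "quadprog"
  res <- switch(backend,
                simplex  = .solveSimplex(obj, Aeq, beq, Ain, bin, lb, ub),
                quadprog = .solveQuadprog(obj, Q, Aeq, beq, Ain, bin,
                                          lb, ub),
                stop("unknown backend: ", backend))
  if (backend == "simplex" && res$status == "numeric_failure")
    res <- .solveQuadprog(obj, Q, Aeq, beq, Ain, bin, lb, ub)
  res
}

.denseMat <- function(A, n) {
  if (is.null(A)) return(matrix(0, 0, n))
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  A
}

## Normalize rows to unit max-abs coefficient (pure row scaling, preserves
## the feasible set); guards the simplex tableau against the wide range of
## 1/kcat coefficients.
.normRows <- function(A, b) {
  if (!nrow(A)) return(list(A = A, b = b))
  s <- apply(abs(A), 1L, max)
  s[s == 0] <- 1
  list(A = A / s, b = b / s)
}

.solveSimplex <- function(obj, Aeq, beq, Ain, bin, lb, ub) {
  n <- length(obj)
  if (any(!is.finite(lb)))
    stop("simplex backend requires finite lower bounds")
  ## eliminate variables fixed by lb == ub (keeps the tableau clean)
  fixed <- which(ub - lb <= 0)
  if (length(fixed)) {
    keep <- setdiff(seq_len(n), fixed)
    xf <- lb[fixed]
    if (!length(keep)) {
      feas <- (!nrow(Aeq) || max(abs(Aeq %*% xf - beq)) < 1e-9) &&
              (!nrow(Ain) || max(Ain %*% xf - bin) < 1e-9)
      return(if (feas)
        list(status = "optimal", x = lb, value = sum(obj * lb))
      else list(status = "infeasible", x = NULL, value = NA_real_))
    }
    sub <- .solveSimplex(obj[keep],
                         Aeq[, keep, drop = FALSE],
                         beq - (if (nrow(Aeq))
                           as.vector(Aeq[, fixed, drop = FALSE] %*% xf)
                           else 0),
                         Ain[, keep, drop = FALSE],
                         bin - (if (nrow(Ain))
                           as.vector(Ain[, fixed, drop = FALSE] %*% xf)
                           else 0),
                         lb[keep], ub[keep])
    if (sub$status != "optimal") return(sub)
    x <- numeric(n); x[fixed] <- xf; x[keep] <- sub$x
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }
  ## shift to y = x - lb >= 0
  if (nrow(Aeq)) beq <- beq - as.vector(Aeq %*% lb)
  if (nrow(Ain)) bin <- bin - as.vector(Ain %*% lb)
  ubf <- which(is.finite(ub))
  if (length(ubf)) {
    Ub <- matrix(0, length(ubf), n)
    Ub[cbind(seq_along(ubf), ubf)] <- 1
    Ain <- rbind(Ain, Ub)
    bin <- c(bin, ub[ubf] - lb[ubf])
  }
  ni <- .normRows(Ain, bin); Ain <- ni$A; bin <- ni$b
  ne <- .normRows(Aeq, beq); Aeq <- ne$A; beq <- ne$b
  ## boot::simplex needs non-negative right-hand sides
  neg <- bin < 0
  A1 <- Ain[!neg, , drop = FALSE]; b1 <- bin[!neg]
  A2 <- -Ain[neg, , drop = FALSE]; b2 <- -bin[neg]
  nege <- beq < 0
  if (any(nege)) {
    Aeq[nege, ] <- -Aeq[nege, , drop = FALSE]
    beq[nege] <- -beq[nege]
  }
  m <- nrow(A1) + nrow(A2) + nrow(Aeq)
  res <- tryCatch(
    boot::simplex(a = obj,
                  A1 = if (nrow(A1)) A1, b1 = if (nrow(A1)) b1,
                  A2 = if (nrow(A2)) A2, b2 = if (nrow(A2)) b2,
                  A3 = if (nrow(Aeq)) Aeq, b3 = if (nrow(Aeq)) beq,
                  maxi = FALSE, n.iter = 50L * (n + m)),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(status = "numeric_failure", x = NULL, value = NA_real_,
                message = conditionMessage(res)))
  status <- switch(as.character(res$solved),
                   "1" = "optimal", "-1" = "infeasible", "numeric_failure")
  if (status != "optimal")
    return(list(status = status, x = NULL, value = NA_real_))
  x <- as.numeric(res$soln)[seq_len(n)] + lb
  list(status = "optimal", x = x, value = sum(obj * x))
}

.solveQuadprog <- function(obj, Q, Aeq, beq, Ain, bin, lb, ub) {
  n <- length(obj)
  if (is.null(Q)) Q <- numeric(n)
  d <- pmax(Q, .QLP_RIDGE)
  lbf <- which(is.finite(lb)); ubf <- which(is.finite(ub))
  Ilb <- matrix(0, length(lbf), n); Ilb[cbind(seq_along(lbf), lbf)] <- 1
  Iub <- matrix(0, length(ubf), n); Iub[cbind(seq_along(ubf), ubf)] <- 1
  Amat <- t(rbind(Aeq, -Ain, Ilb, -Iub))
  bvec <- c(beq, -bin, lb[lbf], -ub[ubf])
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(d, n), dvec = -obj, Amat = Amat,
                       bvec = bvec, meq = nrow(Aeq)),
    error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    status <- if (grepl("inconsistent", msg)) "infeasible"
              else "numeric_failure"
    return(list(status = status, x = NULL, value = NA_real_,
                message = msg))
  }
  x <- res$solution
  list(status = "optimal", x = x,
       value = sum(obj * x) + 0.5 * sum(Q * x^2))
}
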