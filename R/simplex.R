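## Dense bounded-variable two-phase primal simplex.
##
## Solves   maximize c'x   subject to  A x = b,  lb <= x <= ub.
##
## Written for the small, fully boxed LPs this package assembles (at most a
## few hundred variables and ~60 equality rows).  Free directions are boxed
## at +/- .BIG_BOUND by the callers; a solution touching the box is reported
## so callers can flag effectively unbounded variables.  Determinism: fixed
## variable ordering, Dantzig pricing with a Bland anti-cycling fallback, no
## randomisation — repeated runs are bit-identical.

#' Solve a boxed equality-constrained linear programme
#'
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param cvec objective coefficients (length n).
#' @param lb,ub finite variable bounds.
#' @param maximize logical; minimises when FALSE.
#' @param tolCost reduced-cost optimality tolerance.
#' @param tolPivot smallest usable pivot magnitude.
#' @param tolFeas phase-1 feasibility tolerance.
#' @param maxIter iteration cap.
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "maxiter"), `x`, `objective` and `residual` (max |Ax - b|).
#' @keywords internal
lpSolveBounded <- function(A, b, cvec, lb, ub, maximize = TRUE,
                           tolCost = 1e-9, tolPivot = 1e-10,
                           tolFeas = 1e-7, maxIter = 50000L) {
    m <- nrow(A); n <- ncol(A)
    stopifnot(length(b) == m, length(cvec) == n,
              length(lb) == n, length(ub) == n,
              all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
    if (!maximize) cvec <- -cvec
    ## initial nonbasic placement: at a bound, or at zero for straddling vars
    x <- numeric(n + m)
    code <- integer(n + m)            # 1 at-lb, 2 at-ub, 3 free-at-zero
    for (j in seq_len(n)) {
        if (lb[j] > 0)      { x[j] <- lb[j]; code[j] <- 1L }
        else if (ub[j] < 0) { x[j] <- ub[j]; code[j] <- 2L }
        else if (lb[j] == 0) code[j] <- 1L
        else if (ub[j] == 0) code[j] <- 2L
        else                 code[j] <- 3L
    }
    r <- as.numeric(b - A %*% x[seq_len(n)])
    s <- ifelse(r >= 0, 1, -1)
    Aext <- cbind(A, diag(s, m), deparse.level = 0)
    lbx <- c(lb, numeric(m))
    ubx <- c(ub, rep(Inf, m))
    x[n + seq_len(m)] <- abs(r)
    basis <- n + seq_len(m)
    inBasis <- logical(n + m); inBasis[basis] <- TRUE
    Binv <- diag(1 / s, m)            # inverse of diag(s)
    canEnter <- c(rep(TRUE, n), rep(FALSE, m))
    iter <- 0L; sincePivot <- 0L
    refactor <- function() {
        B <- Aext[, basis, drop = FALSE]
        Bi <- tryCatch(solve(B), error = function(e) NULL)
        if (is.null(Bi)) Bi <- tryCatch(qr.solve(B), error = function(e) NULL)
        if (!is.null(Bi)) {
            Binv <<- Bi
            xoff <- x; xoff[basis] <- 0
            x[basis] <<- as.numeric(Binv %*% (b - Aext %*% xoff))
        }
    }
    runPhase <- function(cuse, phase) {
        degen <- 0L; bland <- FALSE
        repeat {
            iter <<- iter + 1L
            if (iter > maxIter) return("maxiter")
            y <- as.numeric(crossprod(Binv, cuse[basis]))
            d <- cuse - as.numeric(crossprod(Aext, y))
            elig <- !inBasis & canEnter &
                ((code == 1L & d > tolCost) |
                 (code == 2L & d < -tolCost) |
                 (code == 3L & abs(d) > tolCost))
            if (!any(elig)) return("optimal")
            cand <- which(elig)
            q <- if (bland) cand[1L] else cand[which.max(abs(d[cand]))]
            dirq <- if (code[q] == 2L) -1 else if (code[q] == 3L) sign(d[q]) else 1
            w <- as.numeric(Binv %*% Aext[, q])
            dw <- dirq * w
            ## distance the entering variable itself can travel
            ownStep <- if (code[q] == 3L) {
                if (dirq > 0) ubx[q] else -lbx[q]
            } else ubx[q] - lbx[q]
            bestStep <- ownStep; leave <- 0L; leaveBound <- 0L
            dec <- dw > tolPivot
            if (any(dec)) {
                steps <- (x[basis][dec] - lbx[basis][dec]) / dw[dec]
                k <- which.min(steps)
                if (steps[k] < bestStep) {
                    bestStep <- max(steps[k], 0)
                    leave <- which(dec)[k]; leaveBound <- 1L
                }
            }
            inc <- dw < -tolPivot
            if (any(inc)) {
                steps <- (ubx[basis][inc] - x[basis][inc]) / (-dw[inc])
                k <- which.min(steps)
                if (steps[k] < bestStep) {
                    bestStep <- max(steps[k], 0)
                    leave <- which(inc)[k]; leaveBound <- 2L
                }
            }
            if (!is.finite(bestStep)) return("unbounded")
            ## apply the step
            x[basis] <<- x[basis] - bestStep * dw
            x[q] <<- x[q] + dirq * bestStep
            if (leave == 0L) {
                ## bound flip: entering variable runs to its opposite bound
                if (dirq > 0) { x[q] <<- ubx[q]; code[q] <<- 2L }
                else          { x[q] <<- lbx[q]; code[q] <<- 1L }
            } else {
                p <- basis[leave]
                if (leaveBound == 1L) { x[p] <<- lbx[p]; code[p] <<- 1L }
                else                  { x[p] <<- ubx[p]; code[p] <<- 2L }
                inBasis[p] <<- FALSE
                basis[leave] <<- q
                inBasis[q] <<- TRUE
                piv <- w[leave]
                Binv[leave, ] <<- Binv[leave, ] / piv
                other <- setdiff(seq_len(m), leave)
                if (length(other))
                    Binv[other, ] <<- Binv[other, ] -
                        outer(w[other], Binv[leave, ])
                sincePivot <<- sincePivot + 1L
                if (sincePivot %% 60L == 0L) refactor()
            }
            ## anti-cycling: after a run of (near-)degenerate steps switch
            ## to Bland's rule for the rest of the phase
            if (bestStep <= 1e-9) {
                degen <- degen + 1L
                if (degen > 150L) bland <- TRUE
            } else degen <- 0L
        }
    }
    cp1 <- c(numeric(n), rep(-1, m))
    st <- runPhase(cp1, 1L)
    if (st == "maxiter") return(list(status = "maxiter", x = x[seq_len(n)],
                                     objective = NA_real_, residual = NA_real_))
    infeasAmt <- sum(x[n + seq_len(m)])
    scale <- max(1, max(abs(b)))
    if (infeasAmt > tolFeas * scale)
        return(list(status = "infeasible", x = x[seq_len(n)],
                    objective = NA_real_, residual = infeasAmt))
    ## pin artificials at zero for phase 2
    ubx[n + seq_len(m)] <- 0
    cp2 <- c(cvec, numeric(m))
    st <- runPhase(cp2, 2L)
    if (st == "maxiter") return(list(status = "maxiter", x = x[seq_len(n)],
                                     objective = NA_real_, residual = NA_real_))
    if (st == "unbounded") return(list(status = "unbounded", x = x[seq_len(n)],
                                       objective = NA_real_,
                                       residual = NA_real_))
    refactor()                        # polish the basic values
    xr <- x[seq_len(n)]
    xr <- pmin(pmax(xr, lb), ub)      # clip 1e-12 bound noise
    obj <- sum(cvec * xr)
    res <- max(abs(A %*% xr - b))
    list(status = "optimal", x = xr,
         objective = if (maximize) obj else -obj, residual = res)
}
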