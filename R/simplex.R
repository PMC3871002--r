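#' Solve a bounded-variable linear program
#'
#' Deterministic two-phase primal simplex for problems of the form
#' optimize \eqn{c'x} subject to \eqn{Ax = b} and \eqn{l \le x \le u}.
#' This is the engine behind every flux-balance computation in the package:
#' the steady-state condition \eqn{Sv = 0} is the equality system and the
#' reaction bounds are the box constraints. Bland's rule is used for both the
#' entering and the leaving variable, so the algorithm cannot cycle and two
#' runs on the same input return bit-identical solutions.
#'
#' Lower bounds must be finite (all reactions are irreversible with
#' non-negative lower bounds); upper bounds may be `Inf`, in which case an
#' unbounded ray is reported as status `"unbounded"` rather than clamped.
#'
#' @param A constraint matrix (m rows, n columns), dense numeric.
#' @param b right-hand side, length m.
#' @param obj objective coefficients, length n.
#' @param lb,ub variable bounds, length n; `lb` finite, `lb <= ub`.
#' @param sense `"min"` or `"max"`.
#' @param tol pivot tolerance on reduced costs.
#' @param feas_tol tolerance on the phase-1 optimum below which the problem
#'   is declared feasible.
#' @param max_iter iteration cap per phase; exceeding it is a solver error.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   and for optimal problems `x` (length n) and `objective`.
#' @export
lp_solve_bounded <- function(A, b, obj, lb, ub, sense = c("min", "max"),
                             tol = 1e-9, feas_tol = 1e-7, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("lower bounds must be finite")
  if (any(lb > ub + 1e-12))   # crossed bounds define an empty box
    return(list(status = "infeasible", x = NULL, objective = NULL))
  cost <- if (sense == "max") -obj else obj

  # start: all structural variables at their lower bound
  r <- as.numeric(b - A %*% lb)
  art_sign <- ifelse(r >= 0, 1, -1)
  Abar <- cbind(A, diag(art_sign, nrow = m, ncol = m))
  lo <- c(lb, rep(0, m))
  hi <- c(ub, rep(Inf, m))
  ntot <- n + m
  stat <- c(rep(0L, n), rep(2L, m))   # 0 at lo, 1 at hi, 2 basic
  basis <- n + seq_len(m)

  ph1 <- c(rep(0, n), rep(1, m))
  res1 <- simplex_iterate(Abar, b, ph1, lo, hi, basis, stat, tol, max_iter)
  if (res1$status == "iterlimit" || res1$status == "numfail")
    stop("simplex solver failure in phase 1 (", res1$status, ")")
  if (res1$objective > feas_tol)
    return(list(status = "infeasible", x = NULL, objective = NULL))

  # artificials are pinned to zero for phase 2
  hi[(n + 1):ntot] <- 0
  res2 <- simplex_iterate(Abar, b, c(cost, rep(0, m)), lo, hi,
                          res1$basis, res1$stat, tol, max_iter)
  if (res2$status == "iterlimit" || res2$status == "numfail")
    stop("simplex solver failure in phase 2 (", res2$status, ")")
  if (res2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NULL))

  x <- res2$x[seq_len(n)]
  # nonbasic variables sit exactly on a bound; basic values may carry solve
  # noise, which the steady-state invariant tolerances absorb
  list(status = "optimal", x = x, objective = sum(obj * x))
}

# One simplex phase on the extended problem. 'stat' codes each variable as
# 0 (nonbasic at lo), 1 (nonbasic at hi), 2 (basic). Bland's rule throughout.
#' @noRd
simplex_iterate <- function(Abar, b, cost, lo, hi, basis, stat, tol, max_iter) {
  m <- nrow(Abar); ntot <- ncol(Abar)
  xval <- numeric(ntot)

  recompute_x <- function(basis, stat) {
    x <- ifelse(stat == 1L, hi, lo)
    x[!is.finite(x)] <- 0
    B <- Abar[, basis, drop = FALSE]
    nb <- setdiff(seq_len(ntot), basis)
    rhs <- b - if (length(nb)) Abar[, nb, drop = FALSE] %*% x[nb] else 0
    xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xb)) return(NULL)
    x[basis] <- as.numeric(xb)
    x
  }

  for (it in seq_len(max_iter)) {
    x <- recompute_x(basis, stat)
    if (is.null(x)) return(list(status = "numfail"))
    B <- Abar[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "numfail"))
    d <- cost - as.numeric(crossprod(Abar, y))

    enter_lo <- which(stat == 0L & d < -tol & hi > lo)
    enter_hi <- which(stat == 1L & d > tol)
    cand <- c(enter_lo, enter_hi)
    if (!length(cand)) {
      return(list(status = "optimal", x = x, basis = basis, stat = stat,
                  objective = sum(cost * x)))
    }
    j <- min(cand)                       # Bland: smallest index
    s <- if (stat[j] == 0L) 1 else -1    # +1 increasing from lo, -1 from hi

    w <- tryCatch(as.numeric(solve(B, Abar[, j])), error = function(e) NULL)
    if (is.null(w)) return(list(status = "numfail"))
    sw <- s * w
    xb <- x[basis]

    ratio <- rep(Inf, m)
    up <- sw > tol
    dn <- sw < -tol
    ratio[up] <- (xb[up] - lo[basis][up]) / sw[up]
    ratio[dn] <- (hi[basis][dn] - xb[dn]) / (-sw[dn])
    ratio[ratio < 0] <- 0                # degenerate steps clipped at 0
    t_flip <- hi[j] - lo[j]
    t_star <- min(ratio, t_flip)

    if (!is.finite(t_star)) return(list(status = "unbounded"))

    if (t_flip <= t_star + 1e-15 && t_flip <= min(ratio)) {
      stat[j] <- if (stat[j] == 0L) 1L else 0L   # bound flip, basis unchanged
      next
    }
    hits <- which(abs(ratio - t_star) <= 1e-12)
    leave_pos <- hits[which.min(basis[hits])]    # Bland on leaving variable
    leaving <- basis[leave_pos]
    stat[leaving] <- if (sw[leave_pos] > 0) 0L else 1L
    basis[leave_pos] <- j
    stat[j] <- 2L
  }
  list(status = "iterlimit")
}
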