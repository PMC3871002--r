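#' Define an optimization objective over reaction fluxes
#'
#' @param weights named numeric vector, reaction id -> objective weight
#'   (reactions not listed have weight 0), or a character vector of ids
#'   which all get weight 1.
#' @param sense `"minimize"` or `"maximize"`.
#' @param label free text; the four canonical labels are `minApo`,
#'   `maxApo`, `minDeg`, `maxDeg`.
#' @return object of class `"fba_objective"`.
#' @export
fba_objective <- function(weights, sense = c("minimize", "maximize"),
                          label = "custom") {
  sense <- match.arg(sense)
  if (is.character(weights)) weights <- stats::setNames(rep(1, length(weights)),
                                                        weights)
  if (!length(weights) || is.null(names(weights)))
    stop("objective weights must be a non-empty named vector")
  structure(list(weights = weights, sense = sense, label = label),
            class = "fba_objective")
}

#' The four canonical grouped objectives
#'
#' `minApo`/`maxApo` place weight 1 on every member of the two
#' apoptosis-initiation groups; `minDeg`/`maxDeg` on every member of the
#' three degradation groups (lysosome, proteasome, mitophagy).
#'
#' @param groups a `flux_groups` object.
#' @param label one of `"minApo"`, `"maxApo"`, `"minDeg"`, `"maxDeg"`.
#' @return an `fba_objective`.
#' @export
canonical_objective <- function(groups, label = c("minApo", "maxApo",
                                                  "minDeg", "maxDeg")) {
  label <- match.arg(label)
  apo <- c("Apoptosis (LBs)", "Apoptosis (mitochondria)")
  deg <- c("Degradation (lysosome)", "Degradation (proteasome)",
           "Degradation (mitophagy)")
  wanted <- if (grepl("Apo", label)) apo else deg
  present <- intersect(wanted, names(groups))
  if (!length(present))
    stop("objective error: none of the groups needed for ", label,
         " are present: ", paste(wanted, collapse = ", "))
  ids <- unique(unlist(groups[present]))
  fba_objective(ids, sense = if (startsWith(label, "min")) "minimize"
                else "maximize", label = label)
}

#' @noRd
objective_vector <- function(model, objective) {
  rids <- reaction_ids(model)
  unknown <- setdiff(names(objective$weights), rids)
  if (length(unknown))
    stop("objective error: unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  cc <- stats::setNames(numeric(length(rids)), rids)
  cc[names(objective$weights)] <- objective$weights
  cc
}

#' Flux balance analysis with deterministic tie-breaking
#'
#' Solves optimize \eqn{c'v} subject to \eqn{Sv = 0},
#' \eqn{lb \le v \le ub}. Because the printed flux of a single optimal
#' solution is otherwise solver-dependent (the optimum face can contain
#' alternate optima), the reported fluxes are made canonical by a secondary
#' parsimonious step: with the objective value fixed at its optimum, the
#' sum of all fluxes is minimized. Identical model and objective therefore
#' always yield identical solutions. Optionally, flux variability analysis
#' marks each reaction whose flux is unique at the optimum.
#'
#' @param model a `cell_model`.
#' @param objective an [fba_objective()].
#' @param parsimonious apply the flux-sum tie-break (default TRUE).
#' @param with_fva also run [flux_variability()] and attach per-reaction
#'   uniqueness flags.
#' @param steady_tol steady-state tolerance on `|S v|` (default 1e-6).
#' @return object of class `"fba_solution"`: `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), and when optimal `fluxes` (named,
#'   uM/h), `objective_value`, and `uniqueness_flags` (named logical, or
#'   NULL when `with_fva = FALSE`).
#' @export
solve_fba <- function(model, objective, parsimonious = TRUE,
                      with_fva = FALSE, steady_tol = 1e-6) {
  stopifnot(inherits(model, "cell_model"), inherits(objective, "fba_objective"))
  S <- build_stoichiometric_matrix(model)
  lb <- reaction_field(model, "lower_bound")
  ub <- reaction_field(model, "upper_bound")
  cc <- objective_vector(model, objective)
  sense <- if (objective$sense == "maximize") "max" else "min"

  res <- lp_solve_bounded(S, rep(0, nrow(S)), cc, lb, ub, sense)
  if (res$status != "optimal")
    return(structure(list(status = res$status, fluxes = NULL,
                          objective_value = NULL, uniqueness_flags = NULL,
                          objective = objective),
                     class = "fba_solution"))
  zopt <- res$objective
  x <- res$x

  if (parsimonious) {
    A2 <- rbind(S, cc)
    b2 <- c(rep(0, nrow(S)), zopt)
    res2 <- lp_solve_bounded(A2, b2, rep(1, ncol(S)), lb, ub, "min",
                             feas_tol = 1e-6)
    # the primary solution certifies feasibility; tiny numerical drift on
    # the fixed-objective row is the only way this can fail
    if (res2$status == "optimal") x <- res2$x
  }

  fluxes <- stats::setNames(x, colnames(S))
  resid <- max(abs(S %*% x))
  if (resid > steady_tol)
    stop("solver error: steady-state residual ", format(resid),
         " exceeds tolerance")
  sol <- structure(list(status = "optimal", fluxes = fluxes,
                        objective_value = zopt, uniqueness_flags = NULL,
                        objective = objective),
                   class = "fba_solution")
  if (with_fva) {
    fva <- flux_variability(model, objective, optimum = zopt)
    sol$uniqueness_flags <- stats::setNames(
      fva$max_flux - fva$min_flux <= 1e-6, fva$reaction)
  }
  sol
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("fba_solution [", x$objective$label, "]: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux variability analysis at the optimum
#'
#' For each reaction, the minimum and maximum flux compatible with the
#' steady state, the bounds, and the objective fixed at its optimal value.
#' A reaction with `max_flux - min_flux <= 1e-6` carries a unique flux at
#' the optimum; a wider interval marks alternate optima.
#'
#' @param model a `cell_model`.
#' @param objective an [fba_objective()].
#' @param optimum optionally the precomputed optimal objective value.
#' @return data.frame with columns `reaction`, `min_flux`, `max_flux`.
#' @export
flux_variability <- function(model, objective, optimum = NULL) {
  S <- build_stoichiometric_matrix(model)
  lb <- reaction_field(model, "lower_bound")
  ub <- reaction_field(model, "upper_bound")
  cc <- objective_vector(model, objective)
  if (is.null(optimum)) {
    base <- lp_solve_bounded(S, rep(0, nrow(S)), cc, lb, ub,
                             if (objective$sense == "maximize") "max" else "min")
    if (base$status != "optimal")
      stop("FVA error: base problem is ", base$status)
    optimum <- base$objective
  }
  A <- rbind(S, cc)
  b <- c(rep(0, nrow(S)), optimum)
  n <- ncol(S)
  mn <- mx <- numeric(n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    lo <- lp_solve_bounded(A, b, e, lb, ub, "min", feas_tol = 1e-6)
    hi <- lp_solve_bounded(A, b, e, lb, ub, "max", feas_tol = 1e-6)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA error: subproblem for ", colnames(S)[j], " is ",
           lo$status, "/", hi$status)
    mn[j] <- lo$objective; mx[j] <- hi$objective
  }
  data.frame(reaction = colnames(S), min_flux = pmin(mn, mx),
             max_flux = pmax(mn, mx), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Brute-force vertex-enumeration oracle for small models
#'
#' Exhaustively enumerates the basic feasible solutions of
#' `{Sv = 0, lb <= v <= ub}`: every choice of a full-rank basic column set
#' combined with every lower/upper-bound assignment of the nonbasic
#' variables is solved and checked for feasibility. Exponential cost is
#' accepted — this function exists as an independent check on the simplex
#' engine, and refuses models with more than `max_reactions` reactions
#' rather than approximating. All bounds must be finite.
#'
#' @param model a `cell_model` with at most `max_reactions` reactions.
#' @param objective an [fba_objective()].
#' @param max_reactions hard size cap (default 12).
#' @return list with `status` (`"optimal"` or `"infeasible"`), `objective_value`
#'   and `fluxes` (one optimal vertex) when optimal.
#' @export
enumerate_vertices <- function(model, objective, max_reactions = 12L) {
  stopifnot(inherits(model, "cell_model"))
  n <- length(model$reactions)
  if (n > max_reactions)
    stop("size error: enumerate_vertices caps at ", max_reactions,
         " reactions, model has ", n)
  S <- build_stoichiometric_matrix(model)
  lb <- reaction_field(model, "lower_bound")
  ub <- reaction_field(model, "upper_bound")
  if (any(!is.finite(ub)))
    stop("size error: enumerate_vertices requires finite upper bounds")
  cc <- objective_vector(model, objective)
  maximize <- objective$sense == "maximize"
  r <- qr(S)$rank

  best_val <- NULL; best_x <- NULL
  consider <- function(x) {
    if (max(abs(S %*% x)) > 1e-7) return()
    if (any(x < lb - 1e-9) || any(x > ub + 1e-9)) return()
    val <- sum(cc * x)
    if (is.null(best_val) || (maximize && val > best_val + 1e-12) ||
        (!maximize && val < best_val - 1e-12)) {
      best_val <<- val; best_x <<- x
    }
  }

  if (r == 0) {
    # no coupling: each flux independently at its best bound
    x <- ifelse((cc > 0) == maximize, ub, lb)
    consider(x)
  } else {
    basics <- utils::combn(n, r)
    for (k in seq_len(ncol(basics))) {
      B <- basics[, k]
      SB <- S[, B, drop = FALSE]
      if (qr(SB)$rank < r) next
      N <- setdiff(seq_len(n), B)
      for (mask in 0:(2^length(N) - 1)) {
        xN <- lb[N]
        if (length(N)) {
          at_ub <- bitwAnd(mask, 2^(seq_along(N) - 1)) > 0
          xN[at_ub] <- ub[N][at_ub]
        }
        rhs <- if (length(N)) -S[, N, drop = FALSE] %*% xN else
          matrix(0, nrow(S), 1)
        xB <- tryCatch(qr.solve(SB, rhs, tol = 1e-10),
                       error = function(e) NULL)
        if (is.null(xB)) next
        x <- numeric(n); x[B] <- xB; x[N] <- xN
        consider(x)
      }
    }
  }
  if (is.null(best_val)) return(list(status = "infeasible"))
  list(status = "optimal", objective_value = best_val,
       fluxes = stats::setNames(best_x, colnames(S)))
}
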