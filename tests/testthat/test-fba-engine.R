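test_that("capacity-limited chain solves to its closed form", {
  m <- two_reaction_chain()
  sol <- solve_fba(m, fba_objective("out", "maximize"), with_fva = TRUE)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(10, 10))
  expect_true(all(sol$uniqueness_flags))
  # every range degenerate
  fva <- flux_variability(m, fba_objective("out", "maximize"))
  expect_equal(fva$min_flux, fva$max_flux)
})

test_that("simplex agrees with the vertex-enumeration oracle over 100 seeds", {
  worst <- 0
  for (s in 1:100) {
    gen <- generate_random_network(
      synthetic_spec(5, 8, 0.5, 1, 1, bound_slack = 1, seed = s))
    obj <- random_objective(gen$v_star, seed = s)
    a <- solve_fba(gen$model, obj, parsimonious = FALSE)
    b <- enumerate_vertices(gen$model, obj)
    expect_identical(a$status, b$status)
    if (a$status == "optimal") {
      expect_steady_and_bounded(gen$model, a)
      worst <- max(worst, abs(a$objective_value - b$objective_value))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the oracle refuses models above its size cap", {
  gen <- generate_random_network(synthetic_spec(6, 13, 0.5, 2, 2, seed = 1))
  expect_identical(length(gen$model$reactions), 13L)
  expect_error(enumerate_vertices(gen$model,
                                  random_objective(gen$v_star, 1)),
               "size error")
})

test_that("FVA exposes the alternate optima of the diamond split", {
  d <- micro_fixtures()$diamond
  obj <- fba_objective("out", "maximize")
  fva <- flux_variability(d, obj)
  b1 <- fva[fva$reaction == "b1", ]
  b2 <- fva[fva$reaction == "b2", ]
  expect_equal(c(b1$min_flux, b1$max_flux), c(0, 10), tolerance = 1e-8)
  expect_equal(c(b2$min_flux, b2$max_flux), c(0, 10), tolerance = 1e-8)
  sol <- solve_fba(d, obj, with_fva = TRUE)
  expect_false(sol$uniqueness_flags[["b1"]])
  # parsimonious tie-break still returns a deterministic split
  expect_identical(sol$fluxes, solve_fba(d, obj, with_fva = TRUE)$fluxes)
})

test_that("reported fluxes always lie inside their FVA range", {
  for (s in c(2, 5, 9)) {
    gen <- generate_random_network(
      synthetic_spec(5, 8, 0.6, 1, 1, bound_slack = 2, seed = s))
    obj <- random_objective(gen$v_star, seed = s)
    sol <- solve_fba(gen$model, obj)
    fva <- flux_variability(gen$model, obj)
    v <- sol$fluxes[fva$reaction]
    expect_true(all(v >= fva$min_flux - 1e-7))
    expect_true(all(v <= fva$max_flux + 1e-7))
  }
})

test_that("relaxing an upper bound never hurts the optimum", {
  for (s in 1:20) {
    gen <- generate_random_network(
      synthetic_spec(5, 8, 0.5, 1, 1, bound_slack = 1, seed = s))
    obj <- random_objective(gen$v_star, seed = s + 500)
    base <- solve_fba(gen$model, obj, parsimonious = FALSE)
    set.seed(s)
    j <- sample(length(gen$model$reactions), 1)
    relaxed <- gen$model
    relaxed$reactions[[j]]$upper_bound <-
      relaxed$reactions[[j]]$upper_bound + 5
    more <- solve_fba(relaxed, obj, parsimonious = FALSE)
    if (base$status == "optimal" && more$status == "optimal")
      expect_gte(more$objective_value, base$objective_value - 1e-8)
  }
})

test_that("degenerate statuses are reported, never clamped", {
  fx <- micro_fixtures()
  expect_identical(solve_fba(fx$infeasible,
                             fba_objective("sink", "maximize"))$status,
                   "infeasible")
  expect_identical(solve_fba(fx$unbounded,
                             fba_objective("fwd", "maximize"))$status,
                   "unbounded")
  # infeasible base problems propagate out of FVA
  expect_error(flux_variability(fx$infeasible,
                                fba_objective("sink", "maximize")),
               "infeasible")
})

test_that("solutions are bit-identical across repeated solves", {
  m <- make_skeleton_model()
  obj <- canonical_objective(model_groups(m), "maxDeg")
  s1 <- solve_fba(m, obj)
  s2 <- solve_fba(m, obj)
  expect_identical(s1, s2)
})

test_that("an independent general-purpose LP solver confirms the optima", {
  for (s in 1:15) {
    gen <- generate_random_network(
      synthetic_spec(5, 8, 0.5, 1, 1, bound_slack = 1, seed = s))
    S <- build_stoichiometric_matrix(gen$model)
    lb <- vapply(gen$model$reactions, `[[`, 0, "lower_bound")
    ub <- vapply(gen$model$reactions, `[[`, 0, "upper_bound")
    set.seed(s + 300)
    cc <- runif(ncol(S), -1, 2)
    mine <- lp_solve_bounded(S, rep(0, nrow(S)), cc, lb, ub, "max")
    ref <- tryCatch(
      pracma::linprog(cc, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                      maxiter = 200, maximize = TRUE),
      error = function(e) NULL)
    expect_identical(mine$status, "optimal")
    if (!is.null(ref) && !is.null(ref$fval) && is.finite(ref$fval))
      expect_equal(mine$objective, ref$fval, tolerance = 1e-6)
  }
})
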