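# tiny builders shared across test files

two_reaction_chain <- function(cap_in = 10, cap_out = 10) {
  cell_model(metabolite("A"), list(
    reaction("in", c(A = 1), 0, cap_in, "input"),
    reaction("out", c(A = -1), 0, cap_out, "output")))
}

# a random objective over a generated network, deterministic in `seed`
random_objective <- function(v_star, seed, k = 3, sense = "maximize") {
  set.seed(seed)
  ids <- sample(names(v_star), min(k, length(v_star)))
  fba_objective(stats::setNames(round(runif(length(ids), -2, 2), 2), ids),
                sense = sense)
}

# assemble a scan_result by hand (for onset-detection oracles)
fake_scan <- function(values, flux, group = "Apoptosis (LBs)",
                      status = rep("optimal", length(values))) {
  pts <- data.frame(input_value = values, status = status,
                    objective_value = 0, check.names = FALSE)
  pts[[group]] <- flux
  structure(list(spec = scan_spec("in", values, "maxDeg"), points = pts),
            class = "scan_result")
}

expect_steady_and_bounded <- function(model, sol,
                                      steady_tol = 1e-6, bound_tol = 1e-9) {
  expect_identical(sol$status, "optimal")
  S <- build_stoichiometric_matrix(model)
  v <- sol$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), steady_tol)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  expect_true(all(v >= lb - bound_tol))
  expect_true(all(v <= ub + bound_tol))
  invisible(v)
}

# local path where a copy of the deposited BioModels file (identifier
# MODEL1302200000) can be placed for the deposited-model checks
deposited_model_path <- function() {
  testthat::test_path("biomodels", "MODEL1302200000.xml")
}

reactions_equal <- function(a, b) {
  for (i in seq_along(a$reactions)) {
    x <- a$reactions[[i]]; y <- b$reactions[[i]]
    for (f in c("id", "name", "lower_bound", "upper_bound", "boundary_kind",
                "speed_tag", "groups"))
      if (!identical(x[[f]], y[[f]])) return(paste(x$id, f))
    if (!identical(x$stoichiometry[order(names(x$stoichiometry))],
                   y$stoichiometry[order(names(y$stoichiometry))]))
      return(paste(x$id, "stoichiometry"))
    if (!identical(is.na(x$best_reference_flux),
                   is.na(y$best_reference_flux)))
      return(paste(x$id, "best_reference_flux"))
    if (is.finite(x$best_reference_flux) &&
        x$best_reference_flux != y$best_reference_flux)
      return(paste(x$id, "best_reference_flux"))
  }
  TRUE
}
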