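test_that("objective suite has the canonical shape and internal consistency", {
  m <- make_skeleton_model()
  g <- model_groups(m)
  suite <- run_objective_suite(m, g)
  expect_identical(names(suite$solutions),
                   c("maxApo", "minApo", "maxDeg", "minDeg"))
  expect_setequal(suite$table$group, canonical_group_labels())
  vals <- as.matrix(suite$table[-1])
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= -1e-9))

  # objective value equals the summed flux of its own groups
  apo <- c("Apoptosis (LBs)", "Apoptosis (mitochondria)")
  deg <- c("Degradation (lysosome)", "Degradation (proteasome)",
           "Degradation (mitophagy)")
  for (lab in names(suite$solutions)) {
    own <- if (grepl("Apo", lab)) apo else deg
    expect_equal(sum(suite$table[suite$table$group %in% own, lab]),
                 suite$solutions[[lab]]$objective_value, tolerance = 1e-8,
                 label = lab)
  }
  # a minimal-apoptosis steady state of the healthy cell has no apoptosis
  expect_equal(suite$solutions$minApo$objective_value, 0, tolerance = 1e-9)
})

test_that("scans are pure, restore the model, and validate their input", {
  nl <- generate_neuronlike_network(3)
  before <- nl$model
  spec <- scan_spec("WINin", seq(0, 24, by = 3), "maxDeg")
  s1 <- run_scan(nl$model, spec, nl$groups)
  s2 <- run_scan(nl$model, spec, nl$groups)
  expect_identical(s1, s2)
  expect_identical(nl$model, before)
  expect_identical(s1$points$input_value, spec$values)

  expect_error(run_scan(nl$model, scan_spec("nope", 0:3, "maxDeg"),
                        nl$groups), "spec error")
  expect_error(run_scan(nl$model, scan_spec("LysoDeg", 0:3, "maxDeg"),
                        nl$groups), "not a boundary input")
  expect_error(scan_spec("WINin", c(3, 2, 1)), "strictly increasing")
})

test_that("an input disconnected from the objective gives a flat series", {
  mets <- rbind(metabolite("A"), metabolite("B"), metabolite("C"))
  m <- cell_model(mets, list(
    reaction("in", c(A = 1), 0, 10, "input"),
    reaction("conv", c(A = -1, B = 1), 0, 10,
             groups = "Degradation (lysosome)"),
    reaction("out", c(B = -1), 0, 10, "output"),
    reaction("noop_in", c(C = 1), 0, 10, "input"),
    reaction("c_out", c(C = -1), 0, 10, "output")))
  g <- model_groups(m)
  sc <- run_scan(m, scan_spec("noop_in", 0:5, "maxDeg",
                              pin_mode = "relax_ub"), g)
  expect_true(all(sc$points$status == "optimal"))
  expect_true(all(sc$points$objective_value ==
                    sc$points$objective_value[1]))
  expect_true(all(sc$points[["Degradation (lysosome)"]] ==
                    sc$points[["Degradation (lysosome)"]][1]))
})

test_that("relax_ub scans have monotone maximization objectives", {
  gen <- generate_random_network(
    synthetic_spec(5, 9, 0.5, 2, 2, bound_slack = 3, seed = 8))
  ids <- vapply(gen$model$reactions, `[[`, "", "id")
  kinds <- vapply(gen$model$reactions, `[[`, "", "boundary_kind")
  input_id <- ids[kinds == "input"][1]
  g <- assign_groups(gen$model,
                     stats::setNames(list("Degradation (lysosome)"),
                                     ids[kinds == "output"][1]))
  sc <- run_scan(gen$model, scan_spec(input_id, 0:8, "maxDeg",
                                      pin_mode = "relax_ub"), g)
  ov <- sc$points$objective_value[sc$points$status == "optimal"]
  expect_true(all(diff(ov) >= -1e-8))
})

test_that("feasibility windows cover exactly the contiguous optimal run", {
  nl <- generate_neuronlike_network(1)
  sc <- run_scan(nl$model, scan_spec("WINin", 0:30, "maxDeg"), nl$groups)
  w <- find_feasibility_window(sc)
  expect_identical(c(w$min_feasible, w$max_feasible), nl$window)
  expect_identical(sc$points$status[sc$points$input_value < nl$window[1]],
                   rep("infeasible", nl$window[1]))

  # all-optimal scan: window spans the whole range
  sc2 <- run_scan(nl$model,
                  scan_spec("WINin", seq(nl$window[1], nl$window[2]),
                            "maxDeg"), nl$groups)
  w2 <- find_feasibility_window(sc2)
  expect_identical(c(w2$min_feasible, w2$max_feasible), nl$window)

  # no optimal point at all
  sc3 <- run_scan(nl$model, scan_spec("WINin", 0:3, "maxDeg"), nl$groups)
  w3 <- find_feasibility_window(sc3)
  expect_true(is.na(w3$min_feasible) && is.na(w3$max_feasible))
})

test_that("onset detection matches hand-checked step series", {
  # appears: series 0,0,5,5 over values 0..3 -> threshold 2
  sc <- fake_scan(0:3, c(0, 0, 5, 5))
  expect_equal(find_onset(sc, "Apoptosis (LBs)", "appears")$threshold, 2)
  # quiet everywhere -> no onset
  expect_true(is.na(find_onset(fake_scan(0:3, rep(0, 4)),
                               "Apoptosis (LBs)", "appears")$threshold))
  # vanishes requires persistence: 5,0,5,0,0 -> threshold 3, not 1
  expect_equal(find_onset(fake_scan(0:4, c(5, 0, 5, 0, 0)),
                          "Apoptosis (LBs)", "vanishes")$threshold, 3)
  # an infeasible tail breaks the persistence run
  sc4 <- fake_scan(0:3, c(5, 0, NA, 0),
                   status = c("optimal", "optimal", "infeasible", "optimal"))
  expect_equal(find_onset(sc4, "Apoptosis (LBs)", "vanishes")$threshold, 3)
  expect_error(find_onset(sc, "No such group", "appears"), "unknown group")
})

test_that("experiment presets resolve to valid scan specifications", {
  for (nm in c("o2", "atp", "mptp", "asyn", "tyrosine")) {
    p <- load_experiment_preset(nm)
    specs <- preset_scan_specs(p)
    expect_setequal(names(specs), c("minApo", "maxDeg"))
    expect_identical(specs$minApo$pin_mode, "pin")
    expect_identical(max(specs$minApo$values),
                     if (nm == "atp") 1000 else 100)
    expect_identical(specs$minApo$augment_objective, nm == "o2")
  }
  m <- make_skeleton_model()
  ids <- vapply(m$reactions, `[[`, "", "id")
  for (nm in names(skeleton_scan_inputs()))
    expect_true(skeleton_scan_inputs()[[nm]] %in% ids)
  expect_error(preset_scan_specs(load_experiment_preset("basic")),
               "objective suite")
})

test_that("the oxygen preset augments the objective with the swept input", {
  m <- make_skeleton_model()
  g <- model_groups(m)
  spec <- preset_scan_specs(load_experiment_preset("o2"), step = 50)$minApo
  sc <- run_scan(m, spec, g)
  expect_true(all(sc$points$status == "optimal"))
  # pinned input in the objective: the optimum tracks the pinned value
  expect_equal(diff(sc$points$objective_value), diff(spec$values),
               tolerance = 1e-6)
})
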