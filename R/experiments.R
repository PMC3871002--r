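#' Run the four-objective basic suite
#'
#' Solves the model under the four canonical target functions (maxApo,
#' minApo, maxDeg, minDeg) and reports each functional group's summed flux
#' per objective — the "basic model" characterization of the cell. Each
#' solve uses the parsimonious tie-break, and flux-variability uniqueness
#' flags can be attached to mark group sums that are not unique at the
#' optimum.
#'
#' @param model a `cell_model`.
#' @param groups a `flux_groups`; default: the groups carried on the model.
#' @param with_fva attach per-reaction uniqueness flags (slow: two LPs per
#'   reaction per objective).
#' @return object of class `"objective_suite_result"`: `table` is a
#'   data.frame with one row per group and the four objective columns in
#'   the order maxApo, minApo, maxDeg, minDeg; `solutions` holds the four
#'   `fba_solution` objects.
#' @export
run_objective_suite <- function(model, groups = model_groups(model),
                                with_fva = FALSE) {
  labels <- c("maxApo", "minApo", "maxDeg", "minDeg")
  sols <- list()
  tab <- data.frame(group = names(groups), stringsAsFactors = FALSE)
  for (lab in labels) {
    sol <- solve_fba(model, canonical_objective(groups, lab),
                     with_fva = with_fva)
    if (sol$status != "optimal")
      stop("analysis error: basic model is ", sol$status, " under ", lab)
    sols[[lab]] <- sol
    tab[[lab]] <- as.numeric(group_flux_sums(groups, sol$fluxes))
  }
  structure(list(table = tab, solutions = sols, groups = groups),
            class = "objective_suite_result")
}

#' @export
print.objective_suite_result <- function(x, ...) {
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Specify an input-flux scan
#'
#' @param input_reaction_id id of a boundary input reaction to sweep.
#' @param values strictly increasing non-negative pinned flux values
#'   (uM/h); the conventional step is 1.
#' @param objective_label canonical objective solved at each step
#'   (`"minApo"` or `"maxDeg"` in the experiment presets).
#' @param pin_mode `"pin"` fixes `lb = ub = value` (the default: the swept
#'   input is forced through the cell); `"relax_ub"` only raises the upper
#'   bound to the value.
#' @param augment_objective also give the swept input reaction weight 1 in
#'   the objective (used by the oxygen experiment).
#' @return object of class `"scan_spec"`.
#' @export
scan_spec <- function(input_reaction_id, values = 0:100,
                      objective_label = c("minApo", "maxDeg", "maxApo",
                                          "minDeg"),
                      pin_mode = c("pin", "relax_ub"),
                      augment_objective = FALSE) {
  objective_label <- match.arg(objective_label)
  pin_mode <- match.arg(pin_mode)
  values <- as.numeric(values)
  if (any(values < 0) || any(diff(values) <= 0))
    stop("scan values must be non-negative and strictly increasing")
  structure(list(input_reaction_id = input_reaction_id, values = values,
                 objective_label = objective_label, pin_mode = pin_mode,
                 augment_objective = augment_objective),
            class = "scan_spec")
}

#' Sweep an input flux and record grouped steady-state fluxes
#'
#' For each scan value the input reaction's bounds are set according to the
#' pin mode, the objective is solved with the parsimonious tie-break, and
#' the per-group summed fluxes are recorded. Infeasible points are recorded
#' as such (their group fluxes are absent), never skipped, so feasibility
#' windows remain computable. The input model is not modified.
#'
#' @param model a `cell_model`.
#' @param spec a [scan_spec()].
#' @param groups a `flux_groups`; default: the groups carried on the model.
#' @return object of class `"scan_result"`: `spec`, and `points`, a
#'   data.frame with columns `input_value`, `status`, `objective_value`,
#'   and one column per group label (NA at non-optimal points).
#' @export
run_scan <- function(model, spec, groups = model_groups(model)) {
  stopifnot(inherits(spec, "scan_spec"))
  ridx <- match(spec$input_reaction_id, reaction_ids(model))
  if (is.na(ridx))
    stop("spec error: unknown reaction id: ", spec$input_reaction_id)
  if (model$reactions[[ridx]]$boundary_kind != "input")
    stop("spec error: ", spec$input_reaction_id,
         " is not a boundary input reaction")
  objective <- canonical_objective(groups, spec$objective_label)
  if (spec$augment_objective) {
    w <- objective$weights
    w[spec$input_reaction_id] <- (w[spec$input_reaction_id] %||% 0) + 1
    objective <- fba_objective(w, sense = objective$sense,
                               label = paste0(objective$label, "+input"))
  }
  pts <- data.frame(input_value = spec$values,
                    status = NA_character_,
                    objective_value = NA_real_)
  for (lab in names(groups)) pts[[lab]] <- NA_real_
  work <- model
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    r <- model$reactions[[ridx]]
    if (spec$pin_mode == "pin") { r$lower_bound <- v; r$upper_bound <- v }
    else r$upper_bound <- v
    work$reactions[[ridx]] <- r
    sol <- solve_fba(work, objective)
    pts$status[i] <- sol$status
    if (sol$status == "optimal") {
      pts$objective_value[i] <- sol$objective_value
      gs <- group_flux_sums(groups, sol$fluxes)
      for (lab in names(groups)) pts[[lab]][i] <- gs[[lab]]
    }
  }
  structure(list(spec = spec, points = pts), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  n_opt <- sum(x$points$status == "optimal")
  cat("scan_result: ", x$spec$input_reaction_id, " over [",
      min(x$spec$values), ", ", max(x$spec$values), "] (",
      nrow(x$points), " points, ", n_opt, " optimal), objective ",
      x$spec$objective_label, "\n", sep = "")
  invisible(x)
}

#' Extract the feasibility window of a scan
#'
#' The window is the maximal contiguous run of optimal scan points starting
#' at the smallest feasible value: `min_feasible` is the first value with an
#' optimal steady state and `max_feasible` the last value of that run.
#' (For a pinned scan the feasible set of the pinned value is the projection
#' of a polytope and hence an interval, so the run is the whole feasible
#' range.) Both are `NA` when no point is optimal.
#'
#' @param scan a `scan_result`.
#' @return object of class `"feasibility_window"` with fields
#'   `min_feasible`, `max_feasible` (uM/h or NA).
#' @export
find_feasibility_window <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  ok <- scan$points$status == "optimal"
  if (!any(ok))
    return(structure(list(min_feasible = NA_real_, max_feasible = NA_real_),
                     class = "feasibility_window"))
  first <- which(ok)[1]
  run_end <- first
  while (run_end < nrow(scan$points) && ok[run_end + 1]) run_end <- run_end + 1
  structure(list(min_feasible = scan$points$input_value[first],
                 max_feasible = scan$points$input_value[run_end]),
            class = "feasibility_window")
}

#' Locate the onset (or extinction) threshold of a group flux
#'
#' `direction = "appears"`: the smallest scanned value whose optimal
#' solution carries a group flux above `tol`. `direction = "vanishes"`: the
#' smallest scanned value from which the group flux stays at or below `tol`
#' for every larger scanned value — persistence is required so that
#' isolated fluctuations (which the narrow dopamine-synthesis bounds can
#' cause at high input fluxes) do not fake an extinction. Infeasible points
#' carry no steady flux: they are ignored for `"appears"` and break the
#' persistence run for `"vanishes"`.
#'
#' @param scan a `scan_result`.
#' @param group a group label present in the scan.
#' @param direction `"appears"` or `"vanishes"`.
#' @param tol flux tolerance in uM/h.
#' @return object of class `"onset_report"`: `group`, `direction`,
#'   `threshold` (uM/h or NA), `tol`.
#' @export
find_onset <- function(scan, group, direction = c("appears", "vanishes"),
                       tol = 1e-6) {
  stopifnot(inherits(scan, "scan_result"))
  direction <- match.arg(direction)
  group <- normalize_group_label(group)
  if (!group %in% names(scan$points))
    stop("unknown group in scan: ", group)
  flux <- scan$points[[group]]
  ok <- scan$points$status == "optimal"
  threshold <- NA_real_
  if (direction == "appears") {
    hit <- which(ok & !is.na(flux) & flux > tol)
    if (length(hit)) threshold <- scan$points$input_value[hit[1]]
  } else {
    quiet <- ok & !is.na(flux) & flux <= tol
    # last index after which 'quiet' holds everywhere
    if (all(quiet)) threshold <- scan$points$input_value[1]
    else {
      run <- rev(cumprod(rev(quiet)))    # 1 where quiet persists to the end
      hit <- which(run == 1)
      if (length(hit)) threshold <- scan$points$input_value[hit[1]]
    }
  }
  structure(list(group = group, direction = direction,
                 threshold = threshold, tol = tol),
            class = "onset_report")
}

#' Load a packaged experiment preset
#'
#' The presets encode the published experiment parameterization as data:
#' scan ranges 0-100 uM/h (0-1000 for the ATP experiment), step 1, the
#' minApo and maxDeg target functions, pinned input bounds, and — for the
#' oxygen experiment only — inclusion of the swept input reaction in the
#' optimization function.
#'
#' @param name one of `"basic"`, `"o2"`, `"atp"`, `"mptp"`, `"asyn"`,
#'   `"tyrosine"`.
#' @return the preset as a list; for scan presets, `$scan_specs(model)`
#'   is resolved by [preset_scan_specs()].
#' @export
load_experiment_preset <- function(name = c("basic", "o2", "atp", "mptp",
                                            "asyn", "tyrosine")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "dnfba", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Resolve a scan preset into scan specifications
#'
#' @param preset a preset list from [load_experiment_preset()].
#' @param step optional override of the scan step (uM/h).
#' @param pin_mode optional override of the pin mode.
#' @return named list of [scan_spec()], one per objective in the preset.
#' @export
preset_scan_specs <- function(preset, step = NULL, pin_mode = NULL) {
  if (identical(preset$experiment, "basic"))
    stop("the basic experiment is an objective suite, not a scan")
  step <- step %||% preset$step
  values <- seq(preset$from, preset$to, by = step)
  specs <- lapply(preset$objectives, function(lab)
    scan_spec(preset$input_reaction, values = values, objective_label = lab,
              pin_mode = pin_mode %||% preset$pin_mode,
              augment_objective = isTRUE(preset$augment_objective)))
  stats::setNames(specs, preset$objectives)
}
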