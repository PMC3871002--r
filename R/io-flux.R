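#' Write grouped flux results as TSV
#'
#' For an objective-suite result the table is wide — one row per group and
#' the four objective columns in the order maxApo, minApo, maxDeg, minDeg.
#' For a scan result it is long — one row per (input value, group) with
#' columns `experiment`, `objective`, `input_value`, `group`, `flux`.
#' Fluxes are printed with two decimals so diffs are stable; full precision
#' lives in the JSON summaries.
#'
#' @param x an `objective_suite_result` or `scan_result`.
#' @param sink file path or connection.
#' @param experiment experiment name written into scan tables.
#' @export
write_flux_table <- function(x, sink, experiment = "custom") {
  UseMethod("write_flux_table")
}

#' @export
write_flux_table.objective_suite_result <- function(x, sink,
                                                    experiment = "basic") {
  tab <- x$table
  out <- paste(c("group", "maxApo", "minApo", "maxDeg", "minDeg"),
               collapse = "\t")
  for (i in seq_len(nrow(tab))) {
    out <- c(out, paste(c(gsub("αSYN", "aSYN", tab$group[i], fixed = TRUE),
                          sprintf("%.2f", c(tab$maxApo[i], tab$minApo[i],
                                            tab$maxDeg[i], tab$minDeg[i]))),
                        collapse = "\t"))
  }
  writeLines(out, sink)
  invisible(sink)
}

#' @export
write_flux_table.scan_result <- function(x, sink, experiment = "custom") {
  glabs <- setdiff(names(x$points),
                   c("input_value", "status", "objective_value"))
  out <- "experiment\tobjective\tinput_value\tgroup\tflux"
  for (i in seq_len(nrow(x$points))) {
    for (g in glabs) {
      v <- x$points[[g]][i]
      out <- c(out, paste(experiment, x$spec$objective_label,
                          sprintf("%.6g", x$points$input_value[i]),
                          gsub("αSYN", "aSYN", g, fixed = TRUE),
                          if (is.na(v)) "NA" else sprintf("%.2f", v),
                          sep = "\t"))
    }
  }
  writeLines(out, sink)
  invisible(sink)
}

#' Summarize a scan as windows and onset thresholds
#'
#' @param scan a `scan_result`.
#' @param onset_groups group labels whose onset ("appears") thresholds are
#'   reported; defaults to the apoptosis groups present in the scan.
#' @return a list (JSON-ready): feasibility window, onsets, objective.
#' @export
scan_summary <- function(scan, onset_groups = NULL) {
  glabs <- setdiff(names(scan$points),
                   c("input_value", "status", "objective_value"))
  if (is.null(onset_groups))
    onset_groups <- intersect(c("Apoptosis (LBs)", "Apoptosis (mitochondria)"),
                              glabs)
  win <- find_feasibility_window(scan)
  onsets <- lapply(onset_groups, function(g) {
    on <- find_onset(scan, g, "appears")
    list(group = gsub("αSYN", "aSYN", g, fixed = TRUE),
         threshold = if (is.na(on$threshold)) NULL else on$threshold)
  })
  # total apoptosis onset across the groups, the usual headline number
  apo_tot <- if (length(onset_groups)) {
    f <- rowSums(as.matrix(scan$points[onset_groups]), na.rm = FALSE)
    ok <- scan$points$status == "optimal" & !is.na(f) & f > 1e-6
    if (any(ok)) scan$points$input_value[which(ok)[1]] else NULL
  } else NULL
  list(objective = scan$spec$objective_label,
       input_reaction = scan$spec$input_reaction_id,
       pin_mode = scan$spec$pin_mode,
       n_points = nrow(scan$points),
       n_optimal = sum(scan$points$status == "optimal"),
       feasibility_window = list(
         min_feasible = if (is.na(win$min_feasible)) NULL else
           win$min_feasible,
         max_feasible = if (is.na(win$max_feasible)) NULL else
           win$max_feasible),
       apoptosis_onset = apo_tot,
       group_onsets = onsets)
}
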