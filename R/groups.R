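#' Canonical functional flux-group labels
#'
#' The eighteen functional groups under which model fluxes are reported:
#' reactive-oxygen-species production (dopamine metabolism, mitochondrial
#' complex I and III), ROS elimination and damage, the two
#' apoptosis-initiation routes (Lewy-body-induced and mitochondria-induced),
#' the three degradation routes (lysosome, proteasome, mitophagy),
#' mitochondrial biogenesis, extracellular dopamine, and the alpha-synuclein
#' aggregation/output/toxicity/DJ-1-inhibition processes. Labels are spelled
#' with the Greek alpha; the ASCII alias `"aSYN"` is accepted wherever
#' labels are read from files.
#'
#' @return character vector of the 18 canonical labels.
#' @export
canonical_group_labels <- function() {
  c("ROS production (DA)",
    "ROS production (mitochondria, complex I)",
    "ROS production (mitochondria, complex III)",
    "ROS elimination (DJ-1)",
    "ROS damage (protein)",
    "ROS damage (mitochondria)",
    "ROS damage (DNA)",
    "Apoptosis (LBs)",
    "Apoptosis (mitochondria)",
    "Degradation (lysosome)",
    "Degradation (proteasome)",
    "Degradation (mitophagy)",
    "Biogenesis of mitochondria",
    "Extracellular DA",
    "αSYN aggregation",
    "αSYN output reaction",
    "Toxic effect of αSYN aggregates",
    "Inhibition of αSYN aggregation by DJ-1")
}

#' Normalize group labels read from files
#'
#' Replaces the ASCII alias prefix `"aSYN"` (and `"alphaSYN"`) with the
#' canonical Greek-alpha spelling.
#'
#' @param labels character vector.
#' @return canonical labels.
#' @export
normalize_group_label <- function(labels) {
  labels <- gsub("alphaSYN", "αSYN", labels, fixed = TRUE)
  gsub("aSYN", "αSYN", labels, fixed = TRUE)
}

#' Build a flux-group mapping from a reaction tag table
#'
#' @param model a `cell_model`.
#' @param tag_table named list: reaction id -> character vector of group
#'   labels. Every id must exist in the model; reactions not mentioned
#'   belong to no group.
#' @return object of class `"flux_groups"`: named list, group label ->
#'   character vector of member reaction ids.
#' @export
assign_groups <- function(model, tag_table) {
  stopifnot(inherits(model, "cell_model"), is.list(tag_table))
  rids <- reaction_ids(model)
  unknown <- setdiff(names(tag_table), rids)
  if (length(unknown))
    stop("grouping error: unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  groups <- list()
  for (id in names(tag_table)) {
    for (lab in normalize_group_label(as.character(tag_table[[id]]))) {
      groups[[lab]] <- c(groups[[lab]], id)
    }
  }
  structure(lapply(groups, unique), class = "flux_groups")
}

#' Extract the flux groups carried on a model's reactions
#'
#' Convenience wrapper over [assign_groups()] using each reaction's own
#' `groups` field as the tag table.
#'
#' @param model a `cell_model`.
#' @return a `flux_groups` object.
#' @export
model_groups <- function(model) {
  tt <- lapply(model$reactions, `[[`, "groups")
  names(tt) <- reaction_ids(model)
  assign_groups(model, tt[vapply(tt, length, 0L) > 0])
}

#' Sum a flux vector over each group
#'
#' @param groups a `flux_groups` object.
#' @param fluxes named numeric vector of reaction fluxes.
#' @return named numeric vector, one summed flux (uM/h) per group label.
#' @export
group_flux_sums <- function(groups, fluxes) {
  stopifnot(inherits(groups, "flux_groups"))
  vapply(groups, function(members) {
    miss <- setdiff(members, names(fluxes))
    if (length(miss))
      stop("grouping error: flux vector lacks reaction(s): ",
           paste(miss, collapse = ", "))
    sum(fluxes[members])
  }, numeric(1))
}
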