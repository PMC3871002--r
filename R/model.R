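#' @title Network containers for the dopaminergic nerve cell model
#'
#' @description
#' The package represents a cell as a process network: metabolites (species,
#' including cofactor-like "currency" metabolites that may flow in and out of
#' the cell) and irreversible reactions with finite non-negative flux bounds
#' in uM/h. Reversible biochemistry is encoded as paired forward/backward
#' reactions, so every flux is >= 0 and every printed flux range is
#' one-sided. Boundary reactions connect the network to the environment:
#' input reactions only produce, output reactions only consume.
#'
#' @name dnfba-model
NULL

COMPARTMENTS <- c("cytosol", "mitochondrion", "vesicle", "extracellular",
                  "lysosome")
BOUNDARY_KINDS <- c("input", "output", "internal")
SPEED_TAGS <- c("default", "slow", "best_et_al")

#' Create a metabolite record
#'
#' @param id short unique token, e.g. `"DA_c"`.
#' @param name free-text name.
#' @param compartment one of cytosol, mitochondrion, vesicle, extracellular,
#'   lysosome.
#' @param is_currency TRUE for molecular units of currency (O2, H2O, NAD+,
#'   NADH, Fe3+, Fe2+, ADP+Pi, ATP) that are allowed to flow in and out of
#'   the cell within their bound ranges.
#' @return a one-row data.frame.
#' @export
metabolite <- function(id, name = id, compartment = "cytosol",
                       is_currency = FALSE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  compartment <- match.arg(compartment, COMPARTMENTS)
  data.frame(id = id, name = name, compartment = compartment,
             is_currency = isTRUE(is_currency), stringsAsFactors = FALSE)
}

#' Create a reaction record
#'
#' @param id short unique token.
#' @param stoichiometry named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound flux bounds in uM/h; `0 <= lb <= ub`,
#'   `upper_bound` may be `Inf`.
#' @param boundary_kind `"input"`, `"output"` or `"internal"`.
#' @param speed_tag bound-policy tag: `"default"` (0-100), `"slow"` (0-30)
#'   or `"best_et_al"` (reference flux +- 10%).
#' @param best_reference_flux reference flux in uM/h, required iff
#'   `speed_tag == "best_et_al"`.
#' @param groups character vector of functional group labels.
#' @param name free-text name.
#' @return a list of class `"dn_reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 100,
                     boundary_kind = "internal", speed_tag = "default",
                     best_reference_flux = NA_real_, groups = character(),
                     name = id) {
  boundary_kind <- match.arg(boundary_kind, BOUNDARY_KINDS)
  speed_tag <- match.arg(speed_tag, SPEED_TAGS)
  stopifnot(is.numeric(stoichiometry))
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 boundary_kind = boundary_kind, speed_tag = speed_tag,
                 best_reference_flux = as.numeric(best_reference_flux),
                 groups = as.character(groups)),
            class = "dn_reaction")
}

#' Assemble a cell model
#'
#' @param metabolites data.frame (rows from [metabolite()]) or list thereof.
#' @param reactions list of [reaction()] records.
#' @param provenance free text: `"deposited"`, `"curated-skeleton"` or
#'   `"synthetic"`.
#' @param validate run [validate_cell_model()] before returning.
#' @return object of class `"cell_model"`.
#' @export
cell_model <- function(metabolites, reactions, provenance = "synthetic",
                       validate = TRUE) {
  if (is.list(metabolites) && !is.data.frame(metabolites))
    metabolites <- do.call(rbind, metabolites)
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  reactions <- unname(reactions)
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      provenance = provenance),
                 class = "cell_model")
  if (validate) validate_cell_model(m)
  m
}

#' Validate the structural invariants of a cell model
#'
#' Checks id uniqueness, compartment membership, bound ordering
#' (`0 <= lb <= ub`), non-empty stoichiometry, sign conventions for boundary
#' reactions (inputs only produce, outputs only consume), resolution of every
#' metabolite reference, and the presence of at least one input and one
#' output reaction.
#'
#' @param model a `cell_model`.
#' @return the model, invisibly; stops with a model-integrity error
#'   otherwise.
#' @export
validate_cell_model <- function(model) {
  stopifnot(inherits(model, "cell_model"))
  met <- model$metabolites
  if (anyDuplicated(met$id))
    stop("model-integrity error: duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  bad <- setdiff(met$compartment, COMPARTMENTS)
  if (length(bad))
    stop("model-integrity error: unknown compartment(s): ",
         paste(bad, collapse = ", "))
  rid <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rid))
    stop("model-integrity error: duplicate reaction ids: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  for (r in model$reactions) {
    if (!is.finite(r$lower_bound) || r$lower_bound < 0)
      stop("model-integrity error: ", r$id, ": lower bound must be finite, >= 0")
    if (r$lower_bound > r$upper_bound)
      stop("model-integrity error: ", r$id, ": lower bound exceeds upper bound")
    st <- r$stoichiometry
    if (!length(st) || is.null(names(st)) || any(!nzchar(names(st))))
      stop("model-integrity error: ", r$id, ": empty or unnamed stoichiometry")
    unresolved <- setdiff(names(st), met$id)
    if (length(unresolved))
      stop("model-integrity error: ", r$id, ": unresolved metabolite(s): ",
           paste(unresolved, collapse = ", "))
    if (any(st == 0))
      stop("model-integrity error: ", r$id, ": zero stoichiometric coefficient")
    if (r$boundary_kind == "input" && any(st < 0))
      stop("model-integrity error: input reaction ", r$id,
           " has negative coefficients")
    if (r$boundary_kind == "output" && any(st > 0))
      stop("model-integrity error: output reaction ", r$id,
           " has positive coefficients")
    if (r$speed_tag == "best_et_al" && !is.finite(r$best_reference_flux))
      stop("policy error: ", r$id,
           ": speed tag 'best_et_al' requires a reference flux")
  }
  kinds <- vapply(model$reactions, `[[`, "", "boundary_kind")
  if (!any(kinds == "input") || !any(kinds == "output"))
    stop("model-integrity error: model needs at least one input and one ",
         "output reaction")
  invisible(model)
}

#' Build the stoichiometric matrix S
#'
#' Rows are metabolites (in model order), columns are reactions (in model
#' order); entry (i, j) is the signed coefficient of metabolite i in
#' reaction j, 0 when absent. The steady-state condition of every
#' flux-balance computation is `S %*% v == 0`.
#'
#' @param model a `cell_model`.
#' @return numeric matrix with dimnames (metabolite ids, reaction ids).
#' @export
build_stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "cell_model"))
  mids <- model$metabolites$id
  rids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    idx <- match(names(st), mids)
    if (anyNA(idx))
      stop("model-integrity error: unresolved metabolite(s) in ", rids[j],
           ": ", paste(names(st)[is.na(idx)], collapse = ", "))
    S[idx, j] <- st
  }
  S
}

#' @export
print.cell_model <- function(x, ...) {
  kinds <- vapply(x$reactions, `[[`, "", "boundary_kind")
  cat("cell_model (", x$provenance, "): ",
      nrow(x$metabolites), " metabolites, ", length(x$reactions),
      " reactions (", sum(kinds == "input"), " in / ",
      sum(kinds == "output"), " out)\n", sep = "")
  invisible(x)
}

# small accessors used throughout
#' @noRd
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")
#' @noRd
reaction_field <- function(model, field)
  vapply(model$reactions, function(r) as.numeric(r[[field]]), numeric(1))
#' @noRd
get_reaction <- function(model, id) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("unknown reaction id: ", id)
  model$reactions[[i]]
}
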