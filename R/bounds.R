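#' Flux-bound policy
#'
#' The model's bound conventions: reactions default to the range 0-100 uM/h;
#' reactions known to proceed slowly or rarely are capped at 30 uM/h;
#' reactions taken over from the kinetic dopamine-terminal model carry that
#' model's flux value as a reference and are constrained to +- 10% around
#' it. Because the full cell model contains additional consumers of
#' cytosolic dopamine, four O-methylation / homovanillic-acid synthesis
#' reactions must additionally have their lower bounds released to 0 for a
#' steady state to exist at all; those ids are the default
#' `zero_lb_overrides`.
#'
#' @param default_range numeric length-2, bounds for `speed_tag "default"`.
#' @param slow_max upper bound for `speed_tag "slow"`.
#' @param best_tolerance fractional half-width around the reference flux for
#'   `speed_tag "best_et_al"`; must be in `[0, 1)`.
#' @param zero_lb_overrides reaction ids whose lower bound is forced to 0
#'   after tag-based bounds are applied.
#' @return object of class `"bounds_policy"`.
#' @export
bounds_policy <- function(default_range = c(0, 100), slow_max = 30,
                          best_tolerance = 0.10,
                          zero_lb_overrides = c("OMSynthesis1", "OMSynthesis2",
                                                "HVASynthesis3",
                                                "HVASynthesis4")) {
  stopifnot(length(default_range) == 2, default_range[1] <= default_range[2],
            best_tolerance >= 0, best_tolerance < 1,
            slow_max <= default_range[2])
  structure(list(default_range = as.numeric(default_range),
                 slow_max = as.numeric(slow_max),
                 best_tolerance = as.numeric(best_tolerance),
                 zero_lb_overrides = as.character(zero_lb_overrides)),
            class = "bounds_policy")
}

#' Apply the bound policy to every reaction
#'
#' Sets each reaction's bounds from its `speed_tag` — default to
#' `default_range`, slow to `(0, slow_max)`, `best_et_al` with reference
#' `f` to `((1 - tol) f, (1 + tol) f)` — and then forces the lower bound of
#' every id in `zero_lb_overrides` to 0. All other reaction fields are left
#' unchanged, and applying the same policy twice is a no-op.
#'
#' @param model a `cell_model` whose reactions carry speed tags.
#' @param policy a [bounds_policy()].
#' @return the model with bounds rewritten.
#' @export
apply_bounds_policy <- function(model, policy = bounds_policy()) {
  stopifnot(inherits(model, "cell_model"), inherits(policy, "bounds_policy"))
  model$reactions <- lapply(model$reactions, function(r) {
    bnds <- switch(r$speed_tag,
      default = policy$default_range,
      slow = c(0, policy$slow_max),
      best_et_al = {
        f <- r$best_reference_flux
        if (!is.finite(f))
          stop("policy error: ", r$id,
               ": 'best_et_al' reaction without reference flux")
        c((1 - policy$best_tolerance) * f, (1 + policy$best_tolerance) * f)
      })
    r$lower_bound <- bnds[1]
    r$upper_bound <- bnds[2]
    if (r$id %in% policy$zero_lb_overrides) r$lower_bound <- 0
    r
  })
  validate_cell_model(model)
  model
}
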