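#' The curated skeleton model of the dopaminergic nerve cell
#'
#' Loads the packaged reconstruction of the dopaminergic neuron network and
#' applies the default bound policy. The skeleton is a documented
#' reconstruction, not the full deposited network: it covers dopamine
#' synthesis, metabolism and transport (including the four O-methylation /
#' homovanillic-acid reactions whose lower bounds the policy releases to
#' zero), MPTP import via the dopamine transporter with complex-I ROS
#' production, both apoptosis-initiation routes (Lewy-body-induced and
#' mitochondria-induced), the lysosomal, proteasomal and mitophagy
#' degradation routes, alpha-synuclein input, aggregation, DJ-1 inhibition
#' and extracellular export, ROS production and damage processes,
#' mitochondrial biogenesis and repair, and boundary reactions for the
#' molecular units of currency. Every canonical flux-group label is
#' populated and the network admits a steady state under the default
#' policy.
#'
#' @param policy bound policy applied after loading; `NULL` keeps the
#'   bounds stored in the table (they coincide with the default policy).
#' @return a validated `cell_model` with provenance `"curated-skeleton"`.
#' @export
make_skeleton_model <- function(policy = bounds_policy()) {
  path <- system.file("extdata", "dopaminergic_skeleton.tsv",
                      package = "dnfba", mustWork = TRUE)
  model <- read_reaction_table(path, provenance = "curated-skeleton")
  if (!is.null(policy)) model <- apply_bounds_policy(model, policy)
  model
}

#' Scan-input reaction ids of the skeleton experiments
#'
#' Maps experiment names to the skeleton's boundary input reactions swept
#' in the corresponding input-flux scan.
#'
#' @return named character vector.
#' @export
skeleton_scan_inputs <- function() {
  c(o2 = "O2in", atp = "ATPin", mptp = "MPTPin", asyn = "aSYNin",
    tyrosine = "TYRin")
}
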