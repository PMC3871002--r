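#' Specification for seeded random-network generation
#'
#' @param n_metabolites,n_reactions network size; `n_reactions` counts
#'   internal plus boundary reactions and must be at least
#'   `n_inputs + n_outputs + 1`.
#' @param density fraction of nonzero stoichiometric entries per internal
#'   reaction, in (0, 1].
#' @param n_inputs,n_outputs number of boundary input/output reactions.
#' @param bound_slack margin (uM/h) around the planted flux when deriving
#'   bounds; 0 pins every reaction to its planted flux.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_metabolites = 5, n_reactions = 8,
                           density = 0.5, n_inputs = 1, n_outputs = 1,
                           bound_slack = 1, seed = 1L) {
  stopifnot(n_reactions >= n_inputs + n_outputs + 1,
            density > 0, density <= 1, bound_slack >= 0,
            n_inputs >= 1, n_outputs >= 1)
  structure(list(n_metabolites = n_metabolites, n_reactions = n_reactions,
                 density = density, n_inputs = n_inputs,
                 n_outputs = n_outputs, bound_slack = bound_slack,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random feasible network with a planted flux
#'
#' Feasibility is guaranteed by construction rather than rejection
#' sampling: internal stoichiometry and a non-negative internal flux vector
#' are sampled first, then the requested boundary reactions are built so
#' that their planted fluxes absorb each metabolite's net imbalance exactly
#' (inputs feed net-consumed metabolites, outputs drain net-produced ones),
#' giving `S %*% v_star == 0` identically. Bounds are then
#' `lb = max(0, v* - slack)`, `ub = v* + slack`, so the planted vector is
#' always feasible and, with slack 0, is the only feasible point.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (a `cell_model`, provenance `"synthetic"`)
#'   and `v_star` (named planted flux vector).
#' @export
generate_random_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed, kind = "Mersenne-Twister")

  nm <- spec$n_metabolites
  n_int <- spec$n_reactions - spec$n_inputs - spec$n_outputs
  mids <- sprintf("M%02d", seq_len(nm))
  mets <- do.call(rbind, lapply(seq_len(nm), function(i)
    metabolite(mids[i], compartment = "cytosol",
               is_currency = i == nm && nm > 2)))

  reactions <- list()
  v_star <- numeric(0)
  Sint <- matrix(0, nm, n_int)
  for (j in seq_len(n_int)) {
    repeat {
      nz <- stats::runif(nm) < spec$density
      if (sum(nz) >= 2) break            # resample degenerate draws
    }
    coef <- numeric(nm)
    coef[nz] <- sample(c(-2, -1, 1, 2), sum(nz), replace = TRUE)
    if (all(coef[nz] > 0)) coef[which(nz)[1]] <- -coef[which(nz)[1]]
    if (all(coef[nz] < 0)) coef[which(nz)[sum(nz)]] <- -coef[which(nz)[sum(nz)]]
    Sint[, j] <- coef
    id <- sprintf("R%02d", j)
    reactions[[j]] <- reaction(id, stats::setNames(coef[nz], mids[nz]),
                               boundary_kind = "internal")
    # dyadic planted fluxes with integer coefficients keep every partial
    # sum exact, so S %*% v_star is bitwise zero whatever the summation order
    v_star[id] <- sample(seq(0.25, 10, by = 0.25), 1)
  }

  imbalance <- as.numeric(Sint %*% v_star)   # >0 net produced, <0 net consumed
  eps <- 1e-9
  produced <- which(imbalance > eps)
  consumed <- which(imbalance < -eps)
  # distribute drained metabolites over the requested output reactions and
  # fed metabolites over the inputs; spare boundary reactions get a token
  # metabolite at planted flux 0
  out_assign <- if (length(produced))
    split(produced, rep_len(seq_len(spec$n_outputs), length(produced)))
  else list()
  in_assign <- if (length(consumed))
    split(consumed, rep_len(seq_len(spec$n_inputs), length(consumed)))
  else list()
  for (k in seq_len(spec$n_outputs)) {
    id <- sprintf("OUT%02d", k)
    rows <- out_assign[[as.character(k)]] %||% integer(0)
    if (length(rows)) {
      st <- stats::setNames(-imbalance[rows], mids[rows])
      v_star[id] <- 1
    } else {
      st <- stats::setNames(-1, mids[nm])
      v_star[id] <- 0
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(id, st, boundary_kind = "output",
               groups = if (k == 1) "Apoptosis (LBs)" else character())
  }
  for (k in seq_len(spec$n_inputs)) {
    id <- sprintf("IN%02d", k)
    rows <- in_assign[[as.character(k)]] %||% integer(0)
    if (length(rows)) {
      st <- stats::setNames(-imbalance[rows], mids[rows])  # positive coefs
      v_star[id] <- 1
    } else {
      st <- stats::setNames(1, mids[1])
      v_star[id] <- 0
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(id, st, boundary_kind = "input")
  }

  for (i in seq_along(reactions)) {
    v <- v_star[[reactions[[i]]$id]]
    reactions[[i]]$lower_bound <- max(0, v - spec$bound_slack)
    reactions[[i]]$upper_bound <- v + spec$bound_slack
  }
  model <- cell_model(mets, reactions, provenance = "synthetic")
  list(model = model, v_star = v_star[reaction_ids(model)])
}

# save/restore the global RNG state so generators are pure functions
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a neuron-like test network with a constructed feasibility window
#'
#' A fixed mid-size topology (about 30 reactions) mimicking the cell
#' model's shape: currency metabolites with boundary exchange, a damage /
#' degradation / apoptosis core in which every degradation route (lysosome,
#' proteasome, mitophagy) and both apoptosis routes are tagged, a
#' degradation bypass that lets minimal-apoptosis solutions reach zero
#' apoptosis, and a designated input (`WINin`) whose sole consumer has
#' bounds `(window[1], window[2])`, so a step-1 pinned scan of `WINin`
#' recovers exactly that feasibility window. The seed only jitters the
#' upper bounds of non-critical wide reactions; the window and group
#' structure are deterministic.
#'
#' @param seed integer seed.
#' @param window numeric length-2, the constructed feasible range (uM/h)
#'   of the designated input.
#' @return list with `model`, `groups` (a `flux_groups`), `window`, and
#'   `scan_input` (the id `"WINin"`).
#' @export
generate_neuronlike_network <- function(seed = 1L, window = c(7, 19)) {
  stopifnot(length(window) == 2, window[1] >= 0, window[1] <= window[2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  wide <- function() round(stats::runif(1, 90, 110), 1)

  mets <- do.call(rbind, list(
    metabolite("W_c", "window substrate"),
    metabolite("Wp_c", "window product"),
    metabolite("SUB_c", "degradable substrate"),
    metabolite("DAM_c", "damaged material"),
    metabolite("DAMu_c", "ubiquitylated damaged material"),
    metabolite("AGGn_c", "aggregate"),
    metabolite("MITn_ok", "intact mitochondrion", "mitochondrion"),
    metabolite("MITn_dam", "defective mitochondrion", "mitochondrion"),
    metabolite("ROSn_c", "reactive oxygen species"),
    metabolite("ATPn_c", "ATP", is_currency = TRUE),
    metabolite("ADPn_c", "ADP + Pi", is_currency = TRUE),
    metabolite("O2n_c", "oxygen", is_currency = TRUE)))

  rx <- list(
    reaction("WINin", c(W_c = 1), 0, 100, "input"),
    reaction("WindowUse", c(W_c = -1, Wp_c = 1), window[1], window[2]),
    reaction("WPout", c(Wp_c = -1), 0, wide(), "output"),
    reaction("SUBin", c(SUB_c = 1), 0, wide(), "input"),
    reaction("O2n_in", c(O2n_c = 1), 0, wide(), "input"),
    reaction("O2n_out", c(O2n_c = -1), 0, wide(), "output"),
    reaction("ATPn_in", c(ATPn_c = 1), 0, wide(), "input"),
    reaction("ADPn_out", c(ADPn_c = -1), 0, wide(), "output"),
    reaction("RespirationN", c(O2n_c = -1, ADPn_c = -1, ATPn_c = 1), 0, 30),
    reaction("ROSGenDA", c(SUB_c = -1, ROSn_c = 1), 0, wide(),
             groups = "ROS production (DA)"),
    reaction("ROSGenCI", c(O2n_c = -1, ROSn_c = 1), 0, 30,
             groups = "ROS production (mitochondria, complex I)"),
    reaction("ROSGenCIII", c(O2n_c = -1, ROSn_c = 1), 0, wide(),
             groups = "ROS production (mitochondria, complex III)"),
    reaction("DamageProt", c(ROSn_c = -1, SUB_c = -1, DAM_c = 1), 0, wide(),
             groups = "ROS damage (protein)"),
    reaction("DamageMito", c(ROSn_c = -1, MITn_ok = -1, MITn_dam = 1), 0,
             wide(), groups = "ROS damage (mitochondria)"),
    reaction("LysoDeg", c(DAM_c = -1, ATPn_c = -1, ADPn_c = 1), 0, wide(),
             groups = "Degradation (lysosome)"),
    reaction("UbiqTag", c(DAM_c = -1, ATPn_c = -1, DAMu_c = 1, ADPn_c = 1),
             0, wide()),
    reaction("ProtDeg", c(DAMu_c = -1, ATPn_c = -1, ADPn_c = 1), 0, 30,
             groups = "Degradation (proteasome)"),
    reaction("MitophagyN", c(MITn_dam = -1, ATPn_c = -1, ADPn_c = 1), 0, 30,
             groups = "Degradation (mitophagy)"),
    reaction("BiogenesisN", c(ATPn_c = -1, MITn_ok = 1, ADPn_c = 1), 0,
             wide(), groups = "Biogenesis of mitochondria"),
    reaction("Aggregation", c(DAM_c = -1, AGGn_c = 1), 0, wide(),
             groups = "αSYN aggregation"),
    reaction("AggDeg", c(AGGn_c = -1, ATPn_c = -1, ADPn_c = 1), 0, wide(),
             groups = "Degradation (lysosome)"),
    reaction("ApoLB", c(AGGn_c = -1), 0, wide(), "output",
             groups = "Apoptosis (LBs)"),
    reaction("ApoMito", c(MITn_dam = -1), 0, wide(), "output",
             groups = "Apoptosis (mitochondria)"))
  model <- cell_model(mets, rx, provenance = "synthetic")
  list(model = model, groups = model_groups(model), window = window,
       scan_input = "WINin")
}

#' Hand-analyzable micro fixtures with closed-form optima
#'
#' A named set of tiny models used as exact oracles for the LP engine:
#' \describe{
#'   \item{chain}{input (0-10) -> A -> output (0-10); maximizing the output
#'     gives optimum 10 with every flux unique.}
#'   \item{diamond}{a pinned demand of 10 routed from A to B over two
#'     parallel branches each bounded (0, 10); any split is optimal, so
#'     both branches have the flux-variability range (0, 10).}
#'   \item{infeasible}{an input pinned to 5 feeding a metabolite with no
#'     outlet: no steady state exists.}
#'   \item{unbounded}{a two-reaction loop with missing (infinite) upper
#'     bounds; maximizing a loop flux is unbounded.}
#' }
#'
#' @return named list of `cell_model` objects with attribute fields
#'   documented above.
#' @export
micro_fixtures <- function() {
  A <- metabolite("A"); B <- metabolite("B")
  list(
    chain = cell_model(A, list(
      reaction("in", c(A = 1), 0, 10, "input"),
      reaction("out", c(A = -1), 0, 10, "output"))),
    diamond = cell_model(rbind(A, B), list(
      reaction("in", c(A = 1), 10, 10, "input"),
      reaction("b1", c(A = -1, B = 1), 0, 10),
      reaction("b2", c(A = -1, B = 1), 0, 10),
      reaction("out", c(B = -1), 10, 10, "output"))),
    infeasible = cell_model(rbind(A, B), list(
      reaction("in", c(A = 1), 5, 5, "input"),
      reaction("sink", c(B = -1), 0, 10, "output"))),
    unbounded = cell_model(rbind(A, B), list(
      reaction("in", c(A = 1), 0, 10, "input"),
      reaction("fwd", c(A = -1, B = 1), 0, Inf),
      reaction("bwd", c(B = -1, A = 1), 0, Inf),
      reaction("out", c(A = -1), 0, 10, "output"))))
}
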