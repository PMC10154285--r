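#' Simulation plan for stochastic simulation at stationarity
#'
#' Describes how endpoint samples are drawn from exact Gillespie (direct
#' method) trajectories.  The default sampling mode simulates `n_cells`
#' independent trajectories and records each at time
#' `burn_in + horizon`, matching the data type the method targets: one
#' measurement per cell at a single time point.  `"thinned_timepoints"`
#' instead records one long trajectory at `n_cells` times spaced
#' `horizon` apart after `burn_in`; samples are then autocorrelated, so
#' a warning is attached.
#'
#' @param n_cells number of samples (>= 1).
#' @param burn_in equilibration time before sampling; `NULL` lets each
#'   simulator default to 20 relaxation times (20 / min degradation
#'   rate).
#' @param horizon extra time before the endpoint (or spacing between
#'   thinned samples); `NULL` defaults to `burn_in / 10`.
#' @param sampling `"endpoint_per_cell"` or `"thinned_timepoints"`.
#' @param seed integer seed (`NULL` = leave RNG state alone).
#' @param state_cap safety cap on molecule counts to catch divergent
#'   models.
#' @return an object of class `simulation_plan`.
#' @export
simulation_plan <- function(n_cells, burn_in = NULL, horizon = NULL,
                            sampling = c("endpoint_per_cell", "thinned_timepoints"),
                            seed = NULL, state_cap = 1e6L) {
  sampling <- match.arg(sampling)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop_fanoreg("n_cells must be >= 1", "fanoreg_parameter_error")
  for (v in list(burn_in, horizon))
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop_fanoreg("burn_in and horizon must be positive", "fanoreg_parameter_error")
  structure(list(n_cells = as.integer(n_cells), burn_in = burn_in,
                 horizon = horizon, sampling = sampling, seed = seed,
                 state_cap = as.integer(state_cap)),
            class = "simulation_plan")
}

# resolve burn-in/horizon defaults and build the per-trajectory sample
# time layout; returns list(times, reps): `reps` independent trajectories
# each sampled at `times`
.plan_times <- function(plan, min_deg) {
  burn <- if (is.null(plan$burn_in)) 20 / min_deg else plan$burn_in
  hor <- if (is.null(plan$horizon)) burn / 10 else plan$horizon
  if (plan$sampling == "endpoint_per_cell") {
    list(times = burn + hor, reps = plan$n_cells, burn_in = burn, horizon = hor)
  } else {
    warning("thinned_timepoints samples are autocorrelated; treat VMR standard errors with care")
    list(times = burn + hor * seq_len(plan$n_cells), reps = 1L,
         burn_in = burn, horizon = hor)
  }
}

.apply_seed <- function(plan) {
  if (!is.null(plan$seed)) set.seed(plan$seed)
}

#' Simulate endpoint counts from a birth-death chain
#'
#' Exact SSA with birth propensity \eqn{f_{n+1}} and death propensity
#' \eqn{g_n n}; returns the state of each cell at the end of
#' `burn_in + horizon`.  Reproducible bit-for-bit given `plan$seed`.
#'
#' @param chain a [birth_death_chain()].
#' @param plan a [simulation_plan()].
#' @param init initial molecule count.
#' @return integer vector of `n_cells` endpoint counts.
#' @export
simulate_birth_death <- function(chain, plan, init = 0L) {
  stopifnot(inherits(chain, "birth_death_chain"), inherits(plan, "simulation_plan"))
  .apply_seed(plan)
  cap <- min(chain$n_max, plan$state_cap, 1e5L)
  nn <- seq_len(cap)
  fv <- .eval_rates(chain$f, nn)
  gv <- .eval_rates(chain$g, nn)
  if (any(!is.finite(fv)) || any(fv < 0) || any(!is.finite(gv)) || any(gv < 0))
    stop_fanoreg("invalid rates in chain", "fanoreg_invalid_model")
  gpos <- gv[gv > 0]
  tl <- .plan_times(plan, if (length(gpos)) min(gpos) else 1)
  out <- integer(tl$reps * length(tl$times))
  for (r in seq_len(tl$reps)) {
    out[((r - 1L) * length(tl$times) + 1L):(r * length(tl$times))] <-
      ssa_birth_death_traj(fv, gv, as.integer(init), tl$times)
  }
  out
}

#' Simulate endpoint states from a multi-gene one-step chain
#'
#' Exact SSA over all `2m` one-step reaction channels of a
#' [network_chain()], with propensities tabulated on the truncated box.
#' Birth transitions that would leave the box are suppressed; choose the
#' box generously and check the returned attribute `boundary_hits` (the
#' number of endpoint samples sitting on a leaky boundary state).
#'
#' @param net a [network_chain()].
#' @param plan a [simulation_plan()].
#' @param min_deg smallest per-molecule degradation rate used for the
#'   default burn-in; `NULL` probes the rate functions at the initial
#'   state.
#' @return integer matrix `n_cells x m` of endpoint counts.
#' @export
simulate_network <- function(net, plan, min_deg = NULL) {
  stopifnot(inherits(net, "network_chain"), inherits(plan, "simulation_plan"))
  .apply_seed(plan)
  pp <- .network_propensities(net)
  if (is.null(min_deg)) {
    probe <- vapply(seq_len(net$m), function(i) {
      s <- pmax(net$init, 1L)
      as.numeric(net$g[[i]](s))
    }, 0)
    probe <- probe[probe > 0]
    min_deg <- if (length(probe)) min(probe) else 1
  }
  tl <- .plan_times(plan, min_deg)
  nt <- length(tl$times)
  out <- matrix(0L, nrow = tl$reps * nt, ncol = net$m)
  for (r in seq_len(tl$reps)) {
    out[((r - 1L) * nt + 1L):(r * nt), ] <-
      ssa_network_traj(pp$birth, pp$death, pp$strides, net$init, net$box, tl$times)
  }
  leak_any <- Reduce(`+`, pp$leak)
  idx <- 1L + as.integer(out %*% pp$strides)
  hits <- sum(leak_any[idx] > 0)
  if (hits > 0)
    warning(sprintf("%d of %d samples sit on a leaky boundary state; enlarge the box",
                    hits, nrow(out)))
  attr(out, "boundary_hits") <- hits
  out
}

#' Multi-step gene-state cycle model
#'
#' The gene walks through `k` sequential states
#' \eqn{G_1 \to G_2 \to \dots \to G_k \to G_1 + M}, producing one mRNA
#' when the cycle completes; mRNA degrades at `deg_rate` per molecule.
#' With many stages the cycle time becomes nearly deterministic, and the
#' mRNA count concentrates: VMR < 1 arises with no autoregulation at
#' all, because the model is not one-step.
#'
#' @param k number of gene-state stages (>= 1).
#' @param stage_rate rate of each stage transition (1/time).
#' @param deg_rate per-molecule mRNA degradation rate (1/time).
#' @return an object of class `multistep_cycle_model`.
#' @export
multistep_cycle_model <- function(k, stage_rate, deg_rate) {
  if (!is.numeric(k) || k < 1 || stage_rate <= 0 || deg_rate <= 0)
    stop_fanoreg("need k >= 1 and positive rates", "fanoreg_invalid_model")
  structure(list(k = as.integer(k), stage_rate = stage_rate, deg_rate = deg_rate),
            class = "multistep_cycle_model")
}

#' Simulate mRNA endpoint counts from the multi-step cycle model
#'
#' @param model a [multistep_cycle_model()].
#' @param plan a [simulation_plan()].
#' @param init_m initial mRNA count (the stage starts at \eqn{G_1}).
#' @return integer vector of endpoint mRNA counts.
#' @examples
#' \donttest{
#' m <- multistep_cycle_model(k = 20, stage_rate = 20, deg_rate = 0.1)
#' x <- simulate_multistep_cycle(m, simulation_plan(500, seed = 1))
#' mean(x); var(x) / mean(x)   # mean ~ 10, VMR well below 1
#' }
#' @export
simulate_multistep_cycle <- function(model, plan, init_m = 0L) {
  stopifnot(inherits(model, "multistep_cycle_model"), inherits(plan, "simulation_plan"))
  .apply_seed(plan)
  tl <- .plan_times(plan, model$deg_rate)
  nt <- length(tl$times)
  out <- integer(tl$reps * nt)
  for (r in seq_len(tl$reps)) {
    out[((r - 1L) * nt + 1L):(r * nt)] <-
      ssa_multistep_traj(model$k, model$stage_rate, model$deg_rate,
                         as.integer(init_m), tl$times, plan$state_cap)
  }
  out
}

#' Telegraph (two-state bursting) model
#'
#' The gene switches between an inactive and an active state at rates
#' `k_on` (off -> on) and `k_off` (on -> off) and transcribes at
#' `rho_off` / `rho_on` accordingly; mRNA degrades at `deg` per
#' molecule.  Slow switching with `rho_off << rho_on` produces bursts
#' and VMR > 1 without any autoregulation (the expression level alone is
#' not Markovian).
#'
#' @param k_on,k_off gene-state switching rates (>= 0).
#' @param rho_on,rho_off transcription rates in the two states (>= 0).
#' @param deg per-molecule degradation rate (> 0).
#' @return an object of class `telegraph_model`.
#' @export
telegraph_model <- function(k_on, k_off, rho_on, rho_off = 0, deg = 1) {
  vals <- c(k_on, k_off, rho_on, rho_off, deg)
  if (any(!is.finite(vals)) || any(vals < 0) || deg <= 0)
    stop_fanoreg("telegraph rates must be >= 0 with deg > 0", "fanoreg_invalid_model")
  structure(list(k_on = k_on, k_off = k_off, rho_on = rho_on,
                 rho_off = rho_off, deg = deg),
            class = "telegraph_model")
}

#' Simulate mRNA endpoint counts from the telegraph model
#'
#' @param model a [telegraph_model()].
#' @param plan a [simulation_plan()].
#' @param init_state initial gene state (1 = active).
#' @param init_m initial mRNA count.
#' @return integer vector of endpoint mRNA counts.
#' @export
simulate_telegraph <- function(model, plan, init_state = 0L, init_m = 0L) {
  stopifnot(inherits(model, "telegraph_model"), inherits(plan, "simulation_plan"))
  .apply_seed(plan)
  tl <- .plan_times(plan, model$deg)
  nt <- length(tl$times)
  out <- integer(tl$reps * nt)
  for (r in seq_len(tl$reps)) {
    out[((r - 1L) * nt + 1L):(r * nt)] <-
      ssa_telegraph_traj(model$k_on, model$k_off, model$rho_on,
                         model$rho_off, model$deg,
                         as.integer(init_state), as.integer(init_m),
                         tl$times, plan$state_cap)
  }
  out
}

#' Closed-form Fano factor of the telegraph model (rho_off = 0)
#'
#' Used as an independent oracle for the simulator:
#' \eqn{1 + \rho_{on} k_{off} / ((k_{on}+k_{off})(k_{on}+k_{off}+\delta))}.
#'
#' @param model a [telegraph_model()] with `rho_off = 0`.
#' @return the stationary VMR.
#' @export
telegraph_fano <- function(model) {
  stopifnot(inherits(model, "telegraph_model"))
  if (model$rho_off != 0)
    stop_fanoreg("closed form implemented for rho_off = 0 only",
                 "fanoreg_parameter_error")
  ks <- model$k_on + model$k_off
  1 + model$rho_on * model$k_off / (ks * (ks + model$deg))
}
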