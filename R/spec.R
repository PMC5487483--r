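#' Balanced random network specification
#'
#' Parameters of the benchmark network: a sparsely connected
#' excitatory/inhibitory (Brunel-type) network of leaky integrate-and-fire
#' neurons with fixed in-degree `K`, driven by external Poisson input whose
#' rate is scaled by `eta`. Optionally all excitatory-to-excitatory
#' connections are plastic (pair-based STDP); all other connections are
#' static.
#'
#' The in-degree follows the convention `K = round(K_S * 11250)`; `K` may
#' also be given directly for small test networks. Neuron and synapse
#' constants default to standard balanced-random-network values
#' (`tau_m = 20` ms, `theta = 20` mV, `V_reset = 0` mV, `tau_ref = 2` ms,
#' `J_exc = 0.1` mV, `J_inh = -g * J_exc` with `g = 6`). The external drive
#' is a per-thread Poisson generator with base rate
#' `drive_rate_hz = theta / (J_ext * tau_m)` (the rate at which the mean
#' drive alone reaches threshold), scaled linearly by `eta`.
#'
#' @param N Total number of neurons.
#' @param exc_fraction Fraction of excitatory neurons (default 0.8); GIDs
#'   `1..round(exc_fraction * N)` are excitatory, the rest inhibitory.
#' @param K_S In-degree scale; `K = round(K_S * 11250)`.
#' @param K In-degree given directly (overrides `K_S`).
#' @param J_exc,J_inh,J_ext Synaptic weights in mV (delta-current amplitude);
#'   `J_inh` must be negative or zero.
#' @param delay_ms Synaptic transmission delay in ms; must be a positive
#'   multiple of the resolution `h` and equal to the communication interval.
#' @param eta Scale factor of the external Poisson drive (>= 0).
#' @param drive_rate_hz Base rate of the external Poisson drive per neuron
#'   (spikes/s), multiplied by `eta`.
#' @param dc_mv Constant (DC) input added every h-step, in mV; mainly for
#'   closed-form tests of the neuron model.
#' @param plastic_ee If `TRUE`, excitatory-to-excitatory synapses use STDP.
#' @param stdp_params List overriding any of `lambda`, `alpha`, `mu`,
#'   `tau_plus`, `tau_minus`, `w_max`, `w_init` (see [stdp_on_pre_delivery()]).
#' @param tau_m,theta,v_reset,tau_ref_ms Leaky integrate-and-fire constants.
#' @param connectivity `"fixed_indegree"` (random, the default) or `"ring"`
#'   (each neuron listens to its predecessor; deterministic test topology).
#' @param autapses,multapses Allow self-connections / repeated connections
#'   when sampling sources (defaults `FALSE` / `TRUE`).
#' @param seed Master seed; every random stream of a run derives from it.
#' @return An object of class `dryspike_spec`.
#' @examples
#' network_spec(N = 1000, K = 100, eta = 1.5, seed = 42)
#' @export
network_spec <- function(N,
                         exc_fraction = 0.8,
                         K_S = NULL,
                         K = NULL,
                         J_exc = 0.1,
                         J_inh = -6 * J_exc,
                         J_ext = J_exc,
                         delay_ms = 1.5,
                         eta = 1.0,
                         drive_rate_hz = theta / (J_ext * tau_m / 1000),
                         dc_mv = 0,
                         plastic_ee = FALSE,
                         stdp_params = list(),
                         tau_m = 20,
                         theta = 20,
                         v_reset = 0,
                         tau_ref_ms = 2,
                         connectivity = c("fixed_indegree", "ring"),
                         autapses = FALSE,
                         multapses = TRUE,
                         seed = 1) {
  connectivity <- match.arg(connectivity)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  if (exc_fraction < 0 || exc_fraction > 1) {
    stop("exc_fraction must lie in [0, 1]")
  }
  N_exc <- as.integer(round(exc_fraction * N))
  if (connectivity == "ring") {
    K <- 1L
  } else {
    if (is.null(K)) {
      if (is.null(K_S)) stop("either K_S or K must be given")
      K <- as.integer(round(K_S * 11250))
    } else {
      K <- as.integer(K)
    }
    if (K < 0L) stop("K must be non-negative")
    if (K > N - 1L) {
      stop(sprintf("infeasible in-degree: K = %d exceeds N - 1 = %d", K, N - 1L))
    }
  }
  K_exc <- as.integer(round(exc_fraction * K))
  K_inh <- K - K_exc
  if (connectivity == "fixed_indegree") {
    if (K_exc > 0L && N_exc < (if (autapses) 1L else 2L)) {
      stop("too few excitatory neurons to sample excitatory sources")
    }
    if (K_inh > 0L && (N - N_exc) < 1L) {
      stop("too few inhibitory neurons to sample inhibitory sources")
    }
    if (!multapses) {
      if (K_exc > N_exc - (!autapses)) stop("K_exc too large without multapses")
      if (K_inh > (N - N_exc)) stop("K_inh too large without multapses")
    }
  }
  if (J_inh > 0) stop("J_inh must be negative or zero (sign convention)")
  if (eta < 0) stop("eta must be non-negative")
  if (drive_rate_hz < 0) stop("drive_rate_hz must be non-negative")
  if (delay_ms <= 0) stop("delay_ms must be positive")
  stdp <- utils::modifyList(
    list(lambda = 0.01, alpha = 1.1, mu = 0.4, tau_plus = 20, tau_minus = 20,
         w_max = 2 * J_exc, w_init = J_exc),
    stdp_params)
  structure(list(
    N = N, exc_fraction = exc_fraction, N_exc = N_exc, K = K,
    K_exc = K_exc, K_inh = K_inh, J_exc = J_exc, J_inh = J_inh,
    J_ext = J_ext, delay_ms = delay_ms, eta = eta,
    drive_rate_hz = drive_rate_hz, dc_mv = dc_mv,
    plastic_ee = isTRUE(plastic_ee), stdp = stdp,
    tau_m = tau_m, theta = theta, v_reset = v_reset,
    tau_ref_ms = tau_ref_ms, connectivity = connectivity,
    autapses = isTRUE(autapses), multapses = isTRUE(multapses),
    seed = seed), class = "dryspike_spec")
}

#' @export
print.dryspike_spec <- function(x, ...) {
  cat(sprintf(
    "<network spec> N = %d (%d exc / %d inh), K = %d, %s%s\n  J = (%.3g, %.3g, %.3g) mV, delay %.3g ms, eta %.3g, drive %.4g Hz, seed %s\n",
    x$N, x$N_exc, x$N - x$N_exc, x$K, x$connectivity,
    if (x$plastic_ee) " + STDP (e->e)" else "",
    x$J_exc, x$J_inh, x$J_ext, x$delay_ms, x$eta, x$drive_rate_hz,
    format(x$seed)))
  invisible(x)
}

#' Kernel configuration
#'
#' Settings of the simulation kernel: the integration resolution `h`, the
#' communication interval `min_delay` (spikes are exchanged once per
#' interval; one simulation cycle spans `H = min_delay / h` h-steps), the
#' total simulated time, the machine [topology()], and (static dry-run mode
#' only) the target rate of the fake spikes.
#'
#' @param topology A [topology()].
#' @param sim_time_ms Total biological time to simulate (ms).
#' @param h Resolution of the neuron update in ms (default 0.1).
#' @param min_delay_ms Communication interval in ms (default 1.5); must be a
#'   positive integer multiple of `h` and equal the minimum synaptic delay of
#'   the network spec.
#' @param static_target_rate Target rate `F` (Hz) of fake spikes in
#'   `dry_static` mode. Any value > 0 selects static filling; 0 selects the
#'   dynamic mode. Must be 0 unless the topology mode is `dry_static`.
#' @param seed Optional seed overriding the network spec's master seed.
#' @return An object of class `dryspike_config`.
#' @examples
#' kernel_config(topology(8, 2, "dry_static"), sim_time_ms = 1000,
#'               static_target_rate = 7)
#' @export
kernel_config <- function(topology, sim_time_ms, h = 0.1, min_delay_ms = 1.5,
                          static_target_rate = 0, seed = NULL) {
  if (!inherits(topology, "dryspike_topology")) {
    stop("topology must be created with topology()")
  }
  if (h <= 0) stop("h must be positive")
  H <- min_delay_ms / h
  if (abs(H - round(H)) > 1e-9 || H < 1) {
    stop(sprintf("min_delay (%g ms) must be a positive integer multiple of h (%g ms)",
                 min_delay_ms, h))
  }
  if (sim_time_ms < 0) stop("sim_time_ms must be non-negative")
  if (static_target_rate < 0) stop("static_target_rate must be non-negative")
  if (static_target_rate > 0 && topology$mode == "dry_dynamic") {
    stop("conflict: static_target_rate > 0 selects static filling, but mode is dry_dynamic")
  }
  if (static_target_rate == 0 && topology$mode == "dry_static") {
    stop("dry_static mode requires static_target_rate > 0")
  }
  structure(list(topology = topology, sim_time_ms = sim_time_ms, h = h,
                 min_delay_ms = min_delay_ms, H = as.integer(round(H)),
                 static_target_rate = static_target_rate, seed = seed),
            class = "dryspike_config")
}

#' @export
print.dryspike_config <- function(x, ...) {
  cat(sprintf("<kernel config> h = %g ms, min_delay = %g ms (H = %d), sim_time = %g ms\n",
              x$h, x$min_delay_ms, x$H, x$sim_time_ms))
  print(x$topology)
  if (x$topology$mode == "dry_static") {
    cat(sprintf("  static target rate F = %g Hz\n", x$static_target_rate))
  }
  invisible(x)
}

# Resolve spec + config into the flat parameter list the C++ kernel expects.
kernel_params <- function(spec, config) {
  h <- config$h
  delay_steps <- spec$delay_ms / h
  if (abs(delay_steps - round(delay_steps)) > 1e-9) {
    stop(sprintf("delay (%g ms) must be an integer multiple of h (%g ms)",
                 spec$delay_ms, h))
  }
  # all synapses share one delay, so min_delay must equal it exactly
  if (abs(spec$delay_ms - config$min_delay_ms) > 1e-9) {
    stop(sprintf(
      "min_delay (%g ms) must equal the minimum synaptic delay (%g ms)",
      config$min_delay_ms, spec$delay_ms))
  }
  t_ref_steps <- spec$tau_ref_ms / h
  if (abs(t_ref_steps - round(t_ref_steps)) > 1e-9) {
    stop(sprintf("tau_ref (%g ms) must be an integer multiple of h (%g ms)",
                 spec$tau_ref_ms, h))
  }
  seed <- if (!is.null(config$seed)) config$seed else spec$seed
  list(N = spec$N, N_exc = spec$N_exc, K_exc = spec$K_exc,
       K_inh = spec$K_inh, H = config$H,
       delay_steps = as.integer(round(delay_steps)), h = h,
       J_exc = spec$J_exc, J_inh = spec$J_inh, J_ext = spec$J_ext,
       dc_mv = spec$dc_mv, eta = spec$eta,
       drive_rate_hz = spec$drive_rate_hz, plastic_ee = spec$plastic_ee,
       connectivity = spec$connectivity, autapses = spec$autapses,
       multapses = spec$multapses, tau_m = spec$tau_m, theta = spec$theta,
       v_reset = spec$v_reset,
       t_ref_steps = as.integer(round(t_ref_steps)),
       stdp = spec$stdp, seed = as.numeric(seed))
}
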