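#' Deterministic random stream
#'
#' Creates one of the package's deterministic random streams (mt19937_64
#' seeded from a splitmix64 mix of `seed` and `key`). The same streams drive
#' the C++ kernel, keyed by virtual process, which is what makes the merged
#' spike record of the emulated real mode invariant to how `M * T` is
#' factorised.
#'
#' @param seed Master seed (non-negative integer).
#' @param key Stream key; virtual-process ids key the per-VP streams.
#' @return An external pointer of class `dryspike_rng`.
#' @examples
#' r <- rng_stream(1, key = 0)
#' rng_poisson(r, lambda = 0.5, n = 5)
#' @export
rng_stream <- function(seed, key = 0) {
  structure(.rng_stream(as.numeric(seed), as.numeric(key)),
            class = "dryspike_rng")
}

#' @rdname rng_stream
#' @param rng A [rng_stream()].
#' @param lambda Poisson mean per draw.
#' @param n Number of draws.
#' @export
rng_poisson <- function(rng, lambda, n) {
  if (lambda < 0) stop("lambda must be non-negative")
  .rng_poisson(rng, lambda, as.integer(n))
}

#' @rdname rng_stream
#' @param bounds Vector of exclusive upper bounds; one uniform draw in
#'   `[0, bounds[i])` is returned per element.
#' @export
rng_bounded <- function(rng, bounds) {
  if (any(bounds < 1)) stop("bounds must be >= 1")
  .rng_bounded(rng, as.integer(bounds))
}

#' @rdname rng_stream
#' @export
rng_unif <- function(rng, n) .rng_unif(rng, as.integer(n))

#' Leaky integrate-and-fire state
#'
#' State container for the stand-alone neuron update: membrane potential,
#' refractory counter, the input ring (one accumulated synaptic amplitude
#' per future h-step) and the membrane parameters.
#'
#' @param params List with `tau_m`, `theta`, `v_reset`, `tau_ref_ms`, `h`
#'   (ms / mV as in [network_spec()]). `tau_ref_ms / h` must be an integer.
#' @param ring_length Length of the input ring (must cover the maximum
#'   synaptic delay in steps).
#' @param V_m Initial membrane potential (default: `v_reset`).
#' @return A list of class `dryspike_lif`.
#' @export
lif_state <- function(params = list(), ring_length = 15, V_m = NULL) {
  p <- utils::modifyList(
    list(tau_m = 20, theta = 20, v_reset = 0, tau_ref_ms = 2, h = 0.1),
    params)
  t_ref <- p$tau_ref_ms / p$h
  if (abs(t_ref - round(t_ref)) > 1e-9) {
    stop("configuration error: tau_ref must be an integer multiple of h")
  }
  structure(list(V_m = if (is.null(V_m)) p$v_reset else V_m,
                 refractory_steps_left = 0L,
                 input_ring = numeric(ring_length),
                 params = p),
            class = "dryspike_lif")
}

#' Update one neuron over the h-steps of a cycle
#'
#' Exact exponential-decay propagation per h-step with delta-current input
#' lumped at the step boundary: `V <- V * exp(-h / tau_m) + ring[s] + drive[s]`.
#' On `V >= theta` the step offset is recorded, `V` is reset and the neuron
#' is refractory for `tau_ref / h` steps, during which the membrane is
#' clamped and inputs are discarded. Consumed ring slots are zeroed.
#'
#' @param state A [lif_state()].
#' @param n_steps Number of h-steps to advance (the cycle length `H`).
#' @param drive External input amplitude per step (scalar or length
#'   `n_steps`), e.g. from [poisson_drive()].
#' @return The updated state, with the emitted spike step offsets (0-based,
#'   in `[0, n_steps)`) in `$spike_offsets`.
#' @examples
#' st <- lif_state()
#' st$input_ring[3] <- 25  # suprathreshold kick at step 2
#' update_neuron(st, 15, drive = 0)$spike_offsets
#' @export
update_neuron <- function(state, n_steps, drive = 0) {
  if (!inherits(state, "dryspike_lif")) stop("state must be a lif_state()")
  n_steps <- as.integer(n_steps)
  if (length(state$input_ring) < n_steps) {
    stop("input_ring shorter than n_steps")
  }
  drive <- rep_len(as.numeric(drive), n_steps)
  p <- state$params
  res <- .lif_update(state$V_m, state$refractory_steps_left,
                     state$input_ring[seq_len(n_steps)], drive,
                     p$tau_m, p$theta, p$v_reset,
                     as.integer(round(p$tau_ref_ms / p$h)), p$h)
  state$V_m <- res$V_m
  state$refractory_steps_left <- res$refractory_steps_left
  state$input_ring[seq_len(n_steps)] <- res$input_ring
  state$spike_offsets <- res$spike_offsets
  state
}

#' External Poisson drive for one cycle
#'
#' Per-h-step spike counts of the external Poisson generator, drawn from the
#' given stream and multiplied by the drive weight. The per-step mean is
#' `eta * rate_hz * h / 1000`; `eta` scales the rate linearly.
#'
#' @param rate_hz Base drive rate in spikes/s (must be >= 0).
#' @param n_steps Number of h-steps.
#' @param rng A [rng_stream()] (in the kernel: the thread's VP stream).
#' @param h Resolution in ms.
#' @param eta Linear scale factor on the rate.
#' @param weight Drive weight multiplying each spike count (mV).
#' @return Numeric vector of per-step input amplitudes.
#' @export
poisson_drive <- function(rate_hz, n_steps, rng, h = 0.1, eta = 1,
                          weight = 1) {
  if (rate_hz < 0) stop("rate_hz must be non-negative")
  if (eta < 0) stop("eta must be non-negative")
  rng_poisson(rng, eta * rate_hz * h / 1000, n_steps) * weight
}

#' Delivery-time STDP update of a plastic synapse
#'
#' Applies the pair-based, all-to-all STDP update that the kernel performs
#' when a presynaptic spike is delivered at `pre_time`. The target's archived
#' post-spike times in `(last_update_time, pre_time]` are replayed: each
#' applies potentiation `dw+ = lambda * w_max^(1-mu) * w^mu * Kplus(t_post)`
#' with the presynaptic trace `Kplus` decaying with `tau_plus`. The spike is
#' delivered with the post-potentiation weight; depression
#' `dw- = -lambda * alpha * w * Kminus(pre_time)` then uses the decayed sum
#' of all archived posts before `pre_time` (`tau_minus`). The weight is
#' clipped to `[0, w_max]`. Simultaneous pre/post pairings contribute
#' nothing. `mu = 0` gives additive, `mu = 1` multiplicative weight
#' dependence (power-law scheme).
#'
#' @param syn List with `weight`, `Kplus` (presynaptic trace, initially 0),
#'   `last_update_time` (initially `-Inf`) and `params` (list with `lambda`,
#'   `alpha`, `mu`, `tau_plus`, `tau_minus`, `w_max`).
#' @param pre_time Arrival time of the presynaptic spike at the synapse (ms;
#'   emission time plus delay). Must be `>= syn$last_update_time`.
#' @param archive Ascending post-synaptic spike times of the target (ms).
#' @return The updated synapse, with `$delivered_weight` set to the weight
#'   the spike was delivered with.
#' @export
stdp_on_pre_delivery <- function(syn, pre_time, archive = numeric(0)) {
  if (pre_time < syn$last_update_time) {
    stop("out-of-order presynaptic spike: pre_time < last_update_time")
  }
  if (is.unsorted(archive)) stop("archive times must be ascending")
  p <- syn$params
  res <- .stdp_apply_pre(syn$weight, syn$Kplus, syn$last_update_time,
                         pre_time, as.numeric(archive),
                         p$lambda, p$alpha, p$mu, p$tau_plus, p$tau_minus,
                         p$w_max)
  syn$weight <- res$weight
  syn$Kplus <- res$Kplus
  syn$last_update_time <- res$last_update_time
  syn$delivered_weight <- res$delivered_weight
  syn
}

#' @rdname stdp_on_pre_delivery
#' @param weight Initial weight.
#' @param params STDP parameter overrides (see above).
#' @export
stdp_synapse <- function(weight, params = list()) {
  p <- utils::modifyList(
    list(lambda = 0.01, alpha = 1.1, mu = 0.4, tau_plus = 20,
         tau_minus = 20, w_max = 2 * weight),
    params)
  list(weight = weight, Kplus = 0, last_update_time = -Inf, params = p)
}
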