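# Independent oracles used across the suite. They deliberately avoid the
# package's delivery / STDP code paths: brute-force replays and per-step
# integrators against which the event-driven kernel is checked.

# Closed-form LIF inter-spike interval (in steps) under constant per-step
# drive A: V_{n+1} = V_n * gamma + A with gamma = exp(-h / tau_m).
lif_dc_isi_steps <- function(A, tau_m = 20, theta = 20, v_reset = 0,
                             tau_ref_ms = 2, h = 0.1) {
  gamma <- exp(-h / tau_m)
  v_inf <- A / (1 - gamma)
  stopifnot(v_inf > theta) # suprathreshold drive required
  # smallest n with v_inf + (v_reset - v_inf) * gamma^n >= theta
  n <- ceiling(log((v_inf - v_reset) / (v_inf - theta)) / (h / tau_m))
  # the >= comparison can make the exact boundary step spike one early
  while (v_inf + (v_reset - v_inf) * gamma^(n - 1) >= theta) n <- n - 1
  as.integer(round(tau_ref_ms / h)) + n
}

# First spike of a DC-driven LIF started at V = v_reset: number of update
# steps until the first threshold crossing (the spike lands at step index
# n - 1, 0-based).
lif_dc_first_steps <- function(A, tau_m = 20, theta = 20, v_reset = 0,
                               h = 0.1) {
  gamma <- exp(-h / tau_m)
  v_inf <- A / (1 - gamma)
  n <- ceiling(log((v_inf - v_reset) / (v_inf - theta)) / (h / tau_m))
  while (v_inf + (v_reset - v_inf) * gamma^(n - 1) >= theta) n <- n - 1
  as.integer(n)
}

# Spike count of a DC-driven LIF over n_steps, from the closed forms above.
lif_dc_count <- function(A, n_steps, ...) {
  first <- lif_dc_first_steps(A, ...)
  isi <- lif_dc_isi_steps(A, ...)
  if (first > n_steps) return(0L)
  as.integer((n_steps - first) %/% isi + 1L)
}

# Time-driven STDP trace integrator: advances exponential traces on a fixed
# grid and processes pre/post events in time order. Convention matches the
# delivery-time scheme: a post potentiates with the pre-trace before any
# simultaneous pre increments it; a pre depresses with the post-trace before
# any simultaneous post increments it.
stdp_time_driven <- function(pre_times, post_times, w0, pars, dt = 0.05) {
  lam <- pars$lambda; alpha <- pars$alpha; mu <- pars$mu
  tp <- pars$tau_plus; tm <- pars$tau_minus; wmax <- pars$w_max
  events <- rbind(
    if (length(pre_times)) data.frame(t = pre_times, kind = "pre"),
    if (length(post_times)) data.frame(t = post_times, kind = "post"))
  events <- events[order(events$t), , drop = FALSE]
  kplus <- 0; kminus <- 0; t_now <- 0; w <- w0
  for (t_ev in unique(events$t)) {
    kplus <- kplus * exp(-(t_ev - t_now) / tp)
    kminus <- kminus * exp(-(t_ev - t_now) / tm)
    t_now <- t_ev
    same_t <- events$t == t_ev
    # use start-of-instant traces for every event at this time, then add
    # the increments (excludes dt == 0 pairings)
    kp_base <- kplus; km_base <- kminus
    # within one instant, potentiation precedes depression (the delivery-time
    # scheme replays the archive before applying the pre's depression)
    for (j in which(same_t & events$kind == "post")) {
      w <- w + lam * wmax^(1 - mu) * w^mu * kp_base
      if (w > wmax) w <- wmax
    }
    for (j in which(same_t & events$kind == "pre")) {
      w <- w - lam * alpha * w * km_base
      if (w < 0) w <- 0
    }
    kplus <- kp_base + sum(same_t & events$kind == "pre")
    kminus <- km_base + sum(same_t & events$kind == "post")
  }
  w
}

# Event-driven counterpart through the package surface: one synapse, pres
# delivered in order against the full post archive.
stdp_event_driven <- function(pre_times, post_times, w0, pars) {
  syn <- stdp_synapse(w0, pars)
  for (tp in sort(pre_times)) {
    syn <- stdp_on_pre_delivery(syn, tp, sort(post_times))
  }
  syn$weight
}

# Brute-force replay of spike routing: given the full connection table and
# the emitted spikes, compute every synaptic event (target, arrival step)
# directly from the adjacency, bypassing buffers and sparse tables.
replay_events <- function(conns, spikes_gid, spikes_step, delay_steps) {
  idx <- split(seq_len(nrow(conns)), conns$source)
  out <- list()
  for (i in seq_along(spikes_gid)) {
    g <- as.character(spikes_gid[i])
    rows <- idx[[g]]
    if (is.null(rows)) next
    out[[length(out) + 1L]] <- data.frame(
      source = spikes_gid[i],
      target = conns$target[rows],
      arrival_step = spikes_step[i] + delay_steps)
  }
  if (!length(out)) {
    return(data.frame(source = integer(0), target = integer(0),
                      arrival_step = numeric(0)))
  }
  do.call(rbind, out)
}

sort_events <- function(df) {
  df <- df[order(df$arrival_step, df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Small driven network used by several tests.
small_spec <- function(N = 80, K = 8, eta = 1.3, seed = 11, ...) {
  network_spec(N = N, K = K, eta = eta, seed = seed, ...)
}
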