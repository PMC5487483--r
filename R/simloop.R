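#' Run a simulation
#'
#' Executes `ceiling(sim_time / min_delay)` simulation cycles in
#' deliver -> update -> gather order. The delivery step reads the global
#' spike buffer produced by the previous cycle's gather and routes the
#' spikes through the per-thread sparse tables to the local target synapses
#' (updating plastic synapses at delivery time); the update step advances
#' all local neurons in h-steps, staging emitted spikes in the spike
#' register; the gather step produces the next global buffer by emulated
#' allgather (real mode) or fake-spike generation (dry modes). Deterministic
#' for a fixed seed and topology.
#'
#' @param spec A [network_spec()].
#' @param config A [kernel_config()]; its topology selects the mode.
#' @param net Optional pre-built [build_local_network()] network (must match
#'   `spec`/`config`); built on the fly otherwise.
#' @param record_events Keep a per-event delivery log (testing; small nets).
#' @param record_buffer Also record the content of every gathered global
#'   buffer as `$buffer_spikes` (in the dry modes this is the fake-spike
#'   record; in dynamic mode its rank-0 section is the real local spikes),
#'   plus the last gathered buffer itself as `$final_buffer`.
#' @param validate_buffers Decode and check every gathered buffer: part
#'   locality in all modes, and in dynamic mode the per-part count identity
#'   between rank 0 and every fake rank. Results in `$metrics$buffer_checks`.
#' @return An object of class `dryspike_run`: list with `spikes` (data frame
#'   `gid`, `time_ms` of the spikes of all built ranks' neurons, sorted by
#'   time then GID), `metrics`, `spec`, `config`, `net` and optionally
#'   `buffer_spikes`, `events`.
#' @examples
#' spec <- network_spec(N = 60, K = 6, eta = 1.2, seed = 7)
#' run <- run_simulation(spec, kernel_config(topology(2, 2, "dry_dynamic"),
#'                                           sim_time_ms = 30))
#' head(run$spikes)
#' @export
run_simulation <- function(spec, config, net = NULL, record_events = FALSE,
                           record_buffer = FALSE, validate_buffers = FALSE) {
  topo <- config$topology
  mode <- topo$mode
  H <- config$H
  T <- topo$T
  M <- topo$M
  if (is.null(net)) {
    net <- build_local_network(spec, topo, config = config,
                               record_events = record_events)
  } else if (.net_info(net$ptr)$cycle != 0) {
    stop("state error: network has already been simulated; rebuild it")
  }
  ranks <- net$ranks
  if (mode != "real_emulated" && !identical(ranks, 0L)) {
    stop("dry modes run on exactly one physical process playing rank 0")
  }
  n_cycles <- as.integer(ceiling(config$sim_time_ms / config$min_delay_ms))
  seed <- if (!is.null(config$seed)) config$seed else spec$seed
  dry_rng <- rng_stream(seed, DRY_STREAM_KEY)
  static_state <- if (mode == "dry_static") {
    static_fill_state(spec$N, config$static_target_rate, config$min_delay_ms,
                      topo, H)
  }

  capacity <- H * T          # empty high-water mark: markers only
  max_hist <- 0L
  gbuf <- NULL
  sp_gid <- vector("list", n_cycles)
  sp_time <- vector("list", n_cycles)
  buf_rec <- if (record_buffer) vector("list", n_cycles)
  cap_trace <- integer(n_cycles)
  count_trace <- matrix(0L, nrow = n_cycles, ncol = M)
  events <- 0
  fake_total <- 0
  n_dropped <- 0
  locality_ok <- TRUE
  identity_ok <- TRUE
  t_deliver <- t_update <- t_gather <- 0

  for (cyc in seq_len(n_cycles)) {
    c0 <- cyc - 1L  # 0-based cycle index
    t0 <- proc.time()[["elapsed"]]
    if (!is.null(gbuf)) {
      for (r in ranks) {
        events <- events + .net_deliver(net$ptr, r, gbuf, capacity,
                                        validate_buffers)
      }
    }
    t1 <- proc.time()[["elapsed"]]
    regs <- lapply(ranks, function(r) .net_update(net$ptr, r))
    t2 <- proc.time()[["elapsed"]]

    all_gid <- unlist(lapply(regs, function(m) m[, 1L]), use.names = FALSE)
    all_step <- unlist(lapply(regs, function(m) m[, 2L]), use.names = FALSE)
    sp_gid[[cyc]] <- all_gid
    sp_time[[cyc]] <- (c0 * H + all_step + 1) * config$h

    if (mode == "real_emulated") {
      counts <- vapply(regs, nrow, 0L)
      max_hist <- max(max_hist, counts)
      capacity <- grow_buffer(capacity, max_hist, H, T)
      sections <- lapply(seq_along(ranks), function(i) {
        m <- regs[[i]]
        encode_section(m[, 1L], m[, 2L], thread_of_gid(m[, 1L], topo),
                       H, T, capacity)
      })
      gbuf <- allgather_emulated(sections)
      count_trace[cyc, ] <- counts
    } else if (mode == "dry_static") {
      # rank-0 real spikes are ignored downstream; fake counts size the
      # buffer. The accumulator counts are deterministic, so they are known
      # before drawing and the capacity can grow first.
      P <- M * H * T
      n_part <- diff(floor(static_state$carry + static_state$q * (0:P)))
      per_rank_planned <- vapply(split(n_part, rep(seq_len(M), each = H * T)),
                                 sum, 0)
      max_hist <- max(max_hist, per_rank_planned)
      capacity <- grow_buffer(capacity, max_hist, H, T)
      fs <- fill_static(static_state, topo, H, spec$N, capacity, dry_rng)
      per_rank <- vapply(split(fs$counts, rep(seq_len(M), each = H * T)),
                         sum, 0L)
      static_state <- fs$state
      gbuf <- fs$buffer
      fake_total <- fake_total + sum(per_rank)
      n_dropped <- n_dropped + fs$n_dropped
      count_trace[cyc, ] <- per_rank
    } else { # dry_dynamic
      n0 <- nrow(regs[[1L]])
      max_hist <- max(max_hist, n0)
      capacity <- grow_buffer(capacity, max_hist, H, T)
      m <- regs[[1L]]
      sec0 <- encode_section(m[, 1L], m[, 2L], thread_of_gid(m[, 1L], topo),
                             H, T, capacity)
      fd <- fill_dynamic(sec0, topo, H, spec$N, dry_rng)
      gbuf <- fd$buffer
      fake_total <- fake_total + n0 * (M - 1L)
      n_dropped <- n_dropped + fd$n_dropped
      count_trace[cyc, ] <- n0
    }
    cap_trace[cyc] <- capacity
    t3 <- proc.time()[["elapsed"]]

    if (validate_buffers || record_buffer) {
      dec <- decode_buffer(gbuf, M, H, T)
      if (validate_buffers) {
        locality_ok <- locality_ok && buffer_locality_ok(dec, topo)
        if (mode == "dry_dynamic" && M > 1L) {
          pc <- vapply(seq_len(M) - 1L, function(r) {
            d <- dec[dec$rank == r, ]
            tabulate(d$step * T + d$thread + 1L, nbins = H * T)
          }, integer(H * T))
          identity_ok <- identity_ok &&
            all(pc[, -1L, drop = FALSE] == pc[, 1L])
        }
      }
      if (record_buffer) {
        dec$time_ms <- (c0 * H + dec$step + 1) * config$h
        buf_rec[[cyc]] <- dec
      }
    }
    .net_advance_cycle(net$ptr)
    t_deliver <- t_deliver + (t1 - t0)
    t_update <- t_update + (t2 - t1)
    t_gather <- t_gather + (t3 - t2)
  }

  spikes <- data.frame(gid = unlist(sp_gid, use.names = FALSE),
                       time_ms = unlist(sp_time, use.names = FALSE))
  if (is.null(spikes$gid)) spikes <- data.frame(gid = integer(0),
                                                time_ms = numeric(0))
  spikes <- spikes[order(spikes$time_ms, spikes$gid), , drop = FALSE]
  rownames(spikes) <- NULL

  counters <- .net_counters(net$ptr)
  sim_ms <- n_cycles * config$min_delay_ms
  n_local0 <- counters[[1]]$n_local
  F_real <- if (n_cycles > 0 && n_local0 > 0) {
    counters[[1]]$local_spike_counter / n_local0 / (sim_ms / 1000)
  } else 0
  metrics <- list(
    n_cycles = n_cycles,
    sim_time_ms = sim_ms,
    mode = mode,
    local_spike_counter = vapply(counters, `[[`, 0, "local_spike_counter"),
    n_local = vapply(counters, `[[`, 0L, "n_local"),
    built_ranks = ranks,
    F_real = F_real,
    fake_rate = if (mode != "real_emulated" && n_cycles > 0) {
      denom <- spec$N * sim_ms / 1000
      if (mode == "dry_static") fake_total / denom
      else (fake_total + counters[[1]]$local_spike_counter) / denom
    },
    send_buffer_size = cap_trace,
    cycle_spike_counts = count_trace,
    events_delivered = events,
    n_dropped_fake = n_dropped,
    timings = c(deliver = t_deliver, update = t_update, gather = t_gather),
    buffer_checks = if (validate_buffers) {
      list(locality_ok = locality_ok, dynamic_identity_ok = identity_ok)
    })
  out <- list(spikes = spikes, metrics = metrics, spec = spec,
              config = config, net = net)
  if (record_buffer) out$final_buffer <- gbuf
  if (record_buffer) {
    bs <- do.call(rbind, buf_rec)
    out$buffer_spikes <- if (is.null(bs)) {
      data.frame(rank = integer(0), step = integer(0), thread = integer(0),
                 gid = integer(0), time_ms = numeric(0))
    } else bs
  }
  if (record_events) out$events <- .net_event_log(net$ptr)
  class(out) <- "dryspike_run"
  out
}

#' @export
print.dryspike_run <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<run> %s: %d cycles (%g ms), %d neuron spike(s), F_real = %.3f Hz\n",
              m$mode, m$n_cycles, m$sim_time_ms, nrow(x$spikes), m$F_real))
  cat(sprintf("  events delivered: %g, final send_buffer_size: %d slots\n",
              m$events_delivered,
              if (m$n_cycles > 0) m$send_buffer_size[m$n_cycles]
              else NA_integer_))
  invisible(x)
}
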