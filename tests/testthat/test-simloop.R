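test_that("zero simulated time yields zero cycles and an empty record", {
  run <- run_simulation(small_spec(), kernel_config(topology(2, 2,
                                                             "dry_dynamic"),
                                                    sim_time_ms = 0))
  expect_identical(nrow(run$spikes), 0L)
  expect_identical(run$metrics$n_cycles, 0L)
  expect_identical(run$metrics$events_delivered, 0)
})

test_that("repeated runs with one seed are identical in all modes", {
  for (mode in c("real_emulated", "dry_static", "dry_dynamic")) {
    cfg <- kernel_config(topology(2, 2, mode), sim_time_ms = 30,
                         static_target_rate = if (mode == "dry_static") 8 else 0)
    r1 <- run_simulation(small_spec(), cfg)
    r2 <- run_simulation(small_spec(), cfg)
    expect_identical(r1$spikes, r2$spikes)
    expect_identical(r1$metrics$send_buffer_size, r2$metrics$send_buffer_size)
  }
})

test_that("unconnected DC-driven neurons fire at the closed-form rate", {
  # N neurons, no synapses (K = 0), suprathreshold DC
  spec <- network_spec(N = 100, K = 0, eta = 0, drive_rate_hz = 0,
                       dc_mv = 0.6, seed = 2)
  cfg <- kernel_config(topology(4, 1, "real_emulated"), sim_time_ms = 300)
  run <- run_simulation(spec, cfg)
  isi <- lif_dc_isi_steps(0.6)
  expect_identical(nrow(run$spikes), 100L * lif_dc_count(0.6, 3000))
  # local_spike_counter equals the per-rank share of the spike record
  counts <- run$metrics$local_spike_counter
  expect_identical(sum(counts), as.numeric(nrow(run$spikes)))
  for (i in seq_along(counts)) {
    r <- run$metrics$built_ranks[i]
    expect_identical(counts[i],
                     as.numeric(sum(rank_of_gid(run$spikes$gid,
                                                cfg$topology) == r)))
  }
  # every neuron is clockwork: ISIs exactly the closed form
  for (tt in split(run$spikes$time_ms, run$spikes$gid)) {
    expect_true(all(abs(diff(tt) - isi * 0.1) < 1e-9))
  }
})

test_that("collocate -> allgather -> deliver equals direct-routing replay", {
  for (seed in 1:3) {
    spec <- network_spec(N = 50, K = 5, eta = 1.4, seed = seed)
    cfg <- kernel_config(topology(2, 2, "real_emulated"), sim_time_ms = 30)
    run <- run_simulation(spec, cfg, record_events = TRUE)
    conns <- rbind(network_connections(run$net, 0),
                   network_connections(run$net, 1))
    H <- cfg$H
    emis_step <- round(run$spikes$time_ms / cfg$h) - 1
    # spikes of the final cycle stay in the buffer, undelivered
    last_cycle <- run$metrics$n_cycles - 1
    in_flight <- emis_step %/% H == last_cycle
    oracle <- replay_events(conns, run$spikes$gid[!in_flight],
                            emis_step[!in_flight],
                            delay_steps = spec$delay_ms / cfg$h)
    got <- run$events
    expect_identical(nrow(got), nrow(oracle))
    expect_identical(run$metrics$events_delivered, as.numeric(nrow(oracle)))
    o <- sort_events(oracle)
    g <- sort_events(got[c("source", "target", "arrival_step")])
    expect_identical(g$source, o$source)
    expect_identical(g$target, o$target)
    expect_equal(g$arrival_step, o$arrival_step)
  }
})

test_that("spikes emitted in cycle c are delivered once, in cycle c + 1", {
  # ring network: one deterministic synapse per neuron makes the
  # per-event timing fully checkable
  spec <- network_spec(N = 12, connectivity = "ring", delay_ms = 0.5,
                       dc_mv = 0.9, drive_rate_hz = 0, eta = 0, seed = 1)
  cfg <- kernel_config(topology(3, 2, "real_emulated"), sim_time_ms = 20,
                       min_delay_ms = 0.5)
  run <- run_simulation(spec, cfg, record_events = TRUE)
  expect_gt(nrow(run$events), 0)
  emis <- run$events$arrival_step - 5 # delay_steps = 5
  expect_true(all(run$events$arrival_step %/% 5 == emis %/% 5 + 1))
  # delivered exactly once: events match spikes of all but the last cycle
  emis_step <- round(run$spikes$time_ms / cfg$h) - 1
  deliverable <- sum(emis_step %/% 5 < run$metrics$n_cycles - 1)
  expect_identical(nrow(run$events), as.integer(deliverable))
})

test_that("buffer locality holds after every gather in all three modes", {
  for (mode in c("real_emulated", "dry_static", "dry_dynamic")) {
    cfg <- kernel_config(topology(4, 2, mode), sim_time_ms = 60,
                         static_target_rate = if (mode == "dry_static") 20 else 0)
    run <- run_simulation(small_spec(N = 120, K = 10), cfg,
                          validate_buffers = TRUE)
    expect_true(run$metrics$buffer_checks$locality_ok)
  }
})

test_that("malformed buffers trip the delivery integrity check", {
  spec <- small_spec(N = 40, K = 4)
  topo <- topology(2, 2, "real_emulated")
  cfg <- kernel_config(topo, sim_time_ms = 3)
  net <- build_local_network(spec, topo, config = cfg)
  reg <- spike_register(4L, 0L, topo) # gid 4 lives on rank 0
  sec <- collocate_send_buffer(reg, cfg$H, 2, capacity = 40L)
  bad <- allgather_emulated(list(collocate_send_buffer(
    spike_register(integer(0), integer(0), topo), cfg$H, 2, 40L), sec))
  .net_update(net$ptr, 0L); .net_advance_cycle(net$ptr)
  expect_error(.net_deliver(net$ptr, 0L, bad, 40L, TRUE),
               "integrity violation")
})

test_that("send_buffer_size equals the historical spike maximum plus markers", {
  cfg <- kernel_config(topology(2, 2, "real_emulated"), sim_time_ms = 75)
  run <- run_simulation(small_spec(N = 100, K = 8, eta = 1.6), cfg)
  caps <- run$metrics$send_buffer_size
  counts <- run$metrics$cycle_spike_counts
  expect_true(all(diff(caps) >= 0L))
  overhead <- cfg$H * 2L
  running_max <- cummax(apply(counts, 1, max))
  expect_identical(caps, pmax(overhead, as.integer(running_max) + overhead))
})

test_that("the merged spike record is invariant to the VP factorisation", {
  sp <- small_spec(N = 80, K = 8, eta = 1.3, seed = 3)
  recs <- lapply(list(c(1, 8), c(2, 4), c(4, 2), c(8, 1)), function(mt) {
    cfg <- kernel_config(topology(mt[1], mt[2], "real_emulated"),
                         sim_time_ms = 45)
    run_simulation(sp, cfg)$spikes
  })
  expect_gt(nrow(recs[[1]]), 0)
  for (r in recs[-1]) expect_identical(r, recs[[1]])
})

test_that("a simulated network cannot be re-entered", {
  spec <- small_spec(N = 30, K = 3)
  topo <- topology(2, 1, "real_emulated")
  cfg <- kernel_config(topo, sim_time_ms = 6)
  net <- build_local_network(spec, topo, config = cfg)
  run_simulation(spec, cfg, net = net)
  expect_error(run_simulation(spec, cfg, net = net), "state error")
})
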