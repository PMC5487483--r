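test_that("ring network on 2 ranks x 3 threads places synapses locally", {
  spec <- network_spec(N = 8, connectivity = "ring", delay_ms = 0.4)
  topo <- topology(2, 3)
  net <- build_local_network(spec, topo, ranks = 0L)
  expect_identical(network_neurons(net, 0), c(2L, 4L, 6L, 8L))
  conns <- network_connections(net, 0)
  expect_identical(nrow(conns), 4L) # one incoming synapse per local neuron
  expect_true(all(conns$target %in% c(2L, 4L, 6L, 8L)))
  expect_identical(sort(conns$source), c(1L, 3L, 5L, 7L))
  expect_identical(conns$thread, thread_of_gid(conns$target, topo))
})

test_that("a single rank holds all N * K synapses", {
  spec <- network_spec(N = 50, K = 7, seed = 3)
  net <- build_local_network(spec, topology(1))
  expect_identical(structural_memory_report(net)$n_synapses, 50 * 7)
})

test_that("synapse counts are conserved across shards and stay local", {
  for (cfg in list(c(200, 16, 1), c(500, 4, 2), c(1000, 16, 3))) {
    N <- cfg[1]; M <- cfg[2]; T <- cfg[3]
    spec <- network_spec(N = N, K = 20, seed = 5)
    topo <- topology(M, T, "real_emulated")
    net <- build_local_network(spec, topo)
    total <- 0
    for (r in seq_len(M) - 1L) {
      conns <- network_connections(net, r)
      total <- total + nrow(conns)
      expect_true(all(rank_of_gid(conns$target, topo) == r))
      expect_identical(conns$thread, thread_of_gid(conns$target, topo))
      expect_true(all(conns$source >= 1 & conns$source <= N))
    }
    expect_identical(total, N * 20L)
  }
})

test_that("sampling honours autapse and multapse settings and in-degree", {
  spec <- network_spec(N = 100, K = 12, seed = 9)
  net <- build_local_network(spec, topology(2))
  conns <- network_connections(net, 0)
  expect_true(all(conns$source != conns$target)) # no autapses by default
  per_target <- table(conns$target)
  expect_true(all(per_target == 12L)) # fixed in-degree
  # excitatory/inhibitory split of sources
  k_exc <- table(conns$target[conns$source <= 80])
  expect_true(all(k_exc == 10L)) # round(0.8 * 12)
  # without multapses, (source, target) pairs are unique
  spec2 <- network_spec(N = 100, K = 12, seed = 9, multapses = FALSE)
  conns2 <- network_connections(build_local_network(spec2, topology(2)), 0)
  expect_false(anyDuplicated(conns2[c("source", "target")]) > 0)
})

test_that("infeasible in-degree is rejected", {
  expect_error(network_spec(N = 10, K = 10), "infeasible in-degree")
  expect_error(network_spec(N = 10, K = 12), "infeasible in-degree")
})

test_that("build is reproducible and independent of the mode", {
  spec <- network_spec(N = 120, K = 10, seed = 21)
  modes <- c("real_emulated", "dry_static", "dry_dynamic")
  built <- lapply(modes, function(m) {
    net <- build_local_network(spec, topology(4, 2, m), ranks = 0L)
    list(conns = network_connections(net, 0),
         rep = unclass(structural_memory_report(net, 0)))
  })
  for (b in built[-1]) {
    expect_identical(b$conns, built[[1]]$conns)
    expect_identical(b$rep, built[[1]]$rep)
  }
  # and across repeated builds with the same seed
  again <- build_local_network(spec, topology(4, 2, "real_emulated"),
                               ranks = 0L)
  expect_identical(network_connections(again, 0), built[[1]]$conns)
})

test_that("plastic synapses are exactly the excitatory-excitatory ones", {
  spec <- network_spec(N = 100, K = 10, plastic_ee = TRUE, seed = 2)
  conns <- network_connections(build_local_network(spec, topology(2)), 0)
  is_ee <- conns$source <= 80 & conns$target <= 80
  expect_identical(conns$type == "stdp", is_ee)
  expect_true(all(conns$weight[conns$type == "stdp"] == spec$stdp$w_init))
  expect_true(all(conns$weight[conns$type == "static_inh"] == spec$J_inh))
})

test_that("structural report counts match the connection table", {
  spec <- network_spec(N = 150, K = 9, plastic_ee = TRUE, seed = 4)
  topo <- topology(3, 2)
  net <- build_local_network(spec, topo, ranks = 0:2)
  for (r in 0:2) {
    conns <- network_connections(net, r)
    rep <- structural_memory_report(net, r)
    expect_identical(rep$n_synapses, as.numeric(nrow(conns)))
    expect_identical(rep$n_plastic, as.numeric(sum(conns$type == "stdp")))
    expect_identical(rep$n_neurons, length(network_neurons(net, r)))
    expect_identical(rep$n_sparse_entries,
                     as.numeric(nrow(unique(conns[c("source", "thread")]))))
  }
  # bytes estimate is a plain weighted sum of the counts
  rep <- structural_memory_report(net, 0, byte_constants =
                                    c(neuron = 10, synapse = 2))
  expect_identical(rep$bytes_estimate,
                   10 * rep$n_neurons + 2 * rep$n_synapses)
})
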