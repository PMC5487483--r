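#' Build the rank-local shard of the network
#'
#' Creates the neurons and the connection infrastructure of one or more
#' ranks. For each rank-local target neuron, `K` presynaptic sources are
#' drawn (fixed in-degree, uniform over the source population, no autapses,
#' multapses allowed by default) from the target's VP-keyed random stream,
#' so building is rank-local: no information from other ranks is needed.
#' Synapses are stored on the thread of their postsynaptic neuron in a
#' per-thread sparse table keyed by source GID, grouped by synapse type.
#'
#' The build path does not depend on the topology mode: rank 0 of a dry run
#' is bit-identical to rank 0 of the corresponding emulated real run with
#' the same seed (the build-phase equivalence contract).
#'
#' @param spec A [network_spec()].
#' @param topo A [topology()].
#' @param ranks Ranks to build. Defaults to rank 0 in the dry modes and to
#'   all ranks in `real_emulated` mode.
#' @param config A [kernel_config()]; defaults to `h = 0.1` ms and
#'   `min_delay = spec$delay_ms` with zero simulated time (build only).
#' @param record_events Keep a per-event delivery log (test instrumentation;
#'   memory grows with every delivered spike).
#' @return An object of class `dryspike_network`.
#' @examples
#' net <- build_local_network(network_spec(N = 100, K = 10), topology(4))
#' structural_memory_report(net)
#' @export
build_local_network <- function(spec, topo, ranks = NULL, config = NULL,
                                record_events = FALSE) {
  if (!inherits(spec, "dryspike_spec")) stop("spec must be a network_spec()")
  if (!inherits(topo, "dryspike_topology")) stop("topo must be a topology()")
  if (is.null(config)) {
    # build-only config; the placeholder target rate never generates spikes
    config <- kernel_config(topo, sim_time_ms = 0, h = 0.1,
                            min_delay_ms = spec$delay_ms,
                            static_target_rate =
                              if (topo$mode == "dry_static") 1 else 0)
  }
  if (is.null(ranks)) {
    ranks <- if (topo$mode == "real_emulated") seq_len(topo$M) - 1L else 0L
  }
  ranks <- as.integer(ranks)
  if (any(ranks < 0L | ranks >= topo$M)) {
    stop(sprintf("invalid rank: ranks must lie in [0, %d)", topo$M))
  }
  par <- kernel_params(spec, config)
  # connection memory lives outside R's heap, so the garbage collector sees
  # no pressure from discarded networks; collect before any large build to
  # run their finalizers
  if (as.double(spec$N) * spec$K * length(ranks) > 1e6) gc(FALSE)
  ptr <- .net_create(par, topo$M, topo$T, ranks, record_events)
  structure(list(ptr = ptr, spec = spec, topo = topo, config = config,
                 ranks = ranks, record_events = record_events),
            class = "dryspike_network")
}

#' @export
print.dryspike_network <- function(x, ...) {
  info <- .net_info(x$ptr)
  rep0 <- .net_report(x$ptr, x$ranks[1])
  cat(sprintf("<network> N = %d on %d x %d VPs (%s), built rank(s): %s\n",
              info$N, info$M, info$T, x$topo$mode,
              paste(x$ranks, collapse = ", ")))
  cat(sprintf("  rank %d: %d neurons, %g synapses\n", x$ranks[1],
              rep0$n_neurons, rep0$n_synapses))
  invisible(x)
}

#' Rank-local neurons of a built network
#'
#' @param net A [build_local_network()] result.
#' @param rank A built rank (default: first built rank).
#' @return Integer vector of local GIDs in ascending order.
#' @export
network_neurons <- function(net, rank = net$ranks[1]) {
  .net_local_gids(net$ptr, as.integer(rank))
}

#' Connection infrastructure of a built rank
#'
#' Flattens the per-thread sparse tables into one data frame. Every stored
#' synapse targets a neuron local to (`rank`, `thread`); sources may be any
#' GID in the network. Intended for inspection and testing at small `N`.
#'
#' @inheritParams network_neurons
#' @return A data frame with columns `source`, `target`, `thread`, `type`
#'   (`"static_exc"`, `"static_inh"`, `"stdp"`), `weight` (current weight;
#'   plastic weights change during simulation) and `delay_steps`.
#' @export
network_connections <- function(net, rank = net$ranks[1]) {
  df <- .net_connections(net$ptr, as.integer(rank))
  df$type <- c("static_exc", "static_inh", "stdp")[df$type + 1L]
  df
}

#' Structural memory report
#'
#' Counts of the rank-local objects: neurons, synapses by type, sparse-table
#' entries and Connectors, ring-buffer slots, and (when known) the current
#' send-buffer capacity. With `byte_constants`, a bytes estimate
#' `sum(counts * constant)` is added; the constants are configurable because
#' absolute per-object sizes are implementation dialect.
#'
#' @inheritParams network_neurons
#' @param send_buffer_size Current per-rank buffer section capacity, if a
#'   simulation has been run.
#' @param byte_constants Optional named numeric vector with entries among
#'   `neuron`, `synapse`, `sparse_entry`, `buffer_slot`.
#' @return A list of counts (class `dryspike_report`).
#' @export
structural_memory_report <- function(net, rank = net$ranks[1],
                                     send_buffer_size = NULL,
                                     byte_constants = NULL) {
  rep <- .net_report(net$ptr, as.integer(rank))
  rep$send_buffer_size <- send_buffer_size
  if (!is.null(byte_constants)) {
    b <- function(name) if (name %in% names(byte_constants)) byte_constants[[name]] else 0
    rep$bytes_estimate <-
      rep$n_neurons * b("neuron") + rep$n_synapses * b("synapse") +
      rep$n_sparse_entries * b("sparse_entry") +
      (rep$ring_slots + if (is.null(send_buffer_size)) 0 else
        send_buffer_size * net$topo$M) * b("buffer_slot")
  }
  structure(rep, class = "dryspike_report")
}

#' @export
print.dryspike_report <- function(x, ...) {
  cat("<structural memory report>\n")
  for (f in names(x)) {
    if (!is.null(x[[f]])) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}
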