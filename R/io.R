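#' Write and read spike files
#'
#' Spike records are written as two-column tab-separated text (GID, time in
#' ms), one spike per line, sorted by time then GID — the GDF-style
#' convention of spiking-network simulators. No header.
#'
#' @param spikes Data frame with columns `gid`, `time_ms`.
#' @param path Output file.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()` a data
#'   frame with columns `gid`, `time_ms`.
#' @export
write_spikes <- function(spikes, path) {
  ord <- order(spikes$time_ms, spikes$gid)
  df <- data.frame(gid = spikes$gid[ord],
                   time_ms = sprintf("%.3f", spikes$time_ms[ord]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(gid = integer(0), time_ms = numeric(0)))
  }
  df <- read.table(path, sep = "\t", col.names = c("gid", "time_ms"),
                   colClasses = c("integer", "numeric"))
  df
}

# Serialize spec + config into one plain list (the config echo).
as_config_list <- function(spec, config) {
  topo <- config$topology
  list(
    network = list(
      N = spec$N, exc_fraction = spec$exc_fraction, K = spec$K,
      J_exc = spec$J_exc, J_inh = spec$J_inh, J_ext = spec$J_ext,
      delay_ms = spec$delay_ms, eta = spec$eta,
      drive_rate_hz = spec$drive_rate_hz, dc_mv = spec$dc_mv,
      plastic_ee = spec$plastic_ee, stdp = spec$stdp, tau_m = spec$tau_m,
      theta = spec$theta, v_reset = spec$v_reset,
      tau_ref_ms = spec$tau_ref_ms, connectivity = spec$connectivity,
      autapses = spec$autapses, multapses = spec$multapses,
      seed = spec$seed),
    kernel = list(h = config$h, min_delay_ms = config$min_delay_ms,
                  sim_time_ms = config$sim_time_ms,
                  static_target_rate = config$static_target_rate,
                  seed = config$seed),
    topology = list(num_processes = topo$M, threads_per_rank = topo$T,
                    mode = topo$mode))
}

# Rebuild spec + config from a config list (inverse of as_config_list).
from_config_list <- function(cfg) {
  nw <- cfg$network
  spec <- network_spec(
    N = nw$N, exc_fraction = nw$exc_fraction, K = nw$K, J_exc = nw$J_exc,
    J_inh = nw$J_inh, J_ext = nw$J_ext, delay_ms = nw$delay_ms,
    eta = nw$eta, drive_rate_hz = nw$drive_rate_hz, dc_mv = nw$dc_mv,
    plastic_ee = nw$plastic_ee, stdp_params = nw$stdp, tau_m = nw$tau_m,
    theta = nw$theta, v_reset = nw$v_reset, tau_ref_ms = nw$tau_ref_ms,
    connectivity = nw$connectivity, autapses = nw$autapses,
    multapses = nw$multapses, seed = nw$seed)
  topo <- topology(cfg$topology$num_processes, cfg$topology$threads_per_rank,
                   cfg$topology$mode)
  ks <- cfg$kernel$seed
  if (length(ks) == 0) ks <- NULL # an absent seed serialises as null / {}
  config <- kernel_config(topo, sim_time_ms = cfg$kernel$sim_time_ms,
                          h = cfg$kernel$h,
                          min_delay_ms = cfg$kernel$min_delay_ms,
                          static_target_rate = cfg$kernel$static_target_rate,
                          seed = ks)
  list(spec = spec, config = config)
}

#' Write and read run configurations
#'
#' A run configuration (network spec + kernel settings + topology) is stored
#' as a YAML document whose keys mirror the [network_spec()] and
#' [kernel_config()] fields. The parsed configuration is echoed bit-exactly
#' into the run manifest.
#'
#' @param spec A [network_spec()].
#' @param config A [kernel_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a list
#'   with elements `spec` and `config`.
#' @export
write_config <- function(spec, config, path) {
  yaml::write_yaml(as_config_list(spec, config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  from_config_list(yaml::read_yaml(path))
}

#' Run manifest
#'
#' Collects everything needed to reproduce and audit a run into one
#' JSON-serialisable list: the fully resolved configuration echo, the mode
#' and seed, the package version, per-phase timings, the kernel counters
#' (`local_spike_counter`, realized rate `F_real`, final
#' `send_buffer_size`), and the structural memory report of rank 0. A run
#' re-executed from its manifest reproduces the spike file byte-identically.
#'
#' @param run A [run_simulation()] result.
#' @return A list (the manifest).
#' @export
run_manifest <- function(run) {
  m <- run$metrics
  final_cap <- if (m$n_cycles > 0) m$send_buffer_size[m$n_cycles]
               else run$config$H * run$config$topology$T
  rep0 <- structural_memory_report(run$net, run$net$ranks[1],
                                   send_buffer_size = final_cap)
  list(
    package = "dryspike",
    version = as.character(packageVersion("dryspike")),
    config = as_config_list(run$spec, run$config),
    mode = m$mode,
    seed = if (!is.null(run$config$seed)) run$config$seed else run$spec$seed,
    n_cycles = m$n_cycles,
    local_spike_counter = m$local_spike_counter,
    F_real = m$F_real,
    fake_rate = m$fake_rate,
    send_buffer_size = final_cap,
    events_delivered = m$events_delivered,
    timings_s = as.list(m$timings),
    structural_report = unclass(rep0))
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
run_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- from_config_list(man$config)
  run_simulation(cfg$spec, cfg$config)
}

#' Ready-to-run example configurations
#'
#' Small desk-scale configurations exercising the main regimes: a
#' deterministic 8-neuron ring on 2 ranks x 3 threads (the minimal layout in
#' which every buffer structure is non-trivial), a small balanced random
#' network, a weak-scaling pair (constant neurons per rank), and a
#' static/dynamic dry-run pair sharing one network.
#'
#' @return Named list; each element is a list with `spec` and `config`.
#' @examples
#' fx <- fixture_suite()
#' names(fx)
#' @export
fixture_suite <- function() {
  ring <- list(
    spec = network_spec(N = 8, connectivity = "ring", delay_ms = 0.4,
                        dc_mv = 20.5, drive_rate_hz = 0, seed = 1),
    config = kernel_config(topology(2, 3, "real_emulated"),
                           sim_time_ms = 40, h = 0.1, min_delay_ms = 0.4))
  brunel_small <- list(
    spec = network_spec(N = 1000, K = 100, eta = 1.7, seed = 1),
    config = kernel_config(topology(4, 2, "dry_dynamic"), sim_time_ms = 150))
  weak <- function(M) {
    N_M <- 250L
    list(spec = network_spec(N = N_M * M, K = 50, eta = 1.7, seed = 1),
         config = kernel_config(topology(M, 2, "dry_dynamic"),
                                sim_time_ms = 150))
  }
  static_spec <- network_spec(N = 1000, K = 100, eta = 1.7, seed = 1)
  list(
    `ring-m2t3` = ring,
    `brunel-small` = brunel_small,
    `brunel-weak-m2` = weak(2L),
    `brunel-weak-m8` = weak(8L),
    `static-pair` = list(
      spec = static_spec,
      config = kernel_config(topology(8, 2, "dry_static"), sim_time_ms = 150,
                             static_target_rate = 7)),
    `dynamic-pair` = list(
      spec = static_spec,
      config = kernel_config(topology(8, 2, "dry_dynamic"),
                             sim_time_ms = 150)))
}
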