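# dryspike

Single-process **dry-run emulation** of distributed spiking-network
simulations.

Developers and users of parallel spiking-network simulators need to know
how a simulation will behave on `M` MPI ranks — memory footprint, spike
load, buffer sizes, dynamics — without booking `M` ranks on a cluster.
`dryspike` exploits the fact that the build phase of such simulators is
rank-local: a single process can construct exactly the neurons, synapses
and sparse tables it would own as rank 0 of an `M × T` (ranks × threads)
machine, and then simulate its shard while *fake spikes* stand in for the
input of the `M − 1` missing ranks.

The package implements, in an R front end over a C++ kernel:

* **Round-robin locality**: rank `gid mod M`, thread
  `(gid mod (M·T)) div M`; shard enumeration and virtual-process (VP)
  bookkeeping.
* **The simulation cycle** deliver → update → gather with per-thread spike
  registers and flat, marker-structured send/receive buffers of equal
  per-rank capacity (a monotone high-water mark, `send_buffer_size`).
* **Three gather modes**: `real_emulated` (all ranks simulated in one
  process; the validation oracle), `dry_static` (buffer filled at a target
  rate *F* by a deterministic error-diffusion accumulator) and
  `dry_dynamic` (rank 0's buffer section replicated into every fake rank
  with re-randomised, locality-correct GIDs — fake counts always equal the
  local spike count).
* **The testbed network**: a balanced random network of
  leaky integrate-and-fire neurons (80 % excitatory, fixed in-degree
  `K = K_S · 11250`, Poisson drive scaled by η) with optional pair-based
  STDP on excitatory-excitatory synapses, updated at spike-delivery time.
* **Validation statistics**: mean rate, instantaneous population activity
  (2.5 ms bins), CV of interspike intervals (≥ 3 spikes filter), relative
  differences `(d_dry − d_real)/d_real`, and η sweeps.

## Worked example

Behave like rank 0 of a 24-rank × 2-thread machine, with the missing ranks
emulated dynamically:

```r
library(dryspike)

spec <- network_spec(N = 1000, K = 100, eta = 1.7, plastic_ee = TRUE,
                     seed = 42)
cfg  <- kernel_config(topology(24, 2, "dry_dynamic"), sim_time_ms = 500)
run  <- run_simulation(spec, cfg)
run
#> <run> dry_dynamic: 334 cycles (501 ms), 890 neuron spike(s), F_real = 43.328 Hz
#>   events delivered: 87511, final send_buffer_size: 43 slots

S <- spike_train_set(run$spikes, pop_size = run$metrics$n_local[1],
                     window_ms = 500)
mean_rate(S)                      # 43.27 Hz  (rank-0 neurons' realized rate)
population_activity_hist(S)$mean  # 43.27 Hz  (2.5 ms-binned activity)
cv_isi(S)$mean                    # 0.16      (fairly regular firing)

structural_memory_report(run$net, 0,
  send_buffer_size = run$metrics$send_buffer_size[run$metrics$n_cycles])
#> <structural memory report>
#>   n_neurons          41
#>   n_synapses         4100
#>   n_sparse_entries   1736
#>   send_buffer_size   43
#>   ...
```

The one physical process holds the 41 neurons whose GIDs are multiples of
24 and their 4100 incoming synapses; `F_real` is the realized rate of those
local neurons, and `send_buffer_size` is the per-rank buffer capacity a
real 24-rank run would need — the number to feed into MPI benchmarks when
estimating communication time (which is deliberately out of scope here).

From a shell, the same run is:

```sh
Rscript inst/exec/dryspike-run --neurons 1000 --k 100 --eta 1.7 --plastic \
  --mode dry_dynamic --num-processes 24 --threads 2 --sim-time 500 \
  --seed 42 --out-dir out/
```

which writes `out/spikes.gdf` (two-column GID/time records) and
`out/manifest.json` (full config echo, counters, structural report);
`run_from_manifest()` reproduces the spike file byte-identically. A target
rate `> 0` (`--target-rate 7`) selects the static mode instead; `0` selects
dynamic filling.

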