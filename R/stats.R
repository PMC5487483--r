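#' Spike train set
#'
#' A recorded set of spikes `(gid, time_ms)` together with the size of the
#' recorded population and the observation window, the unit all the
#' validation statistics operate on.
#'
#' @param spikes Data frame with columns `gid` and `time_ms` (e.g. the
#'   `$spikes` of a [run_simulation()] result).
#' @param pop_size Number of neurons in the recorded population (including
#'   silent ones).
#' @param window_ms Observation window length in ms.
#' @param t_start_ms Window start (default 0); spikes outside
#'   `[t_start, t_start + window]` are dropped.
#' @return An object of class `dryspike_spikes`.
#' @export
spike_train_set <- function(spikes, pop_size, window_ms, t_start_ms = 0) {
  if (!all(c("gid", "time_ms") %in% names(spikes))) {
    stop("spikes must have columns gid and time_ms")
  }
  if (pop_size < 1) stop("pop_size must be positive")
  if (window_ms <= 0) stop("window_ms must be positive")
  keep <- spikes$time_ms >= t_start_ms &
    spikes$time_ms <= t_start_ms + window_ms
  structure(list(spikes = spikes[keep, , drop = FALSE],
                 pop_size = as.integer(pop_size),
                 window_ms = window_ms, t_start_ms = t_start_ms),
            class = "dryspike_spikes")
}

#' Mean firing rate
#'
#' Total spike count divided by population size and window length:
#' the mean spike frequency `F` over the simulation period. Equals the rate
#' derived from the kernel's `local_spike_counter` when the recorded set is
#' the full local population.
#'
#' @param S A [spike_train_set()].
#' @return Rate in Hz.
#' @export
mean_rate <- function(S) {
  stopifnot(inherits(S, "dryspike_spikes"))
  nrow(S$spikes) / S$pop_size / (S$window_ms / 1000)
}

#' Instantaneous population activity distribution
#'
#' Splits the window into successive bins (2.5 ms by default), counts the
#' spikes of the recorded population in each, and converts to spikes per
#' second per neuron. A trailing partial bin is dropped.
#'
#' @param S A [spike_train_set()].
#' @param bin_ms Bin width in ms (> 0).
#' @return List with `rate` (per-bin activity, spikes/s per neuron),
#'   `bin_ms`, `mean` and `sd`.
#' @export
population_activity_hist <- function(S, bin_ms = 2.5) {
  stopifnot(inherits(S, "dryspike_spikes"))
  if (bin_ms <= 0) stop("bin_ms must be positive")
  n_bins <- floor(S$window_ms / bin_ms)
  if (n_bins < 1) stop("window shorter than one bin")
  t_rel <- S$spikes$time_ms - S$t_start_ms
  bin <- floor(t_rel / bin_ms) + 1
  bin <- bin[bin >= 1 & bin <= n_bins]
  counts <- tabulate(bin, nbins = n_bins)
  rate <- counts / S$pop_size / (bin_ms / 1000)
  list(rate = rate, bin_ms = bin_ms, mean = mean(rate),
       sd = if (n_bins > 1) stats::sd(rate) else 0)
}

#' Coefficient of variation of interspike intervals
#'
#' For every neuron of the recorded population that spiked at least
#' `min_spikes` times in the window (default 3, i.e. at least two ISIs), the
#' CV of its interspike intervals `sd(ISI) / mean(ISI)`: 0 for clockwork
#' firing, near 1 for Poisson-like irregularity.
#'
#' @param S A [spike_train_set()].
#' @param min_spikes Minimum spike count for a neuron to qualify.
#' @return List with `per_neuron` (data frame `gid`, `n_spikes`, `cv`),
#'   `mean`, `sd` and `fraction_qualifying` (relative to `pop_size`).
#' @export
cv_isi <- function(S, min_spikes = 3) {
  stopifnot(inherits(S, "dryspike_spikes"))
  sp <- S$spikes
  out <- data.frame(gid = integer(0), n_spikes = integer(0), cv = numeric(0))
  if (nrow(sp) > 0) {
    byg <- split(sp$time_ms, sp$gid)
    byg <- byg[lengths(byg) >= max(min_spikes, 2)]
    if (length(byg) > 0) {
      cvs <- vapply(byg, function(tt) {
        tt <- sort(tt)
        if (anyDuplicated(tt)) {
          stop("integrity error: duplicate spike times for one neuron")
        }
        isi <- diff(tt)
        stats::sd(isi) / mean(isi)
      }, 0)
      out <- data.frame(gid = as.integer(names(byg)),
                        n_spikes = lengths(byg), cv = unname(cvs))
    }
  }
  list(per_neuron = out,
       mean = if (nrow(out)) mean(out$cv) else NA_real_,
       sd = if (nrow(out) > 1) stats::sd(out$cv) else NA_real_,
       fraction_qualifying = nrow(out) / S$pop_size)
}

#' Relative difference between a dry-run and a real-run measurement
#'
#' `(d_dry - d_real) / d_real`: the fraction by which the dry-run value
#' overshoots (positive) or undershoots (negative) the real-run value.
#'
#' @param d_dry,d_real Measured values; `d_real` must be non-zero.
#' @return The relative difference as a fraction.
#' @examples
#' relative_difference(1.12, 1.0)
#' @export
relative_difference <- function(d_dry, d_real) {
  if (any(d_real == 0)) stop("undefined: d_real must be non-zero")
  (d_dry - d_real) / d_real
}

#' Firing rate as a function of the drive scale
#'
#' Runs the network over a grid of `eta` values, for one or more modes, with
#' several master seeds per condition, and tabulates the mean and standard
#' deviation of the realized rank-0 firing rate `F_real`. The dry-run curves
#' typically sit slightly above the emulated real curve at matched `eta`; a
#' 5-10 % reduction of the dry-run `eta` is the rule of thumb to align them.
#'
#' @param spec A [network_spec()] (its `eta` and `seed` are overridden).
#' @param config_fn Function `mode -> kernel_config()`, so each mode can
#'   carry its own topology.
#' @param etas Numeric grid of drive scales.
#' @param modes Modes to sweep.
#' @param seeds Master seeds (>= 2 for a standard deviation).
#' @return Data frame with columns `eta`, `mode`, `F_mean`, `F_sd`,
#'   `n_seeds`.
#' @export
rate_vs_eta_sweep <- function(spec, config_fn, etas,
                              modes = c("real_emulated", "dry_dynamic"),
                              seeds = 1:2) {
  rows <- list()
  for (mode in modes) {
    config <- config_fn(mode)
    for (eta in etas) {
      F <- vapply(seeds, function(s) {
        sp <- spec
        sp$eta <- eta
        sp$seed <- s
        run_simulation(sp, config)$metrics$F_real
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(eta = eta, mode = mode, F_mean = mean(F),
                   F_sd = if (length(F) > 1) stats::sd(F) else NA_real_,
                   n_seeds = length(seeds))
    }
  }
  do.call(rbind, rows)
}
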