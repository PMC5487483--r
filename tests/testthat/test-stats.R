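test_that("mean rate is spikes per neuron per second", {
  empty <- spike_train_set(data.frame(gid = integer(0), time_ms = numeric(0)),
                           pop_size = 10, window_ms = 100)
  expect_identical(mean_rate(empty), 0)
  S <- spike_train_set(data.frame(gid = rep(1:500, length.out = 1250),
                                  time_ms = seq(0.1, 500, length.out = 1250)),
                       pop_size = 500, window_ms = 500)
  expect_equal(mean_rate(S), 5.0)
  expect_error(spike_train_set(data.frame(gid = 1, time_ms = 1), 10, 0),
               "window")
})

test_that("counter-based and detector-based rates agree", {
  spec <- small_spec(N = 100, K = 8, eta = 1.5, seed = 6)
  cfg <- kernel_config(topology(2, 1, "dry_dynamic"), sim_time_ms = 150)
  run <- run_simulation(spec, cfg)
  n_local <- run$metrics$n_local[1]
  S <- spike_train_set(run$spikes, pop_size = n_local,
                       window_ms = run$metrics$sim_time_ms)
  expect_equal(mean_rate(S), run$metrics$F_real, tolerance = 1e-12)
})

test_that("population activity histogram has Poisson-count moments", {
  # clockwork population: every bin identical, sd exactly 0
  reg <- data.frame(gid = rep(1:10, times = 40),
                    time_ms = rep(seq(1.25, 100, by = 2.5), each = 10))
  S <- spike_train_set(reg, pop_size = 10, window_ms = 100)
  h <- population_activity_hist(S)
  expect_identical(length(h$rate), 40L)
  expect_identical(h$sd, 0)
  expect_equal(h$mean, mean_rate(S))
  # extreme synchrony: all spikes in one bin maximises the spread
  burst <- spike_train_set(data.frame(gid = rep(1:10, 5),
                                      time_ms = rep(1, 50)),
                           pop_size = 10, window_ms = 100)
  hb <- population_activity_hist(burst)
  expect_identical(sum(hb$rate > 0), 1L)
  # Poisson surrogate: mean ~ r, sd ~ sqrt(r / (pop * bin_s))
  set.seed(3)
  r <- 40; pop <- 200; win <- 2000
  n <- rpois(1, r * pop * win / 1000)
  Sp <- spike_train_set(data.frame(gid = sample.int(pop, n, TRUE),
                                   time_ms = runif(n, 0, win)),
                        pop_size = pop, window_ms = win)
  hp <- population_activity_hist(Sp)
  expect_lt(abs(hp$mean - r) / r, 0.1)
  expect_lt(abs(hp$sd - sqrt(r / (pop * 0.0025))) / sqrt(r / (pop * 0.0025)),
            0.15)
})

test_that("partial trailing bins are dropped", {
  S <- spike_train_set(data.frame(gid = 1, time_ms = 9.9), pop_size = 1,
                       window_ms = 9.9)
  h <- population_activity_hist(S, bin_ms = 2.5)
  expect_identical(length(h$rate), 3L) # 9.9 ms -> 3 full bins
  expect_error(population_activity_hist(S, bin_ms = 0), "positive")
})

test_that("CV of ISIs separates clockwork from Poisson and filters", {
  regular <- spike_train_set(data.frame(gid = 1, time_ms = seq(10, 490, 10)),
                             pop_size = 1, window_ms = 500)
  cv <- cv_isi(regular)
  expect_equal(cv$per_neuron$cv, 0)
  expect_identical(cv$fraction_qualifying, 1)
  # a neuron with only 2 spikes is excluded by the >= 3 spikes rule
  two <- spike_train_set(data.frame(gid = c(1, 1, 2, 2, 2),
                                    time_ms = c(10, 20, 10, 30, 60)),
                         pop_size = 2, window_ms = 500)
  cv2 <- cv_isi(two)
  expect_identical(cv2$per_neuron$gid, 2L)
  expect_identical(cv2$fraction_qualifying, 0.5)
  # long Poisson train: exponential ISIs give CV near 1
  set.seed(9)
  tt <- cumsum(rexp(4000, rate = 0.1))
  Sp <- spike_train_set(data.frame(gid = 1, time_ms = tt), pop_size = 1,
                        window_ms = max(tt))
  expect_lt(abs(cv_isi(Sp)$per_neuron$cv - 1), 0.05)
})

test_that("relative difference is the dry-over-real fraction", {
  expect_identical(relative_difference(5, 5), 0)
  expect_equal(relative_difference(1.12, 1), 0.12)
  expect_error(relative_difference(1, 0), "undefined")
  # swap antisymmetry with re-based denominator: rd(a,b) = -rd(b,a)/(1+rd(b,a))
  a <- 8.2; b <- 7.1
  expect_equal(relative_difference(a, b),
               -relative_difference(b, a) / (1 + relative_difference(b, a)))
})

test_that("rate sweeps tabulate F(eta) and zero drive silences the network", {
  spec <- small_spec(N = 60, K = 4, seed = 5)
  cfg_fn <- function(mode) kernel_config(topology(2, 1, mode),
                                         sim_time_ms = 60)
  tab <- rate_vs_eta_sweep(spec, cfg_fn, etas = c(0, 1.2, 1.6),
                           modes = c("real_emulated", "dry_dynamic"),
                           seeds = 1:2)
  expect_identical(nrow(tab), 6L)
  # eta = 0 with weak recurrence: silent
  expect_identical(tab$F_mean[tab$eta == 0], c(0, 0))
  # F non-decreasing in eta in the drive-dominated regime
  for (m in unique(tab$mode)) {
    expect_true(!is.unsorted(tab$F_mean[tab$mode == m]))
  }
})
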