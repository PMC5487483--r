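test_that("allgather concatenates equal-capacity sections in rank order", {
  a <- c(5L, -1L, -2L); b <- c(-1L, 7L, -2L); c <- c(-1L, -2L, -2L)
  expect_identical(allgather_emulated(list(a)), a)
  expect_identical(allgather_emulated(list(a, b, c)), c(a, b, c))
  expect_error(allgather_emulated(list(a, b[1:2])), "contract violation")
})

test_that("integer static quota fills every part exactly, with zero drift", {
  # q = N * F * (min_delay/1000) / (M * T * H) = 2 per part
  topo <- topology(2, 1, "dry_static")
  st <- static_fill_state(N = 1600, F = 10, min_delay_ms = 1.5, topo, H = 6)
  expect_equal(st$q, 2)
  rng <- rng_stream(1, 99)
  for (i in 1:5) {
    fs <- fill_static(st, topo, H = 6, N = 1600, capacity = 30L, rng)
    expect_true(all(fs$counts == 2L))
    st <- fs$state
    expect_equal(st$carry, 0)
  }
})

test_that("the error-diffusion accumulator hits the expected per-cycle total", {
  # N=1200, M=4, T=2, H=15, F=10 Hz -> 18 spikes per cycle
  topo <- topology(4, 2, "dry_static")
  st <- static_fill_state(N = 1200, F = 10, min_delay_ms = 1.5, topo, H = 15)
  rng <- rng_stream(2, 99)
  totals <- integer(20)
  for (i in 1:20) {
    fs <- fill_static(st, topo, H = 15, N = 1200, capacity = 200L, rng)
    totals[i] <- sum(fs$counts)
    st <- fs$state
  }
  expect_true(all(abs(totals - 18L) <= 1L))
  expect_equal(mean(totals), 18, tolerance = 1e-6)
})

test_that("long-run static rate converges to the target", {
  # 10 s with N=1000, F=7 Hz: realized fake rate within 0.5 % of target
  topo <- topology(4, 1, "dry_static")
  H <- 15
  st <- static_fill_state(N = 1000, F = 7, min_delay_ms = 1.5, topo, H)
  rng <- rng_stream(3, 99)
  n_cycles <- ceiling(10000 / 1.5)
  total <- 0
  for (i in seq_len(n_cycles)) {
    fs <- fill_static(st, topo, H, N = 1000, capacity = 100L, rng)
    total <- total + sum(fs$counts)
    st <- fs$state
  }
  realized <- total / 1000 / (n_cycles * 1.5 / 1000)
  expect_lt(abs(realized - 7) / 7, 0.005)
})

test_that("static fill places only GIDs local to each part", {
  topo <- topology(4, 2, "dry_static")
  st <- static_fill_state(N = 120, F = 400, min_delay_ms = 1.5, topo, H = 15)
  fs <- fill_static(st, topo, H = 15, N = 120, capacity = 200L,
                    rng_stream(4, 99))
  dec <- decode_buffer(fs$buffer, 4, 15, 2)
  expect_gt(nrow(dec), 0)
  expect_true(buffer_locality_ok(dec, topo))
})

test_that("static fill drops spikes for empty shards with a warning", {
  # N = 3 on M=8 ranks: most (rank, thread) shards are empty
  topo <- topology(8, 1, "dry_static")
  st <- static_fill_state(N = 3, F = 3000, min_delay_ms = 1.5, topo, H = 15)
  expect_warning(
    fs <- fill_static(st, topo, H = 15, N = 3, capacity = 50L,
                      rng_stream(5, 99)),
    "empty")
  expect_gt(fs$n_dropped, 0)
  expect_true(buffer_locality_ok(decode_buffer(fs$buffer, 8, 15, 1), topo))
})

test_that("dynamic fill preserves per-part counts with re-randomised GIDs", {
  topo <- topology(4, 3, "dry_dynamic")
  H <- 5; T <- 3
  rng <- rng_stream(6, 99)
  set.seed(8)
  for (rep in 1:25) {
    n <- sample.int(12, 1) - 1L
    gids <- if (n > 0) sample(local_gids(240, topo, 0L), n, replace = TRUE)
            else integer(0)
    steps <- if (n > 0) sample.int(H, n, replace = TRUE) - 1L else integer(0)
    sec0 <- collocate_send_buffer(spike_register(gids, steps, topo), H, T,
                                  capacity = n + H * T + 3L)
    fd <- fill_dynamic(sec0, topo, H, N = 240, rng)
    expect_identical(fd$buffer[seq_along(sec0)], sec0) # rank 0 untouched
    dec <- decode_buffer(fd$buffer, 4, H, T)
    expect_true(buffer_locality_ok(dec, topo))
    counts0 <- section_part_counts(sec0, H, T)
    for (r in 1:3) {
      sec_r <- fd$buffer[(r * length(sec0) + 1):((r + 1) * length(sec0))]
      expect_identical(section_part_counts(sec_r, H, T), counts0)
    }
  }
})

test_that("an empty rank-0 section propagates zero activity", {
  topo <- topology(3, 2, "dry_dynamic")
  sec0 <- collocate_send_buffer(spike_register(integer(0), integer(0), topo),
                                H = 4, T = 2, capacity = 12L)
  fd <- fill_dynamic(sec0, topo, H = 4, N = 60, rng_stream(7, 99))
  expect_identical(nrow(decode_buffer(fd$buffer, 3, 4, 2)), 0L)
})

test_that("one spike in a part maps to one valid spike per fake rank", {
  topo <- topology(2, 3, "dry_dynamic")
  # single rank-0 spike: gid 6 = (rank 0, thread 0), at step 1
  sec0 <- collocate_send_buffer(spike_register(6L, 1L, topo), H = 4, T = 3,
                                capacity = 14L)
  fd <- fill_dynamic(sec0, topo, H = 4, N = 8, rng_stream(8, 99))
  dec <- decode_buffer(fd$buffer, 2, 4, 3)
  fake <- dec[dec$rank == 1, ]
  expect_identical(nrow(fake), 1L)
  expect_identical(fake$step, 1L)
  expect_identical(fake$thread, 0L)
  expect_identical(rank_of_gid(fake$gid, topo), 1L)
  expect_identical(thread_of_gid(fake$gid, topo), 0L)
})
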