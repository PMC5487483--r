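#' Emulated allgather
#'
#' The gather step of the emulated real mode: the global spike buffer is the
#' concatenation of the send-buffer sections of all ranks, in rank order.
#' Every emulated rank receives an identical copy, so one concatenation
#' stands for all of them.
#'
#' @param sections List of rank sections (integer vectors of equal length),
#'   in rank order `0..M-1`.
#' @return The global spike buffer (integer vector of length
#'   `M * capacity`).
#' @export
allgather_emulated <- function(sections) {
  caps <- lengths(sections)
  if (length(unique(caps)) > 1L) {
    stop("contract violation: send-buffer sections must have equal capacity")
  }
  unlist(sections, use.names = FALSE)
}

#' Static fake-spike fill state
#'
#' The static dry-run mode fills the entire global buffer with fake spikes
#' approximating a user-set target rate `F`. The expected number of spikes
#' per (rank, h-step, thread) buffer part is
#' `q = N * F * (min_delay / 1000) / (M * T * H)`; since per-part counts must
#' be integers, the count is varied between parts by a deterministic
#' error-diffusion accumulator whose carry persists across cycles, so the
#' long-run mean per part converges to `q`.
#'
#' @param N Total number of neurons.
#' @param F Target rate in Hz (> 0).
#' @param min_delay_ms Communication interval (ms).
#' @param topo A [topology()].
#' @param H h-steps per cycle.
#' @return A list of class `dryspike_static_state` with `q` and `carry`.
#' @export
static_fill_state <- function(N, F, min_delay_ms, topo, H) {
  if (F <= 0) stop("static target rate F must be > 0")
  q <- N * F * (min_delay_ms / 1000) / (topo$M * topo$T * H)
  structure(list(q = q, carry = 0), class = "dryspike_static_state")
}

#' Fill the global buffer with fake spikes at a target rate (static mode)
#'
#' Iterates the buffer parts in fixed (rank, h-step, thread) order; each part
#' receives `n = floor(carry + q)` fake spikes (updating the carry), with
#' GIDs drawn uniformly, with replacement, from the neurons local to the
#' part's (rank, thread). Every section is filled, including rank 0's: the
#' real spikes of the rank-0 neurons are ignored downstream in this mode.
#' Parts whose (rank, thread) shard holds no neurons drop their spikes with
#' a warning.
#'
#' @param state A [static_fill_state()]; the returned updated state must be
#'   threaded through consecutive cycles.
#' @param topo A [topology()].
#' @param H h-steps per cycle.
#' @param N Total number of neurons.
#' @param capacity Section capacity (slots).
#' @param rng The fake-spike [rng_stream()] of the physical process.
#' @return List with `buffer` (global buffer), `state` (updated), `counts`
#'   (per-part counts, parts in (rank, h-step, thread) order) and
#'   `n_dropped`.
#' @export
fill_static <- function(state, topo, H, N, capacity, rng) {
  M <- topo$M; T <- topo$T
  P <- M * H * T
  n_part <- diff(floor(state$carry + state$q * (0:P)))
  new_carry <- (state$carry + state$q * P) - sum(n_part)
  # part attributes in (rank, step, thread) order
  rank <- rep(seq_len(M) - 1L, each = H * T)
  thread <- rep(rep(seq_len(T) - 1L, times = H), times = M)
  vp <- rank + M * thread
  shard <- vp_shard_size(vp, N, topo)
  empty <- shard == 0L & n_part > 0
  n_dropped <- sum(n_part[empty])
  if (n_dropped > 0) {
    warning(sprintf("dropping %d fake spikes for empty (rank, thread) shards",
                    n_dropped))
    n_part[empty] <- 0L
  }
  part_vp <- rep.int(vp, n_part)
  gids <- if (length(part_vp)) {
    k <- rng_bounded(rng, rep.int(shard, n_part))
    vp_shard_gid(part_vp, k, topo)
  } else integer(0)
  part_rank <- rep.int(rank, n_part)
  part_step <- rep.int(rep(rep(seq_len(H) - 1L, each = T), times = M), n_part)
  part_thread <- rep.int(thread, n_part)
  sections <- lapply(seq_len(M) - 1L, function(r) {
    sel <- part_rank == r
    encode_section(gids[sel], part_step[sel], part_thread[sel], H, T, capacity)
  })
  list(buffer = allgather_emulated(sections),
       state = structure(list(q = state$q, carry = new_carry),
                         class = "dryspike_static_state"),
       counts = as.integer(n_part), n_dropped = n_dropped)
}

#' Replicate the rank-0 section into the fake ranks (dynamic mode)
#'
#' The dynamic dry-run mode preserves the spikes of the rank-0 neurons and
#' invents the remote input from them: the rank-0 section of the buffer is
#' copied, part by part, into the section of every fake rank, and each GID
#' is replaced by a uniform draw from the neurons that would be local to the
#' fake rank and the part's thread in the corresponding real run. The number
#' of fake spikes per fake rank therefore always equals the number of spikes
#' the rank-0 neurons generated, per part and per cycle. The rank-0 section
#' is left untouched.
#'
#' @param sec0 Collocated rank-0 section (from [collocate_send_buffer()]).
#' @param topo A [topology()].
#' @param H h-steps per cycle.
#' @param N Total number of neurons.
#' @param rng The fake-spike [rng_stream()] of the physical process.
#' @return List with `buffer` (global buffer, rank-0 section first) and
#'   `n_dropped`.
#' @export
fill_dynamic <- function(sec0, topo, H, N, rng) {
  M <- topo$M; T <- topo$T
  capacity <- length(sec0)
  counts <- section_part_counts(sec0, H, T)  # (step, thread) order
  step <- rep(rep(seq_len(H) - 1L, each = T), counts)
  thread <- rep(rep(seq_len(T) - 1L, times = H), counts)
  n_dropped <- 0L
  sections <- vector("list", M)
  sections[[1]] <- sec0
  for (r in seq_len(M - 1L)) {
    vp <- r + M * thread
    shard <- vp_shard_size(vp, N, topo)
    keep <- shard > 0L
    if (any(!keep)) {
      n_dropped <- n_dropped + sum(!keep)
      warning(sprintf(
        "dropping %d fake spikes for empty (rank %d, thread) shards",
        sum(!keep), r))
    }
    k <- rng_bounded(rng, shard[keep])
    gids <- vp_shard_gid(vp[keep], k, topo)
    sections[[r + 1L]] <- encode_section(gids, step[keep], thread[keep],
                                         H, T, capacity)
  }
  list(buffer = allgather_emulated(sections), n_dropped = n_dropped)
}
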