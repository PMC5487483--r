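#' Spike register
#'
#' Per-cycle staging structure for locally emitted spikes: the GIDs of the
#' spiking neurons sorted by thread and h-step. Represented flat as parallel
#' vectors with the thread derived from the GID.
#'
#' @param gids Emitting GIDs.
#' @param steps 0-based h-step offsets within the cycle (same length).
#' @param topo A [topology()].
#' @return A list of class `dryspike_register` with `gid`, `step`, `thread`.
#' @export
spike_register <- function(gids, steps, topo) {
  gids <- as.integer(gids)
  steps <- as.integer(steps)
  if (length(gids) != length(steps)) stop("gids and steps differ in length")
  check_gids(gids)
  if (length(steps) && any(steps < 0L)) stop("steps must be >= 0")
  structure(list(gid = gids, step = steps,
                 thread = thread_of_gid(gids, topo)),
            class = "dryspike_register")
}

# Encode one rank section: parts in (h-step-major, thread-minor) order, each
# part = its GIDs followed by one marker; the unused tail is padding.
encode_section <- function(gid, step, thread, H, T, capacity) {
  n <- length(gid)
  if (capacity < n + H * T) {
    stop(sprintf("section capacity %d too small for %d spikes + %d markers",
                 capacity, n, H * T))
  }
  counts <- tabulate(step * T + thread + 1L, nbins = H * T)
  sec <- rep.int(PAD, capacity)
  marker_pos <- cumsum(counts + 1L)
  sec[marker_pos] <- MARKER
  if (n > 0L) {
    ord <- order(step * T + thread, gid)
    starts <- c(1L, marker_pos[-length(marker_pos)] + 1L)
    nz <- counts > 0L
    pos <- rep.int(starts[nz], counts[nz]) + sequence(counts[nz]) - 1L
    sec[pos] <- gid[ord]
  }
  sec
}

#' Collocate the send buffer from the spike register
#'
#' Writes the register's GIDs into the (h-step, thread) parts of one
#' rank-section of the send buffer, delimited by communication markers, in
#' h-step-major, thread-minor order (GIDs ascending within a part, which is
#' their emission order). Unfilled tail slots are explicit padding. The
#' capacity must already accommodate the spikes; callers grow the buffer
#' first (see [grow_buffer()]).
#'
#' @param register A [spike_register()].
#' @param H h-steps per cycle.
#' @param T Threads per rank.
#' @param capacity Section capacity in slots; defaults to the minimum
#'   (`n_spikes + H * T` marker slots).
#' @return Integer vector of length `capacity` (the filled rank section).
#' @examples
#' reg <- spike_register(c(2, 4), c(0, 3), topology(2, 3))
#' collocate_send_buffer(reg, H = 4, T = 3)
#' @export
collocate_send_buffer <- function(register, H, T,
                                  capacity = length(register$gid) + H * T) {
  encode_section(register$gid, register$step, register$thread, H, T, capacity)
}

#' Decode a spike buffer
#'
#' Inverse of the buffer encoding: recovers `(rank, h-step, thread, gid)`
#' for every GID entry of a global buffer (or of a single section when
#' `M = 1`).
#'
#' @param buf Integer buffer (concatenated equal-capacity rank sections).
#' @param M Number of rank sections.
#' @param H h-steps per cycle.
#' @param T Threads per rank.
#' @return Data frame with columns `rank`, `step`, `thread`, `gid`.
#' @export
decode_buffer <- function(buf, M, H, T) {
  M <- as.integer(M); H <- as.integer(H); T <- as.integer(T)
  if (length(buf) %% M != 0L) stop("buffer length not a multiple of M")
  capacity <- length(buf) %/% M
  rank <- rep(seq_len(M) - 1L, each = capacity)
  is_marker <- buf == MARKER
  if (sum(is_marker) != M * H * T) {
    stop(sprintf("malformed buffer: expected %d markers, found %d",
                 M * H * T, sum(is_marker)))
  }
  # part index of a GID slot = markers before it within its own section
  part <- as.integer(cumsum(is_marker)) - rep((seq_len(M) - 1L) * H * T,
                                              each = capacity)
  keep <- buf >= 1L
  part <- part[keep]
  if (any(part < 0L | part >= H * T)) {
    stop("malformed buffer: GID outside the marker structure of its section")
  }
  data.frame(rank = rank[keep], step = part %/% T, thread = part %% T,
             gid = buf[keep])
}

#' Check buffer part locality
#'
#' Verifies that every GID of a decoded buffer is local to its part's
#' (rank, thread) under the round-robin formulas. This holds after every
#' gather in all three modes.
#'
#' @param decoded Result of [decode_buffer()].
#' @param topo A [topology()].
#' @return `TRUE` if all entries are local to their part.
#' @export
buffer_locality_ok <- function(decoded, topo) {
  nrow(decoded) == 0L ||
    (all(rank_of_gid(decoded$gid, topo) == decoded$rank) &&
     all(thread_of_gid(decoded$gid, topo) == decoded$thread))
}

#' Grow the send-buffer capacity
#'
#' The per-rank section capacity is a high-water mark: it equals the maximum
#' number of spikes any rank emitted in any cycle so far, plus the `H * T`
#' marker slots. Growth applies identically to every rank section and the
#' capacity never shrinks.
#'
#' @param capacity Current section capacity.
#' @param max_hist_spikes Historical per-cycle per-rank spike maximum.
#' @param H h-steps per cycle.
#' @param T Threads per rank.
#' @return The new capacity (>= `capacity`).
#' @export
grow_buffer <- function(capacity, max_hist_spikes, H, T) {
  max(capacity, as.integer(max_hist_spikes) + H * T)
}

# Per-part spike counts of one section, in (h-step, thread) order.
section_part_counts <- function(sec, H, T) {
  is_marker <- sec == MARKER
  if (sum(is_marker) != H * T) stop("malformed section")
  part <- cumsum(is_marker)[sec >= 1L]
  tabulate(part + 1L, nbins = H * T)
}
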