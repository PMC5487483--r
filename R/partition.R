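#' Conceptual machine topology
#'
#' Describes the layout of the conceptually distributed machine: `M` MPI-style
#' ranks with `T` threads each, for a total of `M * T` virtual processes (VPs).
#' In the dry-run modes exactly one physical process exists and plays rank 0;
#' the remaining ranks are *fake ranks* that exist only as buffer sections and
#' locality constraints. In `real_emulated` mode all `M` ranks are simulated
#' sequentially by the same process, which serves as the validation oracle.
#'
#' @param num_ranks Number of (fake) MPI ranks `M` (positive integer).
#' @param threads_per_rank Number of threads per rank `T` (positive integer).
#' @param mode One of `"real_emulated"`, `"dry_static"`, `"dry_dynamic"`.
#' @return An object of class `dryspike_topology` with fields `M`, `T`,
#'   `mode`, `physical_rank` (always 0) and `VP = M * T`.
#' @examples
#' topology(24, 2, "dry_dynamic")
#' @export
topology <- function(num_ranks, threads_per_rank = 1L,
                     mode = c("real_emulated", "dry_static", "dry_dynamic")) {
  mode <- match.arg(mode)
  M <- as.integer(num_ranks)
  T <- as.integer(threads_per_rank)
  if (is.na(M) || M < 1L) stop("num_ranks must be a positive integer")
  if (is.na(T) || T < 1L) stop("threads_per_rank must be a positive integer")
  structure(list(M = M, T = T, mode = mode, physical_rank = 0L, VP = M * T),
            class = "dryspike_topology")
}

#' @export
print.dryspike_topology <- function(x, ...) {
  cat(sprintf("<topology> M = %d rank(s) x T = %d thread(s) = %d VPs, mode %s\n",
              x$M, x$T, x$VP, x$mode))
  invisible(x)
}

check_gids <- function(gid) {
  if (length(gid) == 0L) return(invisible(gid))
  if (anyNA(gid) || any(gid < 1)) {
    stop("invalid GID: GIDs are positive integers (GID 0 is reserved)")
  }
  invisible(gid)
}

#' Home rank of a GID
#'
#' Neurons are distributed round-robin over ranks by their global identifier:
#' the home rank of `gid` is `gid %% M`. Vectorised over `gid`.
#'
#' @param gid Positive integer GID(s); GID 0 is reserved.
#' @param topo A [topology()].
#' @return Integer rank index in `[0, M)`.
#' @examples
#' rank_of_gid(1:8, topology(2))
#' @export
rank_of_gid <- function(gid, topo) {
  check_gids(gid)
  as.integer(gid %% topo$M)
}

#' Home thread of a GID
#'
#' Within its home rank a neuron is assigned to thread
#' `(gid %% (M * T)) %/% M` (integer division), completing the round-robin
#' distribution over the `M * T` virtual processes.
#'
#' @inheritParams rank_of_gid
#' @return Integer thread index in `[0, T)`.
#' @examples
#' thread_of_gid(1:12, topology(2, 3))
#' @export
thread_of_gid <- function(gid, topo) {
  check_gids(gid)
  as.integer((gid %% (topo$M * topo$T)) %/% topo$M)
}

#' Virtual process of a GID
#'
#' The virtual process id `vp = gid %% (M * T)` identifies one
#' (rank, thread) slot: `rank = vp %% M`, `thread = vp %/% M`. All random
#' streams of the simulation are keyed by `vp`, so results of the emulated
#' real mode do not depend on how `M * T` is factorised.
#'
#' @inheritParams rank_of_gid
#' @return Integer VP index in `[0, M * T)`.
#' @export
vp_of_gid <- function(gid, topo) {
  check_gids(gid)
  as.integer(gid %% (topo$M * topo$T))
}

#' Rank-local neuron GIDs
#'
#' Enumerates, in ascending order, the GIDs in `1..N` whose home rank is
#' `rank`. The shards of all ranks partition `1..N` and differ in size by at
#' most one (load balance of the round-robin distribution).
#'
#' @param N Total number of neurons.
#' @param topo A [topology()].
#' @param rank Rank index in `[0, M)`.
#' @return Integer vector of local GIDs (possibly empty).
#' @examples
#' local_gids(8, topology(2), rank = 0)
#' @export
local_gids <- function(N, topo, rank) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 0L || rank >= topo$M) {
    stop(sprintf("invalid rank %d: must lie in [0, %d)", rank, topo$M))
  }
  first <- if (rank == 0L) topo$M else rank
  if (first > N) return(integer(0))
  seq.int(first, N, by = topo$M)
}

#' Neuron shard of a virtual process
#'
#' `vp_shard_size()` counts the neurons in `1..N` that live on virtual
#' process `vp`; `vp_shard_gid()` maps 0-based shard indices back to GIDs.
#' Used to draw fake-spike GIDs uniformly from a (rank, thread) slot without
#' enumerating the shard.
#'
#' @param vp Virtual process id(s) in `[0, M * T)`.
#' @param N Total number of neurons.
#' @param topo A [topology()].
#' @param k 0-based index (or indices) into the shard.
#' @return Shard sizes, or GIDs, as integers.
#' @export
vp_shard_size <- function(vp, N, topo) {
  MT <- topo$VP
  as.integer(ifelse(vp == 0L, N %/% MT,
                    ifelse(vp > N, 0L, (N - vp) %/% MT + 1L)))
}

#' @rdname vp_shard_size
#' @export
vp_shard_gid <- function(vp, k, topo) {
  MT <- topo$VP
  as.integer(ifelse(vp == 0L, (k + 1L) * MT, vp + k * MT))
}
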