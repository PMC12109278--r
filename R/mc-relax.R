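#' Topology-preserving Monte Carlo relaxation
#'
#' Stochastic conformational mixing by crankshaft rotations of contiguous
#' sub-chains (and, for replication intermediates with `forks_free = TRUE`,
#' fork-twist rotations of terminal blocks about the local duplex axis,
#' which transfer torsion across the forks).  Moves are accepted purely on
#' geometric constraints: a hard-core excluded-volume guard checked at
#' interpolated rotation angles (a strand-passage guard, so linking numbers
#' are conserved) and a bond-stretch guard at block boundaries.  There is
#' no energy function; the sampler mixes conformations at fixed topology,
#' emulating stress redistribution after deproteinization rather than any
#' particular thermodynamic ensemble.
#'
#' For closed duplexes the total Lk is conserved exactly; for replication
#' intermediates the total linking difference is conserved while the
#' per-region charges can redistribute only when `forks_free = TRUE`
#' (with fixed forks, sites within 3 bp of each fork junction are anchored).
#'
#' @param x a [duplex_conformation()], [replication_intermediate()] or
#'   [trajectory_frame()].
#' @param n_moves number of attempted moves.
#' @param forks_free allow torsion transfer across the fork junctions
#'   (replication intermediates only).
#' @param seed integer seed (uses the current RNG state when `NULL`).
#' @param max_angle maximum rotation per move, rad (default 0.5).
#' @param block_range sub-chain length range in sites (default 4 to 50).
#' @param hardcore strand-level hard-core distance, nm (default 1.7,
#'   enforcing the 2 nm duplex-axis clearance).
#' @param bond_slack maximum deviation of any backbone bond from its
#'   starting length, nm (default 1).
#' @param fork_move_prob probability that a move is a fork-twist rather
#'   than a crankshaft rotation (replication intermediates with
#'   `forks_free = TRUE` only; default 0.25).
#' @param n_frames number of frames to record (evenly spaced in moves).
#' @return A list of [trajectory_frame()]s, pseudo-time = cumulative move
#'   count; the last frame is the final conformation.  The acceptance rate
#'   is attached as attribute `"acceptance"`.
#' @export
mc_relax <- function(x, n_moves, forks_free = FALSE, seed = NULL,
                     max_angle = 0.5, block_range = c(4, 50),
                     hardcore = 1.7, bond_slack = 1.0,
                     fork_move_prob = 0.25, n_frames = 10) {
  if (inherits(x, "trajectory_frame")) x <- x$conformation
  if (n_moves < 0) stop("n_moves must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  is_ri <- inherits(x, "replication_intermediate")
  if (!is_ri && !inherits(x, "duplex_conformation"))
    stop("mc_relax needs a duplex_conformation or replication_intermediate")

  if (is_ri) {
    n_par <- x$n_parental; n_u <- x$n_unrep; n_r <- x$n_rep
    P <- rbind(x$parentalA$points, x$parentalB$points,
               x$daughter_new1$points, x$daughter_new2$points)
    sid <- c(rep(0L, n_par), rep(1L, n_par), rep(2L, n_r), rep(3L, n_r))
    rix <- c(0:(n_par - 1), 0:(n_par - 1),
             n_u:(n_par - 1), n_u:(n_par - 1))
  } else {
    n_par <- x$n_bp; n_u <- n_par
    P <- rbind(x$strandA$points, x$strandB$points)
    sid <- c(rep(0L, n_par), rep(1L, n_par))
    rix <- c(0:(n_par - 1), 0:(n_par - 1))
  }

  if (n_moves == 0) return(list(trajectory_frame(0, x)))

  res <- mc_relax_cpp(P, sid, rix, n_par, n_u, is_ri, forks_free,
                      as.integer(n_moves), max_angle,
                      as.integer(block_range[1]),
                      as.integer(block_range[2]),
                      hardcore, bond_slack, as.integer(n_frames),
                      fork_move_prob)

  rebuild <- function(Pnew) {
    if (is_ri) {
      iA <- 1:n_par; iB <- n_par + iA
      i1 <- 2 * n_par + 1:n_r; i2 <- 2 * n_par + n_r + 1:n_r
      pA <- strand_curve(Pnew[iA, , drop = FALSE], closed = TRUE,
                         region = x$parentalA$region)
      pB <- strand_curve(Pnew[iB, , drop = FALSE], closed = TRUE,
                         region = x$parentalB$region)
      d1 <- strand_curve(Pnew[i1, , drop = FALSE],
                         region = "replicated_daughter1",
                         nt_index = x$daughter_new1$nt_index)
      d2 <- strand_curve(Pnew[i2, , drop = FALSE],
                         region = "replicated_daughter2",
                         nt_index = x$daughter_new2$nt_index)
      replication_intermediate(pA, pB, d1, d2, n_unrep = n_u,
                               helical_repeat = x$helical_repeat)
    } else {
      duplex_conformation(
        strand_curve(Pnew[1:n_par, , drop = FALSE], closed = TRUE),
        strand_curve(Pnew[n_par + 1:n_par, , drop = FALSE], closed = TRUE),
        helical_repeat = x$helical_repeat,
        check_separation = FALSE)
    }
  }

  nf <- res$n_frames_filled
  every <- max(1, floor(n_moves / n_frames))
  frames <- vector("list", nf)
  for (k in seq_len(nf))
    frames[[k]] <- trajectory_frame(k * every, rebuild(res$frames[[k]]))
  if (nf == 0 ||
      max(abs(frames[[nf]]$conformation |> all_points() - res$points)) > 0)
    frames[[nf + 1]] <- trajectory_frame(n_moves, rebuild(res$points))
  attr(frames, "acceptance") <- res$acceptance
  frames
}
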