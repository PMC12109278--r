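#' Closed circular duplex conformation
#'
#' Two closed strand curves of equal length winding about a common axis.
#' One point per strand per base pair, in nm.
#'
#' @param strandA,strandB closed [strand_curve()]s with equal point counts.
#' @param helical_repeat bp per turn of relaxed B-DNA (default 10.5).
#' @param check_separation validate that the per-index strand separation is
#'   within the 1.5-2.5 nm duplex window (disable for deliberately
#'   distorted fixtures).
#' @return An object of class `duplex_conformation`.
#' @export
duplex_conformation <- function(strandA, strandB, helical_repeat = 10.5,
                                check_separation = TRUE) {
  stopifnot(is_strand_curve(strandA), is_strand_curve(strandB))
  if (!strandA$closed || !strandB$closed)
    stop("both strands of a duplex conformation must be closed")
  n <- nrow(strandA$points)
  if (nrow(strandB$points) != n)
    stop("strands must have equal point counts (one per base pair)")
  if (check_separation) {
    sep <- sqrt(rowSums((strandA$points - strandB$points)^2))
    if (any(sep < 1.5 | sep > 2.5))
      stop(sprintf(paste0("strand separation out of the duplex window ",
                          "[1.5, 2.5] nm at index %d (%.2f nm)"),
                   which(sep < 1.5 | sep > 2.5)[1] - 1,
                   sep[which(sep < 1.5 | sep > 2.5)[1]]))
  }
  structure(list(strandA = strandA, strandB = strandB, n_bp = n,
                 helical_repeat = helical_repeat),
            class = "duplex_conformation")
}

#' @export
print.duplex_conformation <- function(x, ...) {
  cat(sprintf("<duplex_conformation> %d bp, helical repeat %.2f bp/turn\n",
              x$n_bp, x$helical_repeat))
  invisible(x)
}

#' Duplex axis (midpoint) curve
#'
#' Midpoints of paired strand positions, one per base pair.
#'
#' @param x a `duplex_conformation`.
#' @return A closed `strand_curve` with region label `"axis"`.
#' @export
duplex_axis <- function(x) {
  stopifnot(inherits(x, "duplex_conformation"))
  strand_curve((x$strandA$points + x$strandB$points) / 2, closed = TRUE,
               nt_index = x$strandA$nt_index, region = "axis")
}

#' Partially replicated circular molecule
#'
#' A replication intermediate (RI): two closed parental strand curves, each
#' the concatenation of an unreplicated part (a1 or b1) and a replicated
#' part (a2 or b2), plus the two newly synthesized daughter strands.  a2
#' pairs with `daughter_new1`, b2 with `daughter_new2`.  The two replication
#' forks sit between parental indices `n_unrep - 1` and `n_unrep`, and
#' between `n_parental - 1` and `0` (0-based).
#'
#' @param parentalA,parentalB closed [strand_curve()]s of equal length with
#'   per-point region labels: the first `n_unrep` points `"unreplicated"`,
#'   the rest `"replicated_daughter1"` (A) / `"replicated_daughter2"` (B).
#' @param daughter_new1,daughter_new2 open `strand_curve`s with `n_rep`
#'   points pairing with a2 and b2 respectively.
#' @param n_unrep number of unreplicated base pairs.
#' @param helical_repeat bp per turn (default 10.5).
#' @return An object of class `replication_intermediate`.
#' @export
replication_intermediate <- function(parentalA, parentalB,
                                     daughter_new1, daughter_new2,
                                     n_unrep, helical_repeat = 10.5) {
  stopifnot(is_strand_curve(parentalA), is_strand_curve(parentalB),
            is_strand_curve(daughter_new1), is_strand_curve(daughter_new2))
  if (!parentalA$closed || !parentalB$closed)
    stop("parental strands must be closed")
  n <- nrow(parentalA$points)
  if (nrow(parentalB$points) != n)
    stop("parental strands must have equal point counts")
  n_unrep <- as.integer(n_unrep)
  n_rep <- n - n_unrep
  if (n_unrep < 3 || n_rep < 3)
    stop("both regions need at least 3 bp")
  if (nrow(daughter_new1$points) != n_rep ||
      nrow(daughter_new2$points) != n_rep)
    stop("daughter strands must have n_rep = ", n_rep, " points")
  expA <- c(rep("unreplicated", n_unrep),
            rep("replicated_daughter1", n_rep))
  expB <- c(rep("unreplicated", n_unrep),
            rep("replicated_daughter2", n_rep))
  if (!identical(parentalA$region, expA) ||
      !identical(parentalB$region, expB))
    stop("parental region labels must partition into the unreplicated ",
         "prefix and the replicated suffix")
  structure(list(parentalA = parentalA, parentalB = parentalB,
                 daughter_new1 = daughter_new1,
                 daughter_new2 = daughter_new2,
                 n_unrep = n_unrep, n_rep = n_rep,
                 n_parental = n,
                 fork_indices = c(n_unrep - 1L, n - 1L),
                 helical_repeat = helical_repeat),
            class = "replication_intermediate")
}

#' @export
print.replication_intermediate <- function(x, ...) {
  cat(sprintf(paste0("<replication_intermediate> %d bp parental ",
                     "(%d unreplicated + %d replicated), h = %.2f\n"),
              x$n_parental, x$n_unrep, x$n_rep, x$helical_repeat))
  invisible(x)
}

# The three duplexes of an RI as (strand1, strand2, region, closed) records.
ri_duplexes <- function(ri) {
  iu <- seq_len(ri$n_unrep)
  ir <- (ri$n_unrep + 1):ri$n_parental
  list(
    unreplicated = list(
      A = ri$parentalA$points[iu, , drop = FALSE],
      B = ri$parentalB$points[iu, , drop = FALSE],
      region = "unreplicated", closed = FALSE,
      arc_bp = iu - 1L),
    daughter1 = list(
      A = ri$parentalA$points[ir, , drop = FALSE],
      B = ri$daughter_new1$points,
      region = "replicated_daughter1", closed = FALSE,
      arc_bp = seq_len(ri$n_rep) - 1L),
    daughter2 = list(
      A = ri$parentalB$points[ir, , drop = FALSE],
      B = ri$daughter_new2$points,
      region = "replicated_daughter2", closed = FALSE,
      arc_bp = seq_len(ri$n_rep) - 1L)
  )
}

# All nucleotide positions of a conformation, stacked (for Rg and I/O).
all_points <- function(x) {
  if (inherits(x, "duplex_conformation"))
    rbind(x$strandA$points, x$strandB$points)
  else if (inherits(x, "replication_intermediate"))
    rbind(x$parentalA$points, x$parentalB$points,
          x$daughter_new1$points, x$daughter_new2$points)
  else if (inherits(x, "trajectory_frame")) all_points(x$conformation)
  else if (inherits(x, "strand_set"))
    do.call(rbind, lapply(x$strands, function(s) s$points))
  else curve_points(x)
}

#' @export
print.strand_set <- function(x, ...) {
  cat(sprintf("<strand_set> %d strands (%s points)\n", length(x$strands),
              paste(vapply(x$strands, length, 0L), collapse = ", ")))
  invisible(x)
}
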