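#' Gauss linking charge of two straight segments
#'
#' Evaluates the Gauss double integral over two straight segments in closed
#' form (the signed solid angle of the quadrilateral spanned by the four
#' end-to-end vectors, divided by 4 pi).  Summed over all segment pairs of
#' two closed curves this gives their linking number.  The charge is
#' antisymmetric under reversal of either segment's orientation and vanishes
#' for coplanar segments.
#'
#' @param p1,p2 numeric length-3: start and end of the first segment (nm).
#' @param q1,q2 numeric length-3: start and end of the second segment (nm).
#' @return The linking charge in turns (solid angle / 4 pi).
#' @export
#' @examples
#' segment_pair_charge(c(0, 0, 0), c(1, 0, 0), c(0.5, -0.5, 1), c(0.5, 0.5, 1))
segment_pair_charge <- function(p1, p2, q1, q2) {
  stopifnot(length(p1) == 3, length(p2) == 3, length(q1) == 3,
            length(q2) == 3)
  if (vnorm(p2 - p1) < 1e-12 || vnorm(q2 - q1) < 1e-12)
    stop("segments must have positive length")
  if (seg_dist_cpp(p1, p2, q1, q2) < 1e-9)
    stop("degenerate geometry: segments intersect or touch")
  gauss_pair_charge_cpp(p1, p2, q1, q2)
}

#' Per-segment-pair linking contribution matrix
#'
#' Entry (i, j) is the Gauss linking charge between segment i of `curveA`
#' and segment j of `curveB`; for two closed curves the entries sum to
#' their linking number.  For a partially replicated molecule the matrix is
#' partitioned at the fork indices into the a1 x b1, a1 x b2, a2 x b1 and
#' a2 x b2 blocks whose sums are the three terms of the block decomposition
#' of Lk.
#'
#' @param curveA,curveB [strand_curve()]s (or plain point matrices, taken
#'   as open).
#' @param block_bounds optional integer vector of 0-based segment indices
#'   starting each block (e.g. `c(0, n_unrep)`), applied to both axes.
#' @return An object of class `contribution_matrix`: a list with `entries`
#'   (dense numeric matrix, turns), `block_bounds`, and the two curve
#'   closure flags.
#' @export
contribution_matrix <- function(curveA, curveB, block_bounds = NULL) {
  A <- curve_points(curveA); B <- curve_points(curveB)
  ca <- curve_closed(curveA); cb <- curve_closed(curveB)
  M <- gauss_matrix_cpp(A, ca, B, cb)
  if (any(!is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
    stop(sprintf("degenerate segment pair at (i = %d, j = %d)",
                 bad[1] - 1L, bad[2] - 1L))
  }
  structure(list(entries = M, block_bounds = block_bounds,
                 closedA = ca, closedB = cb),
            class = "contribution_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf("<contribution_matrix> %d x %d segments, total charge %.4f\n",
              nrow(x$entries), ncol(x$entries), sum(x$entries)))
  if (!is.null(x$block_bounds))
    cat("  block bounds:", paste(x$block_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname contribution_matrix
#' @param x a `contribution_matrix`.
#' @param ... unused.
#' @export
as_tibble.contribution_matrix <- function(x, ...) {
  M <- x$entries
  tibble::tibble(
    i = rep(seq_len(nrow(M)) - 1L, times = ncol(M)),
    j = rep(seq_len(ncol(M)) - 1L, each = nrow(M)),
    charge = as.vector(M))
}

#' Block sums of a contribution matrix
#'
#' @param x a `contribution_matrix` with block bounds.
#' @return A tibble with one row per block pair: `row_block`, `col_block`,
#'   `charge`.
#' @export
block_sums <- function(x) {
  stopifnot(inherits(x, "contribution_matrix"))
  bb <- x$block_bounds
  if (is.null(bb)) bb <- 0L
  rblk <- findInterval(0:(nrow(x$entries) - 1), bb)
  cblk <- findInterval(0:(ncol(x$entries) - 1), bb)
  nb <- length(bb)
  out <- expand.grid(row_block = seq_len(nb), col_block = seq_len(nb))
  out$charge <- mapply(function(r, c)
    sum(x$entries[rblk == r, cblk == c]), out$row_block, out$col_block)
  tibble::as_tibble(out)
}

#' Linking number of two closed curves
#'
#' The Gauss linking integral, computed as the sum of all segment-pair
#' charges.  Exact (up to floating point) for polygonal curves, hence
#' within 1e-3 of an integer for any non-touching closed pair.
#'
#' @param curveA,curveB closed [strand_curve()]s.
#' @return The linking number in turns.
#' @export
linking_number <- function(curveA, curveB) {
  if (!curve_closed(curveA, TRUE) || !curve_closed(curveB, TRUE))
    stop("linking_number requires two closed curves")
  A <- curve_points(curveA); B <- curve_points(curveB)
  sum(gauss_block_sums_cpp(A, TRUE, B, TRUE, 0L, 0L))
}

#' Writhe of a curve
#'
#' Gauss self-linking integral of the curve's axis: the double integral
#' over distinct segment pairs (each unordered pair counted twice).  Open
#' curves are closed by the implicit straight segment from the last point
#' back to the first (the fork-closure convention for the open regions of a
#' replication intermediate).
#'
#' @param curve a [strand_curve()] or point matrix.
#' @return Writhe in turns; 0 for planar curves, negated by mirror imaging.
#' @export
writhe <- function(curve) {
  P <- curve_points(curve)
  wr <- writhe_cpp(P)
  if (!is.finite(wr)) stop("degenerate self-touching curve")
  wr
}

#' Twist of a duplex region about its axis
#'
#' Sum over successive base-pair frames of the signed rotation of the
#' strand-offset vector about the local axis tangent, divided by 2 pi.
#' Offsets are parallel-transported between frames (minimal rotation
#' carrying one tangent onto the next) so that pure bending contributes no
#' twist.
#'
#' @param strandA,strandB equal-length strand regions ([strand_curve()]s or
#'   point matrices).
#' @param axis their midpoint axis (defaults to the pointwise midpoint).
#' @param closed treat the region as closed (wraps the frame sequence).
#' @return Twist in turns.
#' @export
duplex_twist <- function(strandA, strandB, axis = NULL, closed = NULL) {
  A <- curve_points(strandA); B <- curve_points(strandB)
  if (nrow(A) != nrow(B)) stop("strand regions must have equal length")
  if (is.null(closed))
    closed <- curve_closed(strandA) && curve_closed(strandB)
  M <- if (is.null(axis)) (A + B) / 2 else curve_points(axis)
  if (nrow(M) != nrow(A)) stop("axis must match the strand region length")
  n <- nrow(A)
  # edge tangents; the offset at each vertex is projected perpendicular to
  # the edge it starts (the final vertex of an open region reuses the last
  # edge) and parallel-transported across vertices by the minimal rotation
  # carrying one edge tangent onto the next.  With this discrete twist the
  # polygonal ribbon satisfies Tw + Wr = Lk to floating-point accuracy.
  if (closed) {
    nxt <- c(2:n, 1)
    tang <- rowunit(M[nxt, , drop = FALSE] - M)
    t_at <- tang
    from <- 1:n
    to <- nxt
    t_next <- tang[nxt, , drop = FALSE]
  } else {
    tang <- rowunit(M[2:n, , drop = FALSE] - M[1:(n - 1), , drop = FALSE])
    t_at <- tang[c(1:(n - 1), n - 1), , drop = FALSE]  # per vertex
    from <- 1:(n - 1)
    to <- 2:n
    t_next <- t_at[to, , drop = FALSE]
  }
  u <- A - M
  u <- u - t_at * rowdot(u, t_at)
  if (any(rownorm(u) < 1e-9))
    stop("zero-length strand offset: strand touches the axis")
  u <- rowunit(u)
  u1 <- u[from, , drop = FALSE]
  t1 <- t_at[from, , drop = FALSE]
  u2 <- u[to, , drop = FALSE]
  axis_v <- rowcross(t1, t_next)
  s <- rownorm(axis_v)
  c_ <- rowdot(t1, t_next)
  k <- rowunit(axis_v)
  u1r <- u1 * c_ + rowcross(k, u1) * s + k * rowdot(k, u1) * (1 - c_)
  nz <- s <= 1e-12
  if (any(nz)) u1r[nz, ] <- u1[nz, , drop = FALSE]
  u2p <- u2 - t_next * rowdot(u2, t_next)
  ang <- atan2(rowdot(rowcross(u1r, u2p), t_next), rowdot(u1r, u2p))
  sum(ang) / (2 * pi)
}

#' Relaxed linking number, linking difference and superhelical density
#'
#' `lk0()` is N / h, the linking number of torsionally relaxed B-DNA;
#' `delta_lk()` is Lk - Lk0; `superhelical_density()` is delta Lk / Lk0.
#'
#' @param n_bp number of base pairs (> 0).
#' @param h helical repeat in bp/turn (> 0, default 10.5).
#' @return `lk0`: turns.
#' @export
lk0 <- function(n_bp, h = 10.5) {
  if (any(n_bp <= 0) || any(h <= 0)) stop("n_bp and h must be positive")
  n_bp / h
}

#' @rdname lk0
#' @param lk measured linking number (turns).
#' @param lk0 relaxed linking number (turns).
#' @export
delta_lk <- function(lk, lk0) lk - lk0

#' @rdname lk0
#' @param dlk linking number difference (turns).
#' @export
superhelical_density <- function(dlk, lk0) {
  if (any(lk0 == 0)) stop("lk0 must be nonzero")
  dlk / lk0
}

#' Radius of gyration
#'
#' Root mean squared distance of a point set to its center of mass.
#'
#' @param points an n x 3 matrix of positions (nm), or any conformation
#'   object (all nucleotide positions are used).
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(points) {
  P <- all_points(points)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  if (nrow(P) < 1) stop("radius_of_gyration needs at least one point")
  cm <- colMeans(P)
  sqrt(mean(rowSums((P - matrix(cm, nrow(P), 3, byrow = TRUE))^2)))
}

#' Diagonal band profile of a contribution matrix
#'
#' Splits a square contribution matrix into the main diagonal band (cyclic
#' index distance at most `band_halfwidth_bp`), which carries the positive
#' charge of the double helix, and the off-band remainder, where plectonemic
#' forms appear as contiguous charge ridges ("secondary diagonals").
#' The contacts of one interwound arm all share the same contour midpoint
#' (a crossing between positions u and v sits at the anti-diagonal
#' coordinate u + v, twice the hairpin position), so off-band charge is
#' projected onto the cyclic anti-diagonal coordinate and secondary bands
#' are counted as contiguous runs of that 1D profile whose smoothed
#' per-bin charge exceeds `profile_threshold` and whose total absolute
#' charge reaches `band_charge_min`.
#'
#' @param matrix a square [contribution_matrix()].
#' @param band_halfwidth_bp half-width of the main band in bp (default 15,
#'   about 1.5 helical turns).
#' @param smooth_bp moving-average window for the anti-diagonal profile
#'   (default 21 bp).
#' @param profile_threshold per-bin charge magnitude starting/ending a run
#'   (turns/bp; default 0.005).
#' @param band_charge_min minimum absolute summed charge for a run to be
#'   reported as a secondary band (turns; default 0.3).
#' @return A list with `main_band_sum`, `off_band_sum` (turns),
#'   `n_secondary_bands` and the anti-diagonal `profile` (length-n numeric).
#' @export
diagonal_band_profile <- function(matrix, band_halfwidth_bp = 15,
                                  smooth_bp = 21,
                                  profile_threshold = 0.005,
                                  band_charge_min = 0.3) {
  stopifnot(inherits(matrix, "contribution_matrix"))
  M <- matrix$entries
  n <- nrow(M)
  if (ncol(M) != n) stop("band profile requires a square matrix")
  w <- as.integer(band_halfwidth_bp)
  if (w >= n / 2) stop("band halfwidth must be below n/2")
  d <- abs(row(M) - col(M))
  cyc <- pmin(d, n - d)
  inband <- cyc <= w
  off <- M
  off[inband] <- 0
  # cyclic anti-diagonal coordinate a = (i + j) mod n, 0-based
  a <- (row(M) + col(M) - 2L) %% n
  prof <- vapply(split(off, a), sum, 0)[as.character(0:(n - 1))]
  prof[is.na(prof)] <- 0
  # cyclic moving average
  k <- max(1L, as.integer(smooth_bp))
  kern <- rep(1 / k, k)
  ext <- c(prof[(n - k + 1):n], prof, prof[1:k])
  sm <- stats::filter(ext, kern, sides = 2)[(k + 1):(k + n)]
  hot <- abs(sm) >= profile_threshold
  # contiguous cyclic runs
  nb <- 0L
  if (any(hot) && !all(hot)) {
    r <- rle(hot)
    # rotate so the sequence starts in a cold stretch
    start <- which(!hot)[1]
    hot2 <- hot[c(start:n, seq_len(start - 1))]
    prof2 <- prof[c(start:n, seq_len(start - 1))]
    r <- rle(hot2)
    ends <- cumsum(r$lengths)
    begins <- c(1, head(ends, -1) + 1)
    for (q in seq_along(r$values)) {
      if (!r$values[q]) next
      charge <- sum(prof2[begins[q]:ends[q]])
      if (abs(charge) >= band_charge_min) nb <- nb + 1L
    }
  } else if (all(hot)) nb <- 1L
  list(main_band_sum = sum(M[inband]),
       off_band_sum = sum(off),
       n_secondary_bands = nb,
       profile = as.numeric(prof))
}
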