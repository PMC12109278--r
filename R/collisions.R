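# Juxtaposition (collision) detection on reduced midpoint curves, crossing
# chirality/sign assignment, and the four-type classification for
# replication intermediates.

#' Midpoint curve of a duplex region
#'
#' One point per base pair, the midpoint of the two paired strand
#' positions.
#'
#' @param strandA,strandB paired strand regions of equal length
#'   ([strand_curve()]s or point matrices).
#' @param region region label carried by the resulting curve.
#' @param closed closure flag of the resulting curve.
#' @return A `strand_curve` with region label `region`.
#' @export
midpoint_curve <- function(strandA, strandB, region = "axis",
                           closed = NULL) {
  A <- curve_points(strandA); B <- curve_points(strandB)
  if (nrow(A) != nrow(B))
    stop("paired strand regions must have equal length")
  if (is.null(closed))
    closed <- curve_closed(strandA) && curve_closed(strandB)
  nt <- if (is_strand_curve(strandA)) strandA$nt_index else NULL
  strand_curve((A + B) / 2, closed = closed, nt_index = nt,
               region = region)
}

#' Reduced midpoint curve
#'
#' Every `step`-th point of a midpoint curve (default every 10 nucleotides,
#' about one helical turn), the sampling used for collision detection.
#'
#' @param midpoints a `strand_curve` (typically from [midpoint_curve()]).
#' @param step sampling stride in points (>= 1).
#' @param offset 0-based index of the first retained point.
#' @return A `reduced_curve`: a `strand_curve` with attributes
#'   `source_index` (0-based indices into the parent curve) and
#'   `arc_bp` (contour coordinate of each retained point, in bp).
#' @export
reduce_curve <- function(midpoints, step = 10, offset = 0) {
  stopifnot(is_strand_curve(midpoints))
  if (step < 1) stop("step must be >= 1")
  n <- nrow(midpoints$points)
  keep <- seq(1 + offset, n, by = step)
  out <- strand_curve(midpoints$points[keep, , drop = FALSE],
                      closed = midpoints$closed,
                      nt_index = midpoints$nt_index[keep],
                      region = midpoints$region[keep])
  attr(out, "source_index") <- keep - 1L
  attr(out, "arc_bp") <- keep - 1L
  class(out) <- c("reduced_curve", class(out))
  out
}

#' Minimum distance between two segments
#'
#' Clamped segment-segment minimum Euclidean distance: the skew-line
#' formula when both closest-approach feet fall inside the segments,
#' otherwise the endpoint/edge minimum; parallel and degenerate cases fall
#' back to point-segment distances.
#'
#' @param p1,p2 endpoints of the first segment (nm).
#' @param q1,q2 endpoints of the second segment (nm).
#' @return Distance in nm.
#' @export
segment_distance <- function(p1, p2, q1, q2) {
  seg_dist_cpp(as.numeric(p1), as.numeric(p2),
               as.numeric(q1), as.numeric(q2))
}

# Reduced curves of a conformation, with junction metadata for contour
# exclusion: each curve carries arc coordinates in bp and the contour
# graph is closed through the forks for RIs.
reduced_curves_of <- function(x, step = 10, offset = 0) {
  if (inherits(x, "trajectory_frame")) x <- x$conformation
  if (inherits(x, "duplex_conformation")) {
    mid <- midpoint_curve(x$strandA, x$strandB, region = "unreplicated")
    list(curves = list(whole = reduce_curve(mid, step, offset)),
         n_unrep = x$n_bp, n_rep = 0L, n_parental = x$n_bp, is_ri = FALSE)
  } else if (inherits(x, "replication_intermediate")) {
    dup <- ri_duplexes(x)
    mk <- function(d, region) {
      mid <- strand_curve((d$A + d$B) / 2, closed = FALSE, region = region)
      reduce_curve(mid, step, offset)
    }
    list(curves = list(
      unreplicated = mk(dup$unreplicated, "unreplicated"),
      daughter1 = mk(dup$daughter1, "replicated_daughter1"),
      daughter2 = mk(dup$daughter2, "replicated_daughter2")),
      n_unrep = x$n_unrep, n_rep = x$n_rep, n_parental = x$n_parental,
      is_ri = TRUE)
  } else stop("unsupported conformation type")
}

# Contour separation (bp) between two points given their curve names and
# arc coordinates, walking through the fork junctions where needed.
contour_separation <- function(curve_i, arc_i, curve_j, arc_j,
                               n_unrep, n_rep, is_ri) {
  if (!is_ri || (curve_i == "whole" && curve_j == "whole")) {
    d <- abs(arc_i - arc_j)
    return(min(d, n_unrep - d))
  }
  u <- function(cv) cv == "unreplicated"
  if (curve_i == curve_j) {
    len <- if (u(curve_i)) n_unrep else n_rep
    d <- abs(arc_i - arc_j)
    # open curves: also allow the path around through both forks
    other <- if (u(curve_i)) n_rep else n_unrep
    return(min(d, (len - 1 - max(arc_i, arc_j)) + other +
                 min(arc_i, arc_j) + 2))
  }
  if (u(curve_i) || u(curve_j)) {
    au <- if (u(curve_i)) arc_i else arc_j
    ar <- if (u(curve_i)) arc_j else arc_i
    # unreplicated arc runs fork2(0) -> fork1(n_unrep-1); daughters run
    # fork1(0) -> fork2(n_rep-1)
    via_f1 <- (n_unrep - 1 - au) + ar + 1
    via_f2 <- au + (n_rep - 1 - ar) + 1
    return(min(via_f1, via_f2))
  }
  # two different daughters: meet only at the forks
  via_f1 <- arc_i + arc_j + 1
  via_f2 <- (n_rep - 1 - arc_i) + (n_rep - 1 - arc_j) + 1
  min(via_f1, via_f2)
}

#' Crossing chirality and topological sign
#'
#' Given the tangent vectors at the two juxtaposed points and the
#' connector between them, projects both tangents onto the plane
#' perpendicular to the view axis (the closest-approach connector).
#' Chirality follows the counter-clockwise rotation angle carrying the
#' underlying segment's line onto the overlying one: below 90 degrees the
#' node is left-handed, above it right-handed.  The topological sign
#' follows the rotation sense carrying the overlying tangent onto the
#' underlying one: clockwise is negative, counter-clockwise positive.
#'
#' @param t_under,t_over tangent vectors at the underlying and overlying
#'   points.
#' @param view unit vector from the underlying toward the overlying point.
#' @return A list with `chirality` (`"left"`/`"right"`), `sign` (+1/-1)
#'   and the oriented crossing angle `theta` (rad).
#' @export
crossing_geometry <- function(t_under, t_over, view) {
  v <- unitize(as.numeric(view))
  theta <- signed_angle_about(as.numeric(t_under), as.numeric(t_over), v)
  alpha <- theta %% pi
  if (min(alpha, pi - alpha) < 1e-6)
    stop("indeterminate crossing: projected tangents are parallel")
  chir <- if (alpha < pi / 2) "left" else "right"
  sgn <- if (theta > 0) -1L else 1L
  list(chirality = chir, sign = sgn, theta = theta)
}

#' Detect collision events
#'
#' A collision event is a pair of reduced-midpoint-curve segments whose
#' minimum distance is at most `cutoff` (10 nm, the size of a protein
#' bridging two DNA sites) and which is a strict local minimum of the
#' (i, j) segment-distance landscape (compared against all eight index
#' neighbours, with cyclic wrap on closed curves).  Pairs whose contour
#' separation is within the persistence-length exclusion window are
#' ignored, so only distal juxtapositions count.  Each event is assigned a
#' chirality and topological sign from the local tangents, and for
#' replication intermediates a type: 1 = within the unreplicated region,
#' 2 = between unreplicated and replicated regions, 3 = within the
#' precatenanes (braid-coordinate separation at most `braid_window`),
#' 4 = within the plectonemes of precatenanes (larger separations).
#'
#' @param x a conformation or [trajectory_frame()].
#' @param cutoff distance threshold in nm (default 10).
#' @param exclusion_bp contour exclusion window in bp (default 147,
#'   about one 50 nm persistence length).
#' @param step reduced-curve sampling stride (default 10 nt).
#' @param offset sampling phase (0-based).
#' @param braid_window Type 3 / Type 4 separation in bp (default 100).
#' @return A tibble of class `collision_events` with one row per event:
#'   `frame_time`, `curve_i`, `idx_i`, `curve_j`, `idx_j`, `distance_nm`,
#'   `type`, `chirality`, `sign`.
#' @export
detect_collisions <- function(x, cutoff = 10, exclusion_bp = 147,
                              step = 10, offset = 0, braid_window = 100) {
  time <- if (inherits(x, "trajectory_frame")) x$time else NA_real_
  rc <- reduced_curves_of(x, step, offset)
  cvs <- rc$curves
  nms <- names(cvs)
  rows <- list()

  tangent_at <- function(cv, seg_i) {
    # tangent of segment seg_i (1-based) of the reduced curve
    P <- cv$points
    n <- nrow(P)
    j <- if (seg_i == n) 1L else seg_i + 1L
    unitize(P[j, ] - P[seg_i, ])
  }
  point_of <- function(cv, seg_i) {
    P <- cv$points
    n <- nrow(P)
    j <- if (seg_i == n) 1L else seg_i + 1L
    (P[seg_i, ] + P[j, ]) / 2
  }

  for (a in seq_along(cvs)) {
    for (b in a:length(cvs)) {
      ca <- cvs[[a]]; cb <- cvs[[b]]
      D <- seg_dist_matrix_cpp(ca$points, ca$closed, cb$points, cb$closed)
      na <- nrow(D); nb <- ncol(D)
      if (na < 3 || nb < 3) next
      same <- a == b
      arc_a <- attr(ca, "arc_bp"); arc_b <- attr(cb, "arc_bp")
      # admissibility: outside the contour exclusion window
      adm <- matrix(TRUE, na, nb)
      for (i in 1:na) for (j in 1:nb) {
        if (same && j <= i) { adm[i, j] <- FALSE; next }
        sep <- contour_separation(nms[a], arc_a[i], nms[b], arc_b[j],
                                  rc$n_unrep, rc$n_rep, rc$is_ri)
        if (sep <= exclusion_bp) adm[i, j] <- FALSE
      }
      cand <- which(D <= cutoff & adm, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      neigh <- expand.grid(di = -1:1, dj = -1:1)
      neigh <- neigh[!(neigh$di == 0 & neigh$dj == 0), ]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        d0 <- D[i, j]
        is_min <- TRUE
        smaller_tie <- FALSE
        for (k in seq_len(nrow(neigh))) {
          ii <- i + neigh$di[k]; jj <- j + neigh$dj[k]
          if (ca$closed) ii <- ((ii - 1) %% na) + 1
          if (cb$closed) jj <- ((jj - 1) %% nb) + 1
          if (ii < 1 || ii > na || jj < 1 || jj > nb) next
          if (same && jj <= ii) next
          dn <- D[ii, jj]
          if (dn < d0) { is_min <- FALSE; break }
          if (dn == d0 && (ii < i || (ii == i && jj < j)))
            smaller_tie <- TRUE
        }
        if (!is_min || smaller_tie) next
        ti <- tangent_at(ca, i); tj <- tangent_at(cb, j)
        pi_ <- point_of(ca, i); pj_ <- point_of(cb, j)
        conn <- pj_ - pi_
        if (vnorm(conn) < 1e-9) next
        geom <- tryCatch(crossing_geometry(ti, tj, conn),
                         error = function(e) NULL)
        if (is.null(geom)) next
        type <- if (!rc$is_ri) 1L else {
          ui <- nms[a] == "unreplicated"; uj <- nms[b] == "unreplicated"
          if (ui && uj) 1L
          else if (xor(ui, uj)) 2L
          else if (abs(arc_a[i] - arc_b[j]) <= braid_window) 3L
          else 4L
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          frame_time = time,
          curve_i = nms[a], idx_i = arc_a[i],
          curve_j = nms[b], idx_j = arc_b[j],
          distance_nm = d0, type = type,
          chirality = geom$chirality, sign = geom$sign)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(frame_time = numeric(), curve_i = character(),
                   idx_i = integer(), curve_j = character(),
                   idx_j = integer(), distance_nm = numeric(),
                   type = integer(), chirality = character(),
                   sign = integer())
  class(out) <- c("collision_events", class(out))
  out
}

#' Classify a collision event for a replication intermediate
#'
#' Region-label based classification: both points unreplicated gives
#' Type 1; one unreplicated and one replicated gives Type 2; both
#' replicated gives Type 3 when the braid-coordinate separation (contour
#' position along the replicated region, measured from the same fork) is
#' within `braid_window`, Type 4 otherwise.
#'
#' @param curve_i,curve_j reduced-curve names (`"unreplicated"`,
#'   `"daughter1"`, `"daughter2"`).
#' @param arc_i,arc_j braid/contour coordinates in bp.
#' @param braid_window Type 3 / 4 separation threshold in bp.
#' @return Integer type 1-4.
#' @export
classify_type <- function(curve_i, arc_i, curve_j, arc_j,
                          braid_window = 100) {
  ui <- curve_i == "unreplicated"; uj <- curve_j == "unreplicated"
  if (ui && uj) return(1L)
  if (xor(ui, uj)) return(2L)
  if (abs(arc_i - arc_j) <= braid_window) 3L else 4L
}

#' Tally collision events
#'
#' Counts events per type and chirality (the 4 x 2 reporting table).  When
#' the events span several frames, per-frame counts are averaged.
#'
#' @param events a `collision_events` tibble.
#' @return A tibble with `type`, `chirality`, `count` (mean per frame) and
#'   `n_frames`.
#' @export
tally_collisions <- function(events) {
  grid <- tidyr::expand_grid(type = 1:4, chirality = c("left", "right"))
  nfr <- max(1L, dplyr::n_distinct(events$frame_time))
  if (nrow(events) == 0)
    return(dplyr::mutate(grid, count = 0, n_frames = nfr))
  counts <- events |>
    dplyr::count(.data$type, .data$chirality, name = "total")
  grid |>
    dplyr::left_join(counts, by = c("type", "chirality")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$total, 0L) / nfr,
                  n_frames = nfr) |>
    dplyr::select(-"total")
}
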