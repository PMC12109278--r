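# Small vector-geometry helpers shared by the generator and the topology
# operations.  Points are rows of n x 3 matrices, coordinates in nm.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product / dot product for n x 3 matrices.
rowcross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

rowdot <- function(A, B) rowSums(A * B)

rownorm <- function(A) sqrt(rowSums(A^2))

rowunit <- function(A) A / pmax(rownorm(A), 1e-300)

# Tangent vectors of a polyline (central differences; wrap when closed).
polyline_tangents <- function(P, closed) {
  n <- nrow(P)
  if (closed) {
    nxt <- P[c(2:n, 1), , drop = FALSE]
    prv <- P[c(n, 1:(n - 1)), , drop = FALSE]
  } else {
    nxt <- P[c(2:n, n), , drop = FALSE]
    prv <- P[c(1, 1:(n - 1)), , drop = FALSE]
  }
  rowunit(nxt - prv)
}

polyline_length <- function(P, closed = FALSE) {
  n <- nrow(P)
  d <- sqrt(rowSums((P[c(2:n, 1), , drop = FALSE] - P)^2))
  if (closed) sum(d) else sum(d[-n])
}

# Resample a polyline to m points uniformly spaced in arc length.
resample_polyline <- function(P, m, closed = FALSE) {
  n <- nrow(P)
  Q <- if (closed) rbind(P, P[1, , drop = FALSE]) else P
  seg <- sqrt(rowSums(diff(Q)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- if (closed) seq(0, total, length.out = m + 1)[1:m] else
    seq(0, total, length.out = m)
  out <- matrix(0, length(targets), 3)
  j <- 1
  for (i in seq_along(targets)) {
    t <- targets[i]
    while (j < length(s) - 1 && s[j + 1] < t) j <- j + 1
    w <- if (seg[j] > 0) (t - s[j]) / seg[j] else 0
    out[i, ] <- (1 - w) * Q[j, ] + w * Q[j + 1, ]
  }
  out
}

# Rotation-minimizing frame along a polyline (double-reflection method).
# Returns list(normal = n x 3, binormal = n x 3).  The initial normal is any
# unit vector perpendicular to the first tangent unless supplied.
rmf_frames <- function(P, closed, normal0 = NULL) {
  n <- nrow(P)
  tang <- polyline_tangents(P, closed)
  if (is.null(normal0)) {
    t1 <- tang[1, ]
    ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    normal0 <- unitize(cross3(t1, ref))
  }
  N <- matrix(0, n, 3)
  N[1, ] <- unitize(normal0 - sum(normal0 * tang[1, ]) * tang[1, ])
  for (i in 1:(n - 1)) {
    # double reflection step from (P_i, t_i, N_i) to (P_{i+1}, t_{i+1})
    v1 <- P[i + 1, ] - P[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-18) {
      N[i + 1, ] <- N[i, ]
      next
    }
    rL <- N[i, ] - (2 / c1) * sum(v1 * N[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    N[i + 1, ] <- if (c2 < 1e-18) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    N[i + 1, ] <- unitize(N[i + 1, ] -
                            sum(N[i + 1, ] * tang[i + 1, ]) * tang[i + 1, ])
  }
  B <- rowcross(tang, N)
  list(tangent = tang, normal = N, binormal = B)
}

# Holonomy of the RMF around a closed polyline: the signed angle (about the
# first tangent) from the transported end normal back to the start normal.
rmf_closure_angle <- function(P, frames) {
  n <- nrow(P)
  # transport N[n] across the closing segment back to vertex 1
  t_last <- unitize(P[1, ] - P[n, ])
  # one more double-reflection step onto the first tangent
  v1 <- P[1, ] - P[n, ]
  c1 <- sum(v1 * v1)
  Nn <- frames$normal[n, ]
  tn <- frames$tangent[n, ]
  rL <- Nn - (2 / c1) * sum(v1 * Nn) * v1
  tL <- tn - (2 / c1) * sum(v1 * tn) * v1
  t1 <- frames$tangent[1, ]
  v2 <- t1 - tL
  c2 <- sum(v2 * v2)
  Nend <- if (c2 < 1e-18) rL else rL - (2 / c2) * sum(v2 * rL) * v2
  Nend <- unitize(Nend - sum(Nend * t1) * t1)
  N1 <- frames$normal[1, ]
  atan2(sum(cross3(Nend, N1) * t1), sum(Nend * N1))
}

# Signed angle from vector a to vector b about unit axis v (both projected
# perpendicular to v), in (-pi, pi].
signed_angle_about <- function(a, b, v) {
  ap <- a - sum(a * v) * v
  bp <- b - sum(b * v) * v
  atan2(sum(cross3(ap, bp) * v), sum(ap * bp))
}
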