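#' Oriented piecewise-linear strand curve
#'
#' The basic geometric object of the package: an ordered set of 3D points
#' (in nm) tracing one DNA strand (or a duplex axis), with a closure flag,
#' per-point nucleotide indices and region labels.  Closed curves connect
#' the final point back to the first implicitly; the first point is never
#' duplicated.
#'
#' @param points numeric matrix with 3 columns (x, y, z in nm) and at least
#'   3 rows; consecutive points must be distinct.
#' @param closed logical; is the curve covalently closed?
#' @param nt_index integer vector of per-point nucleotide indices
#'   (0-based); defaults to `0:(n-1)`.
#' @param region character vector of per-point region labels, one of
#'   `"unreplicated"`, `"replicated_daughter1"`, `"replicated_daughter2"`,
#'   `"axis"`; a scalar is recycled.
#'
#' @return An object of class `strand_curve`.
#' @export
strand_curve <- function(points, closed = FALSE, nt_index = NULL,
                         region = "unreplicated") {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 3) stop("a strand curve needs at least 3 points")
  steps <- sqrt(rowSums(diff(points)^2))
  if (any(steps < 1e-9))
    stop("consecutive points must be distinct (zero-length segment at index ",
         which(steps < 1e-9)[1], ")")
  if (closed && sqrt(sum((points[1, ] - points[n, ])^2)) < 1e-9)
    stop("closed curves must not duplicate the first point at the end")
  if (is.null(nt_index)) nt_index <- 0:(n - 1)
  nt_index <- as.integer(nt_index)
  if (length(nt_index) != n) stop("`nt_index` must have one entry per point")
  region <- as.character(region)
  if (length(region) == 1) region <- rep(region, n)
  if (length(region) != n) stop("`region` must be scalar or one per point")
  ok <- region %in% c("unreplicated", "replicated_daughter1",
                      "replicated_daughter2", "axis")
  if (!all(ok)) stop("unknown region label: ", region[!ok][1])
  structure(list(points = points, closed = isTRUE(closed),
                 nt_index = nt_index, region = region),
            class = "strand_curve")
}

#' @export
print.strand_curve <- function(x, ...) {
  cat(sprintf("<strand_curve> %d points, %s, regions: %s\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' @export
length.strand_curve <- function(x) nrow(x$points)

#' @rdname strand_curve
#' @param x a `strand_curve`.
#' @param ... unused.
#' @export
as_tibble.strand_curve <- function(x, ...) {
  P <- x$points
  nt <- x$nt_index
  reg <- x$region
  tibble::tibble(nt_index = nt, x = P[, 1], y = P[, 2], z = P[, 3],
                 region = reg)
}

is_strand_curve <- function(x) inherits(x, "strand_curve")

curve_points <- function(x) if (is_strand_curve(x)) x$points else as.matrix(x)

curve_closed <- function(x, default = FALSE) {
  if (is_strand_curve(x)) x$closed else default
}

#' Trajectory frame
#'
#' A time-stamped conformation.  Trajectories are plain lists of frames with
#' non-decreasing times; for Monte Carlo output, "time" is the cumulative
#' move count.
#'
#' @param time numeric time stamp (simulation time units or move count).
#' @param conformation a [duplex_conformation()] or
#'   [replication_intermediate()].
#' @return An object of class `trajectory_frame`.
#' @export
trajectory_frame <- function(time, conformation) {
  if (!inherits(conformation, c("duplex_conformation",
                                "replication_intermediate",
                                "strand_set")))
    stop("`conformation` must be a duplex_conformation, ",
         "replication_intermediate or strand_set")
  structure(list(time = as.numeric(time), conformation = conformation),
            class = "trajectory_frame")
}

#' @export
print.trajectory_frame <- function(x, ...) {
  cat(sprintf("<trajectory_frame> t = %g\n", x$time))
  print(x$conformation)
  invisible(x)
}
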