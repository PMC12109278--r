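# Seeded construction of conformations with prescribed topology: relaxed
# and supercoiled circles, and replication intermediates whose Gauss-block
# charges match a prescribed partition.  All geometry in nm.

# ---------------------------------------------------------------------------
# low-level curve builders
# ---------------------------------------------------------------------------

# Circular arc of given length through P1 and P2, bulging toward
# `bulge_dir` (unit-ish vector perpendicular to the chord).  Returns m
# points from P1 to P2 along the major side.
arc_through <- function(P1, P2, length, bulge_dir, m) {
  d <- vnorm(P2 - P1)
  if (length <= d) stop("arc length must exceed the chord")
  f <- function(theta) 2 * (length / theta) * sin(theta / 2) - d
  theta <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-9), tol = 1e-12)$root
  r <- length / theta
  Mid <- (P1 + P2) / 2
  u <- unitize(P2 - P1)
  b <- unitize(bulge_dir - sum(bulge_dir * u) * u)
  Cc <- Mid + sqrt(max(r^2 - (d / 2)^2, 0)) * b
  # plane basis at the center
  e1 <- unitize(P1 - Cc)
  e2n <- P2 - Cc
  e2 <- unitize(e2n - sum(e2n * e1) * e1)
  phi2 <- atan2(sum((P2 - Cc) * e2), sum((P2 - Cc) * e1))
  # two candidate sweeps from P1 (angle 0) to P2 (angle phi2)
  s1 <- phi2 %% (2 * pi)
  sweep <- if (abs(s1 - theta) <= abs((s1 - 2 * pi) + theta)) s1 else
    s1 - 2 * pi
  tt <- seq(0, 1, length.out = m)
  ang <- sweep * tt
  P <- matrix(0, m, 3)
  for (k in 1:3)
    P[, k] <- Cc[k] + r * (cos(ang) * e1[k] + sin(ang) * e2[k])
  P
}

# Arc with straight entry/exit stubs so the curve leaves both endpoints
# perpendicular to the chord (keeps fork junction regions uncongested).
stubbed_arc <- function(P1, P2, length, bulge_dir, m, stub = 10) {
  b <- unitize(bulge_dir)
  A1 <- P1 + stub * b
  A2 <- P2 + stub * b
  arc <- arc_through(A1, A2, length - 2 * stub, bulge_dir, m)
  rbind(matrix(P1, 1), arc, matrix(P2, 1))
}

# Open interwound (plectonemic) arm from P1 to P2: outgoing helix around a
# straight spine along `dir`, hairpin cap, returning helix at opposite
# phase.  `k_turns` is the winding of each half; `handed` = +1 / -1 sets
# the helix handedness.  Arm length is tuned to `length` by a secant
# iteration on the spine extent.
plectoneme_arm <- function(P1, P2, length, k_turns, r_p, handed, dir,
                           r_hp = 6) {
  Mb <- (P1 + P2) / 2
  e1 <- unitize(dir)
  u1 <- P1 - Mb
  u1 <- u1 - sum(u1 * e1) * e1
  r_base <- max(vnorm(u1), 1e-3)
  u1 <- unitize(u1)
  u2 <- cross3(e1, u1)
  wvec <- function(phi, rad) {
    outer(rad * cos(phi), u1) + outer(rad * sin(phi), u2)
  }
  # superhelix radius breathes once per crossing (as thermalized
  # plectonemes do), so opposing strands dip below the juxtaposition
  # cutoff at the crossings rather than along the whole arm
  n_cross <- max(1, round(2 * k_turns))
  build <- function(Ls) {
    m_h <- max(32, ceiling(2 * length))
    t <- seq(0, 1, length.out = m_h)
    breathe <- 1 + 0.35 * sin(2 * pi * n_cross * t - pi / 2)
    rad <- (r_base + (r_p - r_base) * pmin(1, t / 0.12)) *
      (1 + (breathe - 1) * pmin(1, t / 0.12, (1 - t) / 0.12))
    phi_out <- handed * 2 * pi * k_turns * t
    spine <- outer(6 + Ls * t, e1) +
      matrix(Mb, m_h, 3, byrow = TRUE)
    out_pts <- spine + wvec(phi_out, rad)
    psi <- seq(0, pi, length.out = max(16, ceiling(pi * r_p)))
    psi <- psi[-c(1, length(psi))]
    top <- handed * 2 * pi * k_turns
    hp <- outer(rep(6 + Ls, length(psi)) + r_hp * sin(psi), e1) +
      matrix(Mb, length(psi), 3, byrow = TRUE) +
      wvec(top + handed * psi, r_p)
    phi_ret <- handed * 2 * pi * k_turns * rev(t) + pi
    rad_r <- rev(rad)
    spine_r <- outer(6 + Ls * rev(t), e1) +
      matrix(Mb, m_h, 3, byrow = TRUE)
    ret_pts <- spine_r + wvec(phi_ret, rad_r)
    rbind(matrix(P1, 1), out_pts, hp, ret_pts, matrix(P2, 1))
  }
  helix_len <- sqrt(1 + (2 * pi * r_p * k_turns)^2)  # scale proxy
  Ls <- max(5, sqrt(max((length / 2)^2 - (2 * pi * r_p * k_turns)^2,
                        25)))
  P <- build(Ls)
  L1 <- polyline_length(P)
  for (it in 1:4) {
    if (abs(L1 - length) < 0.5) break
    Ls2 <- max(5, Ls * (1 + (length - L1) / (2 * Ls)))
    P2_ <- build(Ls2)
    L2 <- polyline_length(P2_)
    Ls <- Ls2; P <- P2_; L1 <- L2
  }
  P
}

# Duplex strands with a prescribed total winding about an axis polyline,
# using a rotation-minimizing frame so that the winding is pure twist.
# For closed axes the phase advance absorbs the frame holonomy so the
# strand polygons close smoothly.  Returns list(A, B, turns_effective).
duplex_from_axis <- function(axis_pts, closed, turns, radius, phase0 = 0) {
  n <- nrow(axis_pts)
  fr <- rmf_frames(axis_pts, closed)
  if (closed) {
    alpha <- rmf_closure_angle(axis_pts, fr)
    total <- 2 * pi * turns - alpha
    phi <- phase0 + total * (0:(n - 1)) / n
  } else {
    phi <- phase0 + 2 * pi * turns * (0:(n - 1)) / (n - 1)
  }
  off <- fr$normal * cos(phi) + fr$binormal * sin(phi)
  list(A = axis_pts + radius * off, B = axis_pts - radius * off)
}

# ---------------------------------------------------------------------------
# circles
# ---------------------------------------------------------------------------

#' Relaxed covalently closed circle
#'
#' A planar circular duplex axis with two helical strands winding
#' `round(n_bp / h)` times, i.e. a torsionally relaxed closed molecule with
#' writhe ~ 0 and integer linking number `round(n_bp / h)`.
#'
#' @param n_bp number of base pairs (>= 63, six helical turns).
#' @param h helical repeat in bp/turn (default 10.5).
#' @param rise rise per bp along the axis, nm (default 0.34).
#' @param duplex_radius strand distance from the axis, nm (default 1).
#' @return A [duplex_conformation()].
#' @export
make_relaxed_circle <- function(n_bp, h = 10.5, rise = 0.34,
                                duplex_radius = 1.0) {
  if (n_bp < 63) stop("n_bp must be at least 63 (six helical turns)")
  n <- as.integer(n_bp)
  R <- n * rise / (2 * pi)
  th <- 2 * pi * (0:(n - 1)) / n
  axis <- cbind(R * cos(th), R * sin(th), 0)
  k <- round(n / h)
  # radial / vertical frame is rotation-minimizing on a planar circle;
  # negative phase advance makes the right-handed winding give Lk = +k
  phi <- -2 * pi * k * (0:(n - 1)) / n
  radial <- cbind(cos(th), sin(th), 0)
  zhat <- cbind(0, 0, rep(1, n))
  off <- radial * cos(phi) + zhat * sin(phi)
  A <- axis + duplex_radius * off
  B <- axis - duplex_radius * off
  duplex_conformation(strand_curve(A, closed = TRUE),
                      strand_curve(B, closed = TRUE), helical_repeat = h)
}

# Closed plectonemic axis polyline with ~`crossings` interwound crossings
# distributed over `n_branches` arms, total length `len`.
plectoneme_axis <- function(len, crossings, n_branches, r_p, handed,
                            phase_jitter = 0) {
  nb <- n_branches
  k_b <- crossings / (2 * nb)
  if (nb == 1) {
    P1 <- c(-4.5, 0, 0); P2 <- c(4.5, 0, 0)
    arm <- plectoneme_arm(P1, P2, len - vnorm(P2 - P1), k_b, r_p, handed,
                          dir = c(0, 1, 0))
    return(arm)
  }
  R0 <- max(16, 7 * nb)
  hub_circ <- 2 * pi * R0
  arm_len <- (len - hub_circ * 0.9) / nb
  pieces <- list()
  dth <- 2 * pi / nb
  delta <- 0.45 * dth
  for (j in seq_len(nb)) {
    beta <- (j - 1) * dth + phase_jitter
    b1 <- beta - delta / 2; b2 <- beta + delta / 2
    P1 <- R0 * c(cos(b1), sin(b1), 0)
    P2 <- R0 * c(cos(b2), sin(b2), 0)
    dirj <- c(cos(beta), sin(beta), 0)
    arm <- plectoneme_arm(P1, P2, arm_len, k_b, r_p, handed, dir = dirj)
    pieces[[length(pieces) + 1]] <- arm
    # hub arc to the next branch base
    a_from <- b2; a_to <- beta + dth - delta / 2
    ang <- seq(a_from, a_to, length.out = 24)
    ang <- ang[-c(1, length(ang))]
    pieces[[length(pieces) + 1]] <-
      cbind(R0 * cos(ang), R0 * sin(ang), 0)
  }
  do.call(rbind, pieces)
}

#' Supercoiled covalently closed circle
#'
#' Builds a plectonemic conformation carrying approximately `|delta_lk|`
#' interwound crossings distributed over `n_branches` branches, with the
#' strand twist adjusted so that the measured linking number equals
#' `round(n_bp / h) + delta_lk` exactly.  Negative `delta_lk` produces a
#' right-handed interwound superhelix (negative crossings), positive a
#' left-handed one.
#'
#' @inheritParams make_relaxed_circle
#' @param delta_lk integer linking number difference (0 returns the relaxed
#'   circle).
#' @param n_branches number of plectonemic branches (>= 1).
#' @param seed integer seed controlling construction phases.
#' @param superhelix_radius plectoneme superhelix radius, nm (default 4.5).
#' @return A [duplex_conformation()].
#' @export
make_supercoiled_circle <- function(n_bp, delta_lk, n_branches = 1,
                                    seed = 1, h = 10.5, rise = 0.34,
                                    duplex_radius = 1.0,
                                    superhelix_radius = 4.5) {
  if (delta_lk == 0) return(make_relaxed_circle(n_bp, h, rise,
                                                duplex_radius))
  if (abs(delta_lk) < 1) stop("|delta_lk| must be at least 1 (or exactly 0)")
  if (delta_lk != round(delta_lk))
    stop("delta_lk must be an integer for a closed molecule")
  if (n_branches < 1) stop("n_branches must be at least 1")
  n <- as.integer(n_bp)
  set.seed(seed)
  jit <- stats::runif(1, 0, 2 * pi / max(n_branches, 1))
  handed <- if (delta_lk < 0) 1 else -1
  raw <- plectoneme_axis(n * rise, abs(delta_lk), n_branches,
                         superhelix_radius, handed, phase_jitter = jit)
  axis <- resample_polyline(raw, n, closed = TRUE)
  target_lk <- round(n / h) + delta_lk
  wr <- writhe_cpp(axis)
  k <- round(target_lk - wr)
  phase0 <- stats::runif(1, 0, 2 * pi)
  for (it in 1:5) {
    st <- duplex_from_axis(axis, TRUE, k, duplex_radius, phase0 = phase0)
    lk <- sum(gauss_block_sums_cpp(st$A, TRUE, st$B, TRUE, 0L, 0L))
    err <- target_lk - round(lk)
    if (err == 0) break
    k <- k + err
  }
  if (err != 0)
    stop("supercoiled construction failed to reach the target linking ",
         "number (residual ", err, " turns); geometric self-intersection ",
         "likely")
  duplex_conformation(strand_curve(st$A, closed = TRUE),
                      strand_curve(st$B, closed = TRUE), helical_repeat = h)
}

# ---------------------------------------------------------------------------
# generator configuration
# ---------------------------------------------------------------------------

#' Generator configuration for replication intermediates
#'
#' Bundles the geometric constants and the prescribed charge partition used
#' by [make_ri()].  The partition must satisfy
#' `precatenane_Ca + braid_writhe = q_rep`; the total linking difference of
#' the constructed molecule is `q_unrep + q_wrap + q_rep`.
#'
#' @param n_bp total parental length in bp.
#' @param frac_replicated fraction of the molecule replicated; `n_rep =
#'   round(n_bp * frac_replicated)` unless `n_rep` is given explicitly.
#' @param q_unrep,q_wrap,q_rep prescribed region charges in turns.
#' @param precatenane_Ca precatenane winding of the daughter duplexes
#'   (turns; right-handed positive).
#' @param braid_writhe writhe of the braid axis (plectonemes of
#'   precatenanes), turns.
#' @param n_plectoneme_branches branches of the unreplicated plectoneme.
#' @param seed integer seed.
#' @param helical_repeat_h,rise_per_bp,duplex_radius,superhelix_radius
#'   geometry constants (bp/turn, nm, nm, nm).
#' @param braid_radius daughter-duplex distance from the braid axis, nm.
#' @param unrep_twist_fraction fraction of `q_unrep` realized as twist
#'   (Component 1); the rest is plectonemic writhe.
#' @param fork_gap_nm distance between the two fork junctions, nm.
#' @param n_rep optional explicit replicated bp count.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_bp = 2000, frac_replicated = 0.25,
                             q_unrep = 0, q_wrap = 0, q_rep = 0,
                             precatenane_Ca = q_rep, braid_writhe = 0,
                             n_plectoneme_branches = 1, seed = 1,
                             helical_repeat_h = 10.5, rise_per_bp = 0.34,
                             duplex_radius = 1.0, superhelix_radius = 4.5,
                             braid_radius = 4.0,
                             unrep_twist_fraction = 0.3,
                             fork_gap_nm = 12, n_rep = NULL) {
  if (abs(precatenane_Ca + braid_writhe - q_rep) > 1e-9)
    stop("prescribed partition must satisfy precatenane_Ca + braid_writhe ",
         "= q_rep")
  if (is.null(n_rep)) n_rep <- round(n_bp * frac_replicated)
  n_unrep <- n_bp - n_rep
  if (n_unrep < 60 || n_rep < 60)
    stop("both regions need at least 60 bp for a sane construction")
  structure(list(n_bp = as.integer(n_bp), n_unrep = as.integer(n_unrep),
                 n_rep = as.integer(n_rep),
                 frac_replicated = n_rep / n_bp,
                 q_unrep = q_unrep, q_wrap = q_wrap, q_rep = q_rep,
                 precatenane_Ca = precatenane_Ca,
                 braid_writhe = braid_writhe,
                 n_plectoneme_branches = as.integer(n_plectoneme_branches),
                 seed = as.integer(seed),
                 helical_repeat_h = helical_repeat_h,
                 rise_per_bp = rise_per_bp,
                 duplex_radius = duplex_radius,
                 superhelix_radius = superhelix_radius,
                 braid_radius = braid_radius,
                 unrep_twist_fraction = unrep_twist_fraction,
                 fork_gap_nm = fork_gap_nm),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> %d bp (%d unrep + %d rep), ",
                     "q = (%+g, %+g, %+g), Ca = %+g, braid Wr = %+g, ",
                     "seed %d\n"),
              x$n_bp, x$n_unrep, x$n_rep, x$q_unrep, x$q_wrap, x$q_rep,
              x$precatenane_Ca, x$braid_writhe, x$seed))
  invisible(x)
}

#' In-vivo stage configurations
#'
#' Ready-made configurations for the two canonical replication stages: the
#' early intermediate (1491 bp unreplicated / 509 bp replicated, charge
#' partition -12 / 0 / +2, total linking difference -10) and the late
#' intermediate (504 bp unreplicated / 1506 bp replicated, partition
#' -2 / 0 / +12, total +10).  Stress is confined per region (no wrapping),
#' matching a pre-equilibrium with rotation-restricted forks.
#'
#' @param seed integer seed.
#' @return A [generator_config()].
#' @export
ri_config_early <- function(seed = 1) {
  generator_config(n_bp = 2000, n_rep = 509,
                   q_unrep = -12, q_wrap = 0, q_rep = 2,
                   precatenane_Ca = 2, braid_writhe = 0, seed = seed)
}

#' @rdname ri_config_early
#' @export
ri_config_late <- function(seed = 1) {
  generator_config(n_bp = 2010, n_rep = 1506,
                   q_unrep = -2, q_wrap = 0, q_rep = 12,
                   precatenane_Ca = 12, braid_writhe = 0, seed = seed)
}

# ---------------------------------------------------------------------------
# replication intermediates
# ---------------------------------------------------------------------------

# One full geometric build for a given set of continuous control variables.
build_ri_geometry <- function(cfg, T_u, Ca_geom, wrap_turns, phases) {
  rise <- cfg$rise_per_bp
  h <- cfg$helical_repeat_h
  n_u <- cfg$n_unrep; n_r <- cfg$n_rep
  F1 <- c(-cfg$fork_gap_nm / 2, 0, 0)
  F2 <- c(cfg$fork_gap_nm / 2, 0, 0)
  L_u <- n_u * rise
  L_rep <- n_r * rise

  # unreplicated axis: plectonemic arm (or plain arc) in the +y half-space
  wr_target <- (1 - cfg$unrep_twist_fraction) * cfg$q_unrep
  if (abs(wr_target) < 0.75) {
    axis_u_raw <- stubbed_arc(F1, F2, L_u, c(0, 1, 0),
                              m = max(64, ceiling(L_u)))
  } else {
    handed <- if (wr_target < 0) 1 else -1
    axis_u_raw <- plectoneme_arm(F1, F2, L_u, abs(wr_target) / 2,
                                 cfg$superhelix_radius, handed,
                                 dir = c(0, 1, 0))
  }
  axis_u <- resample_polyline(axis_u_raw, n_u, closed = FALSE)

  # braid axis: arc (or plectonemic arm) in the -y half-space, length set
  # so each daughter helix has the replicated contour length
  circ <- 2 * pi * cfg$braid_radius * abs(Ca_geom)
  L_b <- sqrt(max(L_rep^2 - circ^2, (3 * cfg$fork_gap_nm)^2))
  if (abs(cfg$braid_writhe) < 0.75) {
    braid_raw <- stubbed_arc(F2, F1, L_b, c(0, -1, 0),
                             m = max(64, ceiling(L_b)))
  } else {
    handed_b <- if (cfg$braid_writhe < 0) 1 else -1
    braid_raw <- plectoneme_arm(F2, F1, L_b, abs(cfg$braid_writhe) / 2,
                                cfg$superhelix_radius + 4, handed_b,
                                dir = c(0, -1, 0))
  }
  braid_axis <- resample_polyline(braid_raw, n_r, closed = FALSE)

  # optional wrapping of the braid around the unreplicated duplex
  if (abs(wrap_turns) > 1e-6) {
    fr_u <- rmf_frames(axis_u, closed = FALSE)
    # re-route the braid axis along the unreplicated axis, winding round it
    tt <- seq(0, 1, length.out = n_r)
    idx <- pmax(1, pmin(n_u, 1 + round(tt * (n_u - 1))))
    psi_w <- 2 * pi * wrap_turns * tt + phases$wrap
    R_w <- 9
    braid_axis <- axis_u[idx, , drop = FALSE] +
      R_w * (fr_u$normal[idx, , drop = FALSE] * cos(psi_w) +
               fr_u$binormal[idx, , drop = FALSE] * sin(psi_w))
  }

  # daughter axes: interwound about the braid axis
  fr_b <- rmf_frames(braid_axis, closed = FALSE)
  tt <- seq(0, 1, length.out = n_r)
  psi <- phases$braid + 2 * pi * Ca_geom * tt
  offd <- fr_b$normal * cos(psi) + fr_b$binormal * sin(psi)
  d1 <- braid_axis + cfg$braid_radius * offd
  d2 <- braid_axis - cfg$braid_radius * offd

  # strands
  su <- duplex_from_axis(axis_u, FALSE, T_u, cfg$duplex_radius,
                         phase0 = phases$unrep)
  sd1 <- duplex_from_axis(d1, FALSE, n_r / h, cfg$duplex_radius,
                          phase0 = phases$d1)
  sd2 <- duplex_from_axis(d2, FALSE, n_r / h, cfg$duplex_radius,
                          phase0 = phases$d2)

  pA <- strand_curve(rbind(su$A, sd1$A), closed = TRUE,
                     region = c(rep("unreplicated", n_u),
                                rep("replicated_daughter1", n_r)))
  pB <- strand_curve(rbind(su$B, sd2$A), closed = TRUE,
                     region = c(rep("unreplicated", n_u),
                                rep("replicated_daughter2", n_r)))
  dn1 <- strand_curve(sd1$B, region = "replicated_daughter1",
                      nt_index = n_u:(n_u + n_r - 1))
  dn2 <- strand_curve(sd2$B, region = "replicated_daughter2",
                      nt_index = n_u:(n_u + n_r - 1))
  replication_intermediate(pA, pB, dn1, dn2, n_unrep = n_u,
                           helical_repeat = h)
}

# Gauss block charges (q_unrep, q_wrap, q_rep) of an RI.
ri_block_charges <- function(ri) {
  S <- gauss_block_sums_cpp(ri$parentalA$points, TRUE,
                            ri$parentalB$points, TRUE,
                            c(0L, ri$n_unrep), c(0L, ri$n_unrep))
  c(q_unrep = S[1, 1] - ri$n_unrep / ri$helical_repeat,
    q_wrap = S[1, 2] + S[2, 1],
    q_rep = S[2, 2])
}

#' Construct a replication intermediate with prescribed topology
#'
#' Builds an RI whose unreplicated region is a plectonemic (or plain) arc
#' carrying `q_unrep`, whose replicated region is a two-daughter braid with
#' `precatenane_Ca` interwinding turns plus `braid_writhe` of braid-axis
#' writhe, and whose `q_wrap` is realized by winding the braid around the
#' unreplicated duplex.  The construction measures its own Gauss-block
#' charges and corrects the continuous controls (unreplicated strand twist,
#' braid turns, wrap turns) until each prescribed region charge is met to
#' within 0.1 turns.
#'
#' @param config a [generator_config()].
#' @return A [replication_intermediate()].
#' @export
make_ri <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  phases <- list(unrep = stats::runif(1, 0, 2 * pi),
                 braid = stats::runif(1, 0, 2 * pi),
                 d1 = stats::runif(1, 0, 2 * pi),
                 d2 = stats::runif(1, 0, 2 * pi),
                 wrap = stats::runif(1, 0, 2 * pi))
  h <- cfg$helical_repeat_h

  # initial controls: twist carries what the axis writhe does not.  A
  # probe build measures the writhe actually realized by the unreplicated
  # axis so the twist guess starts close.
  T_u <- cfg$n_unrep / h + cfg$unrep_twist_fraction * cfg$q_unrep
  Ca_geom <- cfg$precatenane_Ca
  wrap_turns <- if (abs(cfg$q_wrap) > 1e-9) cfg$q_wrap / 2 else 0
  probe <- build_ri_geometry(cfg, T_u, Ca_geom, wrap_turns, phases)
  dup <- ri_duplexes(probe)
  wr_u <- writhe((dup$unreplicated$A + dup$unreplicated$B) / 2)
  T_u <- cfg$n_unrep / h + cfg$q_unrep - wr_u

  # the wrapping block sum is set by the strand phases at the fork
  # junctions (a whole crossing can sit on either side of a fork); scan
  # the braid and unreplicated phases for the junction configuration
  # closest to the prescribed q_wrap
  scan_phase <- function(field, n_steps) {
    err_of <- function(ph) {
      p2 <- phases; p2[[field]] <- ph
      q <- ri_block_charges(build_ri_geometry(cfg, T_u, Ca_geom,
                                              wrap_turns, p2))
      max(abs(c(cfg$q_unrep - q[["q_unrep"]],
                cfg$q_wrap - q[["q_wrap"]],
                cfg$q_rep - q[["q_rep"]])))
    }
    cand <- 2 * pi * (0:(n_steps - 1)) / n_steps
    e <- vapply(cand, err_of, 0)
    phases[[field]] <<- cand[which.min(e)]
  }
  scan_phase("braid", 12)
  scan_phase("unrep", 6)

  ri <- build_ri_geometry(cfg, T_u, Ca_geom, wrap_turns, phases)
  q <- ri_block_charges(ri)
  errs <- function(q) c(cfg$q_unrep - q[["q_unrep"]],
                        cfg$q_wrap - q[["q_wrap"]],
                        cfg$q_rep - q[["q_rep"]])
  best <- list(ri = ri, err = errs(q), T_u = T_u, Ca = Ca_geom)
  for (it in 1:6) {
    err <- errs(q)
    if (max(abs(err)) <= max(abs(best$err))) {
      best <- list(ri = ri, err = err, T_u = T_u, Ca = Ca_geom)
    }
    if (max(abs(best$err)) < 0.15) break
    # small damped corrections; the junction geometry flips a crossing
    # between adjacent blocks if the end phases sweep too far, so steps
    # are capped at half a turn
    step1 <- max(-0.5, min(0.5, err[1]))
    step3 <- max(-0.5, min(0.5, err[3]))
    T_u <- T_u + step1
    Ca_geom <- Ca_geom + step3
    if (abs(cfg$q_wrap) > 1e-9) wrap_turns <- wrap_turns + err[2] / 2
    ri <- build_ri_geometry(cfg, T_u, Ca_geom, wrap_turns, phases)
    q <- ri_block_charges(ri)
  }
  ri <- best$ri
  err <- best$err
  if (max(abs(err)) > 0.3)
    stop(sprintf(paste0("RI construction did not converge: residuals ",
                        "(%.2f, %.2f, %.2f) turns; the prescribed packing ",
                        "is likely infeasible"),
                 err[1], err[2], err[3]))
  check_ri_packing(ri)
  ri
}

# Coarse excluded-volume sanity check between distal duplex regions.
check_ri_packing <- function(ri, hardcore = 2.0) {
  pts <- all_points(ri)
  sub <- pts[seq(1, nrow(pts), by = 3), , drop = FALSE]
  # nearest-neighbour distance via cell hashing would be overkill here; a
  # blocked pairwise pass over the subsample is fast enough
  n <- nrow(sub)
  ridx <- rep(c(ri$parentalA$nt_index, ri$parentalB$nt_index,
                ri$daughter_new1$nt_index, ri$daughter_new2$nt_index),
              length.out = nrow(pts))[seq(1, nrow(pts), by = 3)]
  step <- 400
  for (i0 in seq(1, n, by = step)) {
    ii <- i0:min(i0 + step - 1, n)
    D2 <- outer(rowSums(sub[ii, , drop = FALSE]^2), rowSums(sub^2), "+") -
      2 * sub[ii, , drop = FALSE] %*% t(sub)
    cyc <- abs(outer(ridx[ii], ridx, "-"))
    cyc <- pmin(cyc, ri$n_parental - cyc)
    bad <- D2 < hardcore^2 & cyc > 30
    if (any(bad))
      stop("infeasible packing: distal segments closer than ", hardcore,
           " nm in the constructed intermediate")
  }
  invisible(TRUE)
}
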