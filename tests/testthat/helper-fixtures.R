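# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

early_ri <- function() fixture("early_ri", function() make_ri(ri_config_early()))
late_ri <- function() fixture("late_ri", function() make_ri(ri_config_late()))
relaxed_ri <- function() fixture("relaxed_ri", function()
  make_ri(generator_config(n_bp = 2000, n_rep = 509)))
plectoneme5 <- function() fixture("plectoneme5", function()
  make_supercoiled_circle(2000, -5, 1, seed = 1))
relaxed2000 <- function() fixture("relaxed2000", function()
  make_relaxed_circle(2000))

# Independent oracle: nested adaptive quadrature of the Gauss linking
# integrand over two straight segments (matches the closed-form kernel's
# sign convention).
gauss_charge_quadrature <- function(p1, p2, q1, q2, reltol = 1e-9) {
  u <- p2 - p1
  v <- q2 - q1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  inner <- function(s) {
    r1 <- p1 + s * u
    stats::integrate(function(t) {
      d1 <- q1[1] + t * v[1] - r1[1]
      d2 <- q1[2] + t * v[2] - r1[2]
      d3 <- q1[3] + t * v[3] - r1[3]
      dn <- sqrt(d1^2 + d2^2 + d3^2)
      -(d1 * cr[1] + d2 * cr[2] + d3 * cr[3]) / dn^3 / (4 * pi)
    }, 0, 1, rel.tol = reltol, abs.tol = 1e-12)$value
  }
  stats::integrate(Vectorize(inner), 0, 1, rel.tol = reltol,
                   abs.tol = 1e-12)$value
}

# Random skew segment pair with a guaranteed clearance, so the Gauss
# integrand stays regular for the quadrature oracle.
random_separated_pair <- function(min_sep = 0.6) {
  repeat {
    p1 <- runif(3, -2, 2); p2 <- runif(3, -2, 2)
    q1 <- runif(3, -2, 2) + c(0, 0, 2.5)
    q2 <- runif(3, -2, 2) + c(0, 0, 2.5)
    if (segment_distance(p1, p2, q1, q2) >= min_sep &&
        sqrt(sum((p2 - p1)^2)) > 0.1 && sqrt(sum((q2 - q1)^2)) > 0.1)
      return(list(p1 = p1, p2 = p2, q1 = q1, q2 = q2))
  }
}

# Mirror a conformation through the z = 0 plane.
mirror_duplex <- function(d) {
  m <- diag(c(1, 1, -1))
  duplex_conformation(
    strand_curve(d$strandA$points %*% m, closed = TRUE),
    strand_curve(d$strandB$points %*% m, closed = TRUE),
    helical_repeat = d$helical_repeat, check_separation = FALSE)
}

# Closed duplex whose axis has two long straight stretches crossing once
# at 5 nm vertical separation, joined by wide peripheral loops: exactly
# one distal juxtaposition by construction.
crossed_stretch_duplex <- function() {
  fixture("crossed_stretch", function() {
    arc <- getFromNamespace("arc_through", "dnatopo")
    s2s <- 75 * c(cos(pi / 3), sin(pi / 3), 0) + c(0, 0, 5)
    s2e <- -75 * c(cos(pi / 3), sin(pi / 3), 0) + c(0, 0, 5)
    s1 <- cbind(seq(-75, 75, length.out = 150), 0, 0)
    s2 <- t(sapply(seq(1, 0, length.out = 150),
                   function(t) s2s * t + s2e * (1 - t)))
    loopA <- arc(c(75, 0, 0), s2s, 260, c(1, 0.6, 0), m = 200)
    loopB <- arc(s2e, c(-75, 0, 0), 260, c(-1, -0.6, 0), m = 200)
    ax <- rbind(s1[-150, ], loopA[-200, ], s2[-150, ], loopB[-200, ])
    off <- matrix(c(0, 0, 1), nrow(ax), 3, byrow = TRUE)
    duplex_conformation(strand_curve(ax + off, closed = TRUE),
                        strand_curve(ax - off, closed = TRUE))
  })
}

# Unit circle pair forming a Hopf link, n segments each.
hopf_pair <- function(n = 64) {
  th <- 2 * pi * (0:(n - 1)) / n
  list(A = strand_curve(cbind(cos(th), sin(th), 0 * th), closed = TRUE),
       B = strand_curve(cbind(1 + cos(th), 0 * th, sin(th)),
                        closed = TRUE))
}
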