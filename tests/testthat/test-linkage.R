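# The Gauss-integral core: segment-pair charges, linking numbers, writhe,
# twist, and the scalar descriptors.

test_that("segment-pair charge matches adaptive quadrature on random pairs", {
  set.seed(101)
  for (i in 1:50) {
    s <- random_separated_pair()
    expect_equal(segment_pair_charge(s$p1, s$p2, s$q1, s$q2),
                 gauss_charge_quadrature(s$p1, s$p2, s$q1, s$q2),
                 tolerance = 1e-6)
  }
})

test_that("segment-pair charge symmetries and degenerate cases", {
  p1 <- c(0, 0, 0); p2 <- c(1, 0, 0)
  q1 <- c(0.2, -0.5, 1); q2 <- c(0.3, 0.8, 1.4)
  ch <- segment_pair_charge(p1, p2, q1, q2)
  # antisymmetric under reversal of either segment
  expect_equal(segment_pair_charge(p2, p1, q1, q2), -ch)
  expect_equal(segment_pair_charge(p1, p2, q2, q1), -ch)
  expect_equal(segment_pair_charge(p2, p1, q2, q1), ch)
  # coplanar segments enclose no solid angle
  expect_identical(segment_pair_charge(c(0, 0, 0), c(1, 0, 0),
                                       c(0, 1, 0), c(1, 2, 0)), 0)
  # touching segments are degenerate
  expect_error(segment_pair_charge(c(0, 0, 0), c(1, 0, 0),
                                   c(0.5, 0, 0), c(0.5, 1, 0)),
               "degenerate")
  expect_error(segment_pair_charge(c(0, 0, 0), c(0, 0, 0),
                                   c(0, 1, 0), c(1, 1, 0)),
               "positive length")
})

test_that("linking numbers of canonical links are exact", {
  hp <- hopf_pair(64)
  expect_equal(abs(linking_number(hp$A, hp$B)), 1, tolerance = 1e-3)
  # far-separated circles are unlinked
  far <- strand_curve(hp$B$points + matrix(c(200, 0, 0), 64, 3,
                                           byrow = TRUE), closed = TRUE)
  expect_equal(linking_number(hp$A, far), 0, tolerance = 1e-6)
  # (2,4) torus link: two curves each winding once around, twice through
  tt <- 2 * pi * (0:199) / 200
  mk <- function(off) strand_curve(
    cbind((3 + cos(2 * tt + off)) * cos(tt),
          (3 + cos(2 * tt + off)) * sin(tt),
          sin(2 * tt + off)), closed = TRUE)
  expect_equal(abs(linking_number(mk(0), mk(pi))), 2, tolerance = 1e-3)
  # open curves are rejected
  expect_error(linking_number(strand_curve(matrix(rnorm(9), 3)), hp$A),
               "closed")
  # rigid motion invariance
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(s) strand_curve(s$points %*% R +
                                    matrix(c(5, -2, 1), nrow(s$points), 3,
                                           byrow = TRUE), closed = TRUE)
  expect_equal(linking_number(rot(hp$A), rot(hp$B)),
               linking_number(hp$A, hp$B), tolerance = 1e-6)
})

test_that("contribution matrix sums to Lk and concentrates on the diagonal
          for a relaxed circle", {
  d <- make_relaxed_circle(2100)
  cm <- conformation_matrix(d)
  expect_equal(sum(cm$entries), 200, tolerance = 0.01)
  pr <- diagonal_band_profile(cm)
  frac <- pr$main_band_sum / sum(cm$entries)
  expect_gte(frac, 0.99)
  expect_identical(pr$n_secondary_bands, 0L)
})

test_that("writhe vanishes for planar curves and is odd under mirroring", {
  th <- 2 * pi * (0:199) / 200
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_equal(writhe(circ), 0, tolerance = 1e-6)
  sc <- plectoneme5()
  ax <- duplex_axis(sc)
  wr <- writhe(ax)
  expect_equal(wr, -5, tolerance = 0.5)
  mir <- ax$points %*% diag(c(1, 1, -1))
  expect_equal(writhe(mir), -wr, tolerance = 1e-9)
})

test_that("twist of ideal duplexes matches construction", {
  n <- 105
  z <- 0.34 * (0:(n - 1))
  phi <- 2 * pi * 10 * (0:(n - 1)) / (n - 1)
  A <- cbind(cos(phi), sin(phi), z)
  B <- cbind(-cos(phi), -sin(phi), z)
  expect_equal(duplex_twist(A, B, cbind(0, 0, z), closed = FALSE), 10,
               tolerance = 1e-3)
  d <- make_relaxed_circle(2100)
  ax <- duplex_axis(d)
  expect_equal(duplex_twist(d$strandA, d$strandB, ax), 200,
               tolerance = 1e-3)
  expect_equal(writhe(ax), 0, tolerance = 1e-6)
})

test_that("White's theorem holds on stochastically deformed duplexes", {
  for (s in 1:5) {
    d <- make_relaxed_circle(210)
    f <- mc_relax(d, 2000, seed = s, n_frames = 1)
    conf <- f[[length(f)]]$conformation
    ax <- duplex_axis(conf)
    tw <- duplex_twist(conf$strandA, conf$strandB, ax)
    expect_equal(tw + writhe(ax),
                 linking_number(conf$strandA, conf$strandB),
                 tolerance = 0.05)
  }
})

test_that("scalar descriptors follow their defining formulas", {
  expect_identical(lk0(2100, 10.5), 200)
  expect_equal(delta_lk(190, lk0(2000, 10.5)), 190 - 2000 / 10.5)
  expect_equal(superhelical_density(-10, 200), -0.05)
  expect_error(lk0(0), "positive")
  expect_error(superhelical_density(1, 0), "nonzero")
})

test_that("radius of gyration has its analytic values", {
  th <- 2 * pi * (0:99) / 100
  ring <- cbind(7 * cos(th), 7 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 7, tolerance = 1e-9)
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(4, 0, 0))), 2)
})

test_that("closed-curve linking numbers are integers on generator output", {
  d <- relaxed2000()
  expect_equal(linking_number(d$strandA, d$strandB), 190,
               tolerance = 1e-3)
  sc <- plectoneme5()
  lk <- linking_number(sc$strandA, sc$strandB)
  expect_equal(lk, round(lk), tolerance = 1e-3)
  expect_equal(lk - 190, -5, tolerance = 1e-3)
})
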