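# Juxtaposition detection, crossing geometry, classification and tallies.

test_that("midpoint and reduced curves follow the sampling rules", {
  d <- relaxed2000()
  mid <- midpoint_curve(d$strandA, d$strandB)
  expect_identical(nrow(mid$points), 2000L)
  expect_equal(max(abs(mid$points - duplex_axis(d)$points)), 0,
               tolerance = 1e-9)
  red <- reduce_curve(mid, step = 10)
  expect_identical(nrow(red$points), 200L)
  expect_identical(nrow(reduce_curve(mid, step = 1)$points), 2000L)
  # a 509-point daughter region keeps ceiling(509/10) points
  sub <- strand_curve(mid$points[1:509, ], region = "replicated_daughter1")
  expect_identical(nrow(reduce_curve(sub, step = 10)$points), 51L)
  expect_error(midpoint_curve(d$strandA$points[1:10, ],
                              d$strandB$points[1:9, ]), "equal length")
  # an RI yields three reduced curves
  rc <- dnatopo:::reduced_curves_of(early_ri())
  expect_identical(names(rc$curves),
                   c("unreplicated", "daughter1", "daughter2"))
})

test_that("segment distance is the clamped minimum distance", {
  expect_equal(segment_distance(c(0, 0, 0), c(1, 0, 0),
                                c(0, 0, 3), c(1, 0, 3)), 3)
  expect_equal(segment_distance(c(-1, 0, 0), c(1, 0, 0),
                                c(0, -1, 0), c(0, 1, 0)), 0)
  set.seed(7)
  for (i in 1:25) {
    p1 <- runif(3, -3, 3); p2 <- runif(3, -3, 3)
    q1 <- runif(3, -3, 3); q2 <- runif(3, -3, 3)
    tt <- seq(0, 1, length.out = 200)
    g1 <- outer(tt, p2 - p1) + matrix(p1, 200, 3, byrow = TRUE)
    g2 <- outer(tt, q2 - q1) + matrix(q1, 200, 3, byrow = TRUE)
    brute <- sqrt(min(outer(rowSums(g1^2), rowSums(g2^2), "+") -
                        2 * g1 %*% t(g2)))
    expect_equal(segment_distance(p1, p2, q1, q2), brute,
                 tolerance = 1e-3)
  }
})

test_that("crossing geometry follows the rotation criteria", {
  # 45 degree crossing: left-handed; the overpassing strand aligns with
  # the underlying one by a clockwise rotation, so the sign is negative
  g <- crossing_geometry(c(1, 0, 0), c(cos(pi / 4), sin(pi / 4), 0),
                         c(0, 0, 1))
  expect_identical(g$chirality, "left")
  expect_identical(g$sign, -1L)
  g2 <- crossing_geometry(c(1, 0, 0), c(cos(3 * pi / 4), sin(3 * pi / 4), 0),
                          c(0, 0, 1))
  expect_identical(g2$chirality, "right")
  expect_identical(g2$sign, -1L)
  # counter-clockwise alignment of the overlying strand gives the
  # positive sign
  g3 <- crossing_geometry(c(1, 0, 0), c(cos(pi / 4), -sin(pi / 4), 0),
                          c(0, 0, 1))
  expect_identical(g3$chirality, "right")
  expect_identical(g3$sign, 1L)
  # mirror image flips chirality and sign
  gm <- crossing_geometry(c(1, 0, 0) * c(1, 1, -1),
                          c(cos(pi / 4), sin(pi / 4), 0) * c(1, 1, -1),
                          c(0, 0, 1) * c(1, 1, -1))
  expect_identical(gm$chirality, "right")
  expect_identical(gm$sign, -g$sign)
  # reversing both tangent orientations leaves the sign unchanged
  gr <- crossing_geometry(-c(1, 0, 0), -c(cos(pi / 4), sin(pi / 4), 0),
                          c(0, 0, 1))
  expect_identical(gr$sign, g$sign)
  # swapping the two points changes nothing
  gs <- crossing_geometry(c(cos(pi / 4), sin(pi / 4), 0), c(1, 0, 0),
                          -c(0, 0, 1))
  expect_identical(gs$chirality, g$chirality)
  expect_identical(gs$sign, g$sign)
  expect_error(crossing_geometry(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
               "indeterminate")
})

test_that("an isolated crossing yields exactly one event", {
  ev <- detect_collisions(crossed_stretch_duplex())
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$distance_nm, 5, tolerance = 0.1)
  expect_identical(ev$type, 1L)
})

test_that("a relaxed circle has no distal juxtapositions", {
  expect_identical(nrow(detect_collisions(relaxed2000())), 0L)
})

test_that("negative plectonemes give right-handed negative collisions and
          mirrors flip them", {
  sc <- plectoneme5()
  ev <- detect_collisions(sc)
  expect_gte(nrow(ev), 4)
  expect_lte(nrow(ev), 6)
  expect_true(all(ev$chirality == "right"))
  expect_true(all(ev$sign == -1))
  evm <- detect_collisions(mirror_duplex(sc))
  expect_identical(nrow(evm), nrow(ev))
  expect_true(all(evm$chirality == "left"))
  expect_true(all(evm$sign == 1))
})

test_that("event counts are stable under a reduced-curve phase shift", {
  sc <- plectoneme5()
  n0 <- nrow(detect_collisions(sc, offset = 0))
  n5 <- nrow(detect_collisions(sc, offset = 5))
  expect_lte(abs(n0 - n5), 1)
})

test_that("detection respects the persistence-length exclusion", {
  sc <- plectoneme5()
  ev <- detect_collisions(sc)
  d <- abs(ev$idx_i - ev$idx_j)
  cyc <- pmin(d, 2000 - d)
  expect_true(all(cyc > 147))
})

test_that("collision types follow the region classification", {
  expect_identical(classify_type("unreplicated", 100, "unreplicated", 600),
                   1L)
  expect_identical(classify_type("unreplicated", 100, "daughter1", 40), 2L)
  expect_identical(classify_type("daughter1", 100, "daughter2", 120), 3L)
  expect_identical(classify_type("daughter1", 100, "daughter2", 500), 4L)
  # the early in-vivo fixture: right-handed supercoil contacts in the
  # unreplicated region, right-handed precatenane contacts in the braid
  ev <- detect_collisions(early_ri())
  t1 <- ev[ev$type == 1, ]
  expect_gt(nrow(t1), 0)
  expect_true(all(t1$chirality == "right"))
  t3 <- ev[ev$type == 3, ]
  expect_gt(nrow(t3), 0)
  expect_true(all(t3$chirality == "right"))
})

test_that("negative precatenanes collide left-handed", {
  cfg <- generator_config(n_bp = 2000, n_rep = 509, q_unrep = 0,
                          q_rep = -2, precatenane_Ca = -2, seed = 2)
  ev <- detect_collisions(make_ri(cfg))
  t3 <- ev[ev$type == 3, ]
  expect_gt(nrow(t3), 0)
  expect_true(all(t3$chirality == "left"))
})

test_that("tallies count type by chirality and average over frames", {
  empty <- detect_collisions(relaxed2000())
  tl <- tally_collisions(empty)
  expect_identical(nrow(tl), 8L)
  expect_true(all(tl$count == 0))
  sc <- plectoneme5()
  ev <- detect_collisions(sc)
  tl2 <- tally_collisions(ev)
  expect_equal(tl2$count[tl2$type == 1 & tl2$chirality == "right"],
               nrow(ev))
  expect_equal(sum(tl2$count), nrow(ev))
  # frame averaging
  ev$frame_time <- 1
  ev2 <- ev; ev2$frame_time <- 2
  tl3 <- tally_collisions(rbind(ev, ev2))
  expect_equal(sum(tl3$count), nrow(ev))
})
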