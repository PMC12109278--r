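# Synthetic-conformation generator: prescribed topology is realized and
# recoverable.

test_that("relaxed circles carry the rounded relaxed linking number", {
  d <- make_relaxed_circle(2100)
  expect_equal(linking_number(d$strandA, d$strandB), 200,
               tolerance = 0.01)
  expect_equal(writhe(duplex_axis(d)), 0, tolerance = 0.01)
  d2 <- relaxed2000()
  expect_equal(linking_number(d2$strandA, d2$strandB), round(2000 / 10.5),
               tolerance = 1e-3)
  expect_error(make_relaxed_circle(40), "at least 63")
})

test_that("supercoiled circles hit the prescribed linking difference with
          matching chirality", {
  sc <- make_supercoiled_circle(2000, -10, 1, seed = 1)
  dlk <- linking_number(sc$strandA, sc$strandB) - 190
  expect_equal(dlk, -10, tolerance = 0.2)
  expect_lt(writhe(duplex_axis(sc)), -5)  # right-handed interwinding
  scp <- make_supercoiled_circle(2000, 10, 1, seed = 1)
  expect_equal(linking_number(scp$strandA, scp$strandB) - 190, 10,
               tolerance = 0.2)
  expect_gt(writhe(duplex_axis(scp)), 5)  # left-handed interwinding
  # zero stress falls back to the relaxed construction
  sc0 <- make_supercoiled_circle(2000, 0, 1, seed = 1)
  expect_equal(linking_number(sc0$strandA, sc0$strandB) - 190, 0,
               tolerance = 0.05)
  expect_error(make_supercoiled_circle(2000, -0.5), "at least 1")
  expect_error(make_supercoiled_circle(2000, -2.5), "integer")
})

test_that("branched plectonemes show one secondary band per branch", {
  sc3 <- make_supercoiled_circle(2000, -10, 3, seed = 1)
  expect_equal(linking_number(sc3$strandA, sc3$strandB) - 190, -10,
               tolerance = 0.2)
  pr <- diagonal_band_profile(conformation_matrix(sc3))
  expect_identical(pr$n_secondary_bands, 3L)
  # off-band charge tracks the axis writhe
  expect_equal(pr$off_band_sum, writhe(duplex_axis(sc3)), tolerance = 0.5)
})

test_that("replication intermediates recover the prescribed partition", {
  dec <- decompose_ri(early_ri())
  expect_equal(dec$q_unrep, -12, tolerance = 0.3)
  expect_equal(dec$q_wrap, 0, tolerance = 0.3)
  expect_equal(dec$q_rep, 2, tolerance = 0.3)
  expect_equal(dec$c4_precatenanes, 2, tolerance = 0.3)
  expect_equal(dec$c5_plectonemes_of_precatenanes, 0, tolerance = 0.3)
  expect_equal(dec$delta_lk_total, -10, tolerance = 0.3)

  decl <- decompose_ri(late_ri())
  expect_equal(decl$q_unrep, -2, tolerance = 0.3)
  expect_equal(decl$q_rep, 12, tolerance = 0.3)
  expect_equal(decl$c4_precatenanes, 12, tolerance = 0.3)
  expect_equal(decl$delta_lk_total, 10, tolerance = 0.3)
})

test_that("a torsionally relaxed intermediate has near-zero components", {
  dec <- glance(decompose_ri(relaxed_ri()))
  for (comp in c("c1", "c2", "c3", "c4", "c5"))
    expect_equal(dec[[comp]], 0, tolerance = 0.1)
})

test_that("construction is deterministic for a fixed seed", {
  a <- make_supercoiled_circle(500, -3, 1, seed = 9)
  b <- make_supercoiled_circle(500, -3, 1, seed = 9)
  expect_identical(a$strandA$points, b$strandA$points)
  cfg <- generator_config(n_bp = 800, n_rep = 300, q_unrep = -3,
                          q_rep = 2, precatenane_Ca = 2, seed = 3)
  r1 <- make_ri(cfg)
  r2 <- make_ri(cfg)
  expect_identical(r1$parentalA$points, r2$parentalA$points)
  c2 <- make_supercoiled_circle(500, -3, 1, seed = 10)
  expect_false(identical(a$strandA$points, c2$strandA$points))
})

test_that("generator config validates its partition invariants", {
  expect_error(generator_config(q_rep = 2, precatenane_Ca = 1,
                                braid_writhe = 0.5),
               "precatenane_Ca \\+ braid_writhe")
  expect_error(generator_config(n_bp = 100, frac_replicated = 0.5),
               "at least 60 bp")
  cfg <- ri_config_early()
  expect_identical(cfg$n_unrep, 1491L)
  expect_identical(cfg$n_rep, 509L)
  cfgl <- ri_config_late()
  expect_identical(cfgl$n_unrep, 504L)
  expect_identical(cfgl$n_rep, 1506L)
  expect_equal(cfgl$q_unrep + cfgl$q_wrap + cfgl$q_rep, 10)
})

test_that("duplex strands stay at duplex separation", {
  d <- relaxed2000()
  sep <- sqrt(rowSums((d$strandA$points - d$strandB$points)^2))
  expect_true(all(sep >= 1.5 & sep <= 2.5))
  ri <- early_ri()
  iu <- seq_len(ri$n_unrep)
  sepu <- sqrt(rowSums((ri$parentalA$points[iu, ] -
                          ri$parentalB$points[iu, ])^2))
  expect_true(all(sepu >= 1.5 & sepu <= 2.5))
})
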