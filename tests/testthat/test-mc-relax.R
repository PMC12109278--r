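# Topology preservation and stress redistribution under the Monte Carlo
# relaxer.

test_that("closed-molecule linking number is invariant under relaxation", {
  sc <- plectoneme5()
  lk0_ <- linking_number(sc$strandA, sc$strandB)
  fr <- mc_relax(sc, 100000, seed = 3, n_frames = 2)
  f <- fr[[length(fr)]]$conformation
  expect_lt(abs(linking_number(f$strandA, f$strandB) - lk0_), 0.05)
  expect_gt(attr(fr, "acceptance"), 0.05)
})

test_that("fixed forks confine the region charges", {
  ri <- early_ri()
  q0 <- glance(decompose_ri(ri))
  fr <- mc_relax(ri, 100000, forks_free = FALSE, seed = 5, n_frames = 1)
  q1 <- glance(decompose_ri(fr[[length(fr)]]$conformation))
  expect_lt(abs(q1$q_unrep - q0$q_unrep), 0.3)
  expect_lt(abs(q1$q_rep - q0$q_rep), 0.3)
  expect_lt(abs(q1$delta_lk_total - q0$delta_lk_total), 0.1)
})

test_that("free forks redistribute charge while conserving the total", {
  ri <- early_ri()
  q0 <- glance(decompose_ri(ri))
  fr <- mc_relax(ri, 400000, forks_free = TRUE, seed = 1,
                 fork_move_prob = 0.4, n_frames = 1)
  q1 <- glance(decompose_ri(fr[[length(fr)]]$conformation))
  expect_lt(abs(q1$delta_lk_total - q0$delta_lk_total), 0.1)
  expect_gt(abs(q1$q_unrep - q0$q_unrep), 0.5)
})

test_that("trajectories are seeded, time-ordered and reproducible", {
  d <- make_relaxed_circle(210)
  fr1 <- mc_relax(d, 5000, seed = 8)
  fr2 <- mc_relax(d, 5000, seed = 8)
  expect_identical(fr1[[length(fr1)]]$conformation$strandA$points,
                   fr2[[length(fr2)]]$conformation$strandA$points)
  times <- vapply(fr1, function(f) f$time, 0)
  expect_true(all(diff(times) >= 0))
  fr3 <- mc_relax(d, 5000, seed = 9)
  expect_false(identical(fr1[[length(fr1)]]$conformation$strandA$points,
                         fr3[[length(fr3)]]$conformation$strandA$points))
  # zero moves returns the input unchanged
  fr0 <- mc_relax(d, 0)
  expect_identical(fr0[[1]]$conformation$strandA$points,
                   d$strandA$points)
})
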