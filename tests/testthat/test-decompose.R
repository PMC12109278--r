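# Block decomposition of Lk and the five-component partition.

test_that("block sums partition the full contribution matrix exactly", {
  ri <- early_ri()
  cm <- conformation_matrix(ri)
  bs <- block_sums(cm)
  expect_equal(sum(bs$charge), sum(cm$entries), tolerance = 1e-9)
  expect_identical(nrow(bs), 4L)
  # the a1 x b1 block sum minus the baseline is the unreplicated charge
  dec <- decompose_ri(ri)
  a1b1 <- bs$charge[bs$row_block == 1 & bs$col_block == 1]
  expect_equal(a1b1 - 1491 / 10.5, dec$q_unrep, tolerance = 1e-9)
})

test_that("components are internally consistent by construction", {
  for (ri in list(early_ri(), late_ri())) {
    d <- decompose_ri(ri)
    expect_equal(d$c1_dTw_unrep + d$c2_Wr_unrep, d$q_unrep,
                 tolerance = 1e-6)
    expect_equal(d$c3_wrapping, d$q_wrap, tolerance = 1e-12)
    expect_equal(d$c4_precatenanes + d$c5_plectonemes_of_precatenanes,
                 d$q_rep, tolerance = 1e-6)
    expect_equal(d$c1_dTw_unrep + d$c2_Wr_unrep + d$c3_wrapping +
                   d$c4_precatenanes + d$c5_plectonemes_of_precatenanes,
                 d$delta_lk_total, tolerance = 1e-6)
    # total parental linking number is an integer
    lk <- d$delta_lk_total + d$baseline_unrep
    expect_equal(lk, round(lk), tolerance = 1e-3)
  }
})

test_that("tidy and glance present the decomposition as tibbles", {
  d <- decompose_ri(early_ri())
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$component, paste0("c", 1:5))
  expect_equal(sum(td$value), d$delta_lk_total, tolerance = 1e-6)
  g <- glance(d)
  expect_identical(nrow(g), 1L)
  expect_equal(g$baseline_unrep, 142)
})

test_that("malformed intermediates are rejected", {
  ri <- early_ri()
  badA <- strand_curve(ri$parentalA$points, closed = TRUE,
                       region = "unreplicated")
  expect_error(replication_intermediate(badA, ri$parentalB,
                                        ri$daughter_new1,
                                        ri$daughter_new2,
                                        n_unrep = ri$n_unrep),
               "region labels")
  expect_error(replication_intermediate(ri$parentalA, ri$parentalB,
                                        ri$daughter_new2,
                                        ri$daughter_new2,
                                        n_unrep = ri$n_unrep - 5),
               "region labels|n_rep")
})
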