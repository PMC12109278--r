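# Domain types and oxDNA-format interoperability.

test_that("strand curves validate their invariants", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3, byrow = TRUE)
  s <- strand_curve(P, closed = TRUE)
  expect_identical(length(s), 3L)
  expect_error(strand_curve(P[1:2, ]), "at least 3")
  expect_error(strand_curve(rbind(P, P[3, ])), "distinct")
  expect_error(strand_curve(P, region = "bogus"), "unknown region")
  tb <- tibble::as_tibble(s)
  expect_identical(nrow(tb), 3L)
  expect_identical(tb$nt_index, 0:2)
})

test_that("a hand-written minimal file pair parses into one frame", {
  top <- c("6 2",
           "1 A 2 1", "1 T 0 2", "1 C 1 0",
           "2 G 5 4", "2 A 3 5", "2 T 4 3")
  conf <- c("t = 3.5",
            "b = 20 20 20",
            "E = 0 0 0",
            vapply(1:6, function(i)
              paste(c(i, i %% 2, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0),
                    collapse = " "), ""))
  tp <- withr::local_tempfile(fileext = ".top")
  cp <- withr::local_tempfile(fileext = ".dat")
  writeLines(top, tp); writeLines(conf, cp)
  fr <- read_oxdna(tp, cp)
  expect_identical(length(fr), 1L)
  expect_equal(fr[[1]]$time, 3.5)
  conf_obj <- fr[[1]]$conformation
  expect_s3_class(conf_obj, "duplex_conformation")
  expect_identical(nrow(conf_obj$strandA$points), 3L)
  # positions converted from oxDNA units to nm
  expect_equal(conf_obj$strandA$points[2, 1], 2 * 0.8518)
})

test_that("write/read roundtrip preserves coordinates, closure and counts", {
  d <- make_relaxed_circle(210)
  tp <- withr::local_tempfile(fileext = ".top")
  cp <- withr::local_tempfile(fileext = ".dat")
  write_oxdna(d, tp, cp)
  expect_identical(length(readLines(tp)), 421L)  # header + 2 x 210 records
  fr <- read_oxdna(tp, cp)
  conf <- fr[[1]]$conformation
  expect_true(conf$strandA$closed && conf$strandB$closed)
  expect_lt(max(abs(conf$strandA$points - d$strandA$points)), 1e-6)
  expect_lt(max(abs(conf$strandB$points - d$strandB$points)), 1e-6)
})

test_that("a 21-bp circle writes 42 nucleotide records", {
  th <- 2 * pi * (0:20) / 21
  A <- strand_curve(cbind(3 * cos(th), 3 * sin(th), 1), closed = TRUE)
  B <- strand_curve(cbind(3 * cos(th), 3 * sin(th), -1), closed = TRUE)
  d <- duplex_conformation(A, B)
  tp <- withr::local_tempfile(fileext = ".top")
  cp <- withr::local_tempfile(fileext = ".dat")
  write_oxdna(d, tp, cp)
  expect_identical(length(readLines(tp)) - 1L, 42L)
})

test_that("replication intermediates roundtrip through the sidecar map", {
  cfg <- generator_config(n_bp = 800, n_rep = 300, q_unrep = -3,
                          q_rep = 2, precatenane_Ca = 2, seed = 3)
  ri <- make_ri(cfg)
  tp <- withr::local_tempfile(fileext = ".top")
  cp <- withr::local_tempfile(fileext = ".dat")
  write_oxdna(ri, tp, cp)
  expect_true(file.exists(paste0(cp, ".regions.json")))
  ri2 <- read_oxdna(tp, cp)[[1]]$conformation
  expect_s3_class(ri2, "replication_intermediate")
  expect_identical(ri2$n_unrep, ri$n_unrep)
  expect_lt(max(abs(ri2$daughter_new1$points - ri$daughter_new1$points)),
            1e-6)
  expect_identical(ri2$parentalA$region, ri$parentalA$region)
  # every nucleotide index appears in exactly one region
  rmap <- jsonlite::read_json(paste0(cp, ".regions.json"),
                              simplifyVector = TRUE)
  spans <- rmap$regions[rmap$regions$strand == 1, ]
  covered <- unlist(mapply(function(f, t) f:(t - 1), spans$from, spans$to))
  expect_identical(sort(covered), 0:(ri$n_parental - 1))
})

test_that("multi-frame configurations give one frame per block", {
  d <- make_relaxed_circle(105)
  tp <- withr::local_tempfile(fileext = ".top")
  cp <- withr::local_tempfile(fileext = ".dat")
  write_oxdna(list(trajectory_frame(0, d), trajectory_frame(10, d)),
              tp, cp)
  fr <- read_oxdna(tp, cp)
  expect_identical(length(fr), 2L)
  expect_equal(vapply(fr, function(f) f$time, 0), c(0, 10))
})

test_that("format errors name the offending location", {
  d <- make_relaxed_circle(105)
  tp <- withr::local_tempfile(fileext = ".top")
  cp <- withr::local_tempfile(fileext = ".dat")
  write_oxdna(d, tp, cp)
  top <- readLines(tp)
  writeLines(top[-5], tp)
  expect_error(read_oxdna(tp, cp), "declares 210")
  writeLines(top, tp)
  conf <- readLines(cp)
  conf[4] <- "not numbers at all x y z"
  writeLines(conf, cp)
  expect_error(read_oxdna(tp, cp), "non-numeric")
})
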