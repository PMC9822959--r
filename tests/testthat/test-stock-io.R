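test_that("stock CSV parsing handles clean rows, gaps and missing values", {
  p <- write_stock_fixture(c("Year,SSB,R,F",
                             "2000,100,50,0.3",
                             "2001,110,55,0.2"))
  s <- read_stock_csv(p, recruitment_age = 0)
  expect_s3_class(s, "stock_series")
  expect_equal(nrow(s), 2)
  expect_equal(s$year, c(2000L, 2001L))
  expect_equal(s$ssb, c(100, 110))

  gap <- write_stock_fixture(c("Year,SSB,R,F",
                               "2000,100,50,0.3",
                               "2002,110,55,0.2"))
  expect_error(read_stock_csv(gap), class = "fishshift_validation_error",
               regexp = "2001")

  na_r <- write_stock_fixture(c("Year,SSB,R,F",
                                "2000,100,NA,0.3",
                                "2001,110,55,0.2"))
  s2 <- read_stock_csv(na_r)
  expect_true(is.na(s2$recruitment[1]))
  expect_equal(s2$ssb, c(100, 110))
  expect_equal(s2$fmort, c(0.3, 0.2))

  bad_col <- write_stock_fixture(c("Year,Biomass,R,F", "2000,1,1,0"))
  expect_error(read_stock_csv(bad_col), class = "fishshift_format_error",
               regexp = "SSB")
})

test_that("write/read round-trips a stock series bit-exactly", {
  set.seed(1)
  s <- stock_series(2001:2030, exp(rnorm(30, 10, 1)), exp(rnorm(30, 8, 1)),
                    runif(30, 0, 1.3), stock_id = "rt", recruitment_age = 1)
  s$recruitment[c(4, 9)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_stock_csv(s, path)
  s2 <- read_stock_csv(path, recruitment_age = 1, stock_id = "rt")
  expect_identical(s2$ssb, s$ssb)
  expect_identical(s2$recruitment, s$recruitment)
  expect_identical(s2$fmort, s$fmort)
  expect_identical(s2$year, s$year)
})

test_that("recruitment is shifted to its spawn year", {
  s <- stock_series(2000:2002, c(10, 20, 30), c(5, 6, 7), c(0, 0, 0),
                    recruitment_age = 1)
  pairs <- align_srr(s)
  expect_equal(pairs$year, c(2000L, 2001L))
  expect_equal(pairs$s, c(10, 20))
  expect_equal(pairs$r, c(6, 7))

  attr(s, "recruitment_age") <- 0L
  p0 <- align_srr(s)
  expect_equal(nrow(p0), 3)
  expect_equal(p0$r, c(5, 6, 7))

  attr(s, "recruitment_age") <- 3L
  expect_error(align_srr(s), class = "fishshift_input_error")
})

test_that("spawn-year alignment drops incomplete pairs and stays in range", {
  set.seed(7)
  for (a in 0:2) {
    ssb <- runif(20, 50, 150)
    rec <- runif(20, 10, 90)
    rec[c(3, 11)] <- NA
    ssb[15] <- NA
    s <- stock_series(1981:2000, ssb, rec, rep(0.2, 20), recruitment_age = a)
    pairs <- align_srr(s)
    expect_true(all(pairs$year + a <= 2000))
    complete <- sum(!is.na(ssb[seq_len(20 - a)]) &
                      !is.na(rec[seq_len(20 - a) + a]))
    expect_equal(nrow(pairs), complete)
  }
})

test_that("SST reader validates, sorts and rejects duplicates", {
  p <- write_stock_fixture(c("Year,SST", "2001,10.4", "2000,10.1"))
  e <- read_sst_csv(p)
  expect_equal(e$year, c(2000L, 2001L))
  expect_equal(e$sst, c(10.1, 10.4))

  dup <- write_stock_fixture(c("Year,SST", "2000,10.4", "2000,10.1"))
  expect_error(read_sst_csv(dup), class = "fishshift_validation_error")

  bad <- write_stock_fixture(c("Year,SST", "2000,10.4", "2001,warm"))
  expect_error(read_sst_csv(bad), class = "fishshift_format_error",
               regexp = "2")
})

test_that("series invariants are enforced", {
  expect_error(stock_series(c(2000, 2000), c(1, 1), c(1, 1), c(0, 0)),
               class = "fishshift_validation_error")
  expect_error(stock_series(2000:2001, c(-1, 1), c(1, 1), c(0, 0)),
               class = "fishshift_validation_error")
  expect_error(stock_series(2000:2001, c(1, 1), c(1, 1), c(-0.1, 0)),
               class = "fishshift_validation_error")
  expect_error(reference_points(b_lim = 10, b_pa = 5),
               class = "fishshift_validation_error")
})
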