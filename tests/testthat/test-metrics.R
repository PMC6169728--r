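# Explained common variance, R^2 = beta^2, and domain loading summaries.

test_that("ECV handles the limiting configurations", {
  tbl <- tibble::tibble(general = c(0.5, 0.6), specific = c(0, 0))
  expect_equal(ecv(tbl), 100)
  tbl2 <- tibble::tibble(general = c(0.4, 0.7), specific = c(0.4, 0.7))
  expect_equal(ecv(tbl2), 50)
  expect_error(ecv(tibble::tibble(general = 0, specific = 0)), "undefined")
})

test_that("ECV is invariant to item order and global sign flips", {
  withr::with_seed(2, {
    tbl <- tibble::tibble(general = runif(20, -1, 1), specific = runif(20, -1, 1))
    e0 <- ecv(tbl)
    expect_equal(ecv(tbl[sample(20), ]), e0)
    flipped <- tbl
    flipped$general <- -flipped$general
    expect_equal(ecv(flipped), e0)
  })
})

test_that("variance explained is beta squared, in percent", {
  expect_equal(r2_from_beta(0), 0)
  expect_equal(r2_from_beta(0.13), 1.69)
  expect_equal(r2_from_beta(-0.05), 0.25)      # even function
  expect_equal(r2_from_beta(0.05), r2_from_beta(-0.05))
  b <- seq(0, 1, by = 0.05)
  expect_true(all(diff(r2_from_beta(b)) > 0))  # monotone in |beta|
  expect_error(r2_from_beta(1.2), "<= 1")
})

test_that("loading summaries aggregate general loadings by domain", {
  one <- tibble::tibble(scale = "ia", general = 0.62)
  s1 <- loading_summary(one)
  expect_equal(s1$mean, 0.62)
  expect_equal(s1$min, 0.62)
  expect_equal(s1$max, 0.62)

  tbl <- tibble::tibble(
    scale = c("ia", "ia", "odd", "dep"),
    general = c(0.7, 0.5, 0.45, 0.3)
  )
  s <- loading_summary(tbl)
  expect_equal(s$mean[s$domain == "neurodevelopmental"], 0.6)
  expect_true(all(s$mean >= s$min & s$mean <= s$max))
  expect_error(loading_summary(tibble::tibble(scale = "mystery", general = 0.5)),
               "mystery")
})

test_that("shipped loading tables round-trip and carry both designs", {
  a <- example_loadings("atac")
  s <- example_loadings("smfq_scared")
  expect_equal(nrow(a), 62)
  expect_equal(nrow(s), 99)
  expect_true(all(abs(a$general) <= 1 & abs(a$specific) <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_loading_table(a, path)
  expect_equal(as.data.frame(read_loading_table(path)), as.data.frame(a))
})
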