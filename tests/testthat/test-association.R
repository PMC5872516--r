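make_binary_df <- function(mat) {
  as.data.frame(lapply(as.data.frame(mat), function(v)
    factor(ifelse(v == 1, "yes", "no"), levels = c("no", "yes"))))
}

test_that("combination exposure is exact-profile matching", {
  d <- make_binary_df(rbind(
    c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 0, 0), c(1, 0, 0, 0)
  ))
  names(d) <- paste0("m", 1:4)
  e <- combination_exposure(d, names(d), c(1, 0, 0, 0))
  expect_equal(e, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(combination_exposure(d, names(d), c(1, 1, 1, 1)),
               rep(FALSE, 4))
  # "at least" mode ignores zero bits
  expect_equal(combination_exposure(d, names(d), c(1, 0, 0, 0),
                                    mode = "at_least"),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_error(combination_exposure(d, names(d), c(0, 0, 0, 0)), "mask")
  expect_error(combination_exposure(d, names(d), c(1, 0)), "length")
})

test_that("odds ratios follow the cross-ratio formula", {
  e <- rep(c(TRUE, FALSE), c(30, 45))
  o <- rep(c(1, 0, 1, 0), c(10, 20, 5, 40))
  r <- odds_ratio(e, o)
  expect_equal(r$odds_ratio, 4.0)
  expect_false(r$haldane)

  # a = b and c = d gives OR 1
  r2 <- odds_ratio(rep(c(TRUE, FALSE), each = 20),
                   rep(c(1, 0), times = 20))
  expect_equal(r2$odds_ratio, 1.0)
  expect_error(odds_ratio(logical(0), logical(0)), "empty")
})

test_that("odds ratios match an independent transcription, zero cells included", {
  set.seed(41)
  for (i in 1:200) {
    cells <- c(sample(0:2, 1), sample(0:40, 3, TRUE))[sample(4)]
    if (sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    e <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    o <- rep(c(1, 0, 1, 0), cells)
    r <- odds_ratio(e, o)
    w <- oracle_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$odds_ratio, w$or, tolerance = 1e-12)
    expect_equal(r$ci_low, w$lo, tolerance = 1e-12)
    expect_equal(r$ci_high, w$hi, tolerance = 1e-12)
    expect_identical(r$haldane, min(cells) == 0L)
    expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  }
})

test_that("the combination table walks the published mask order", {
  set.seed(42)
  d <- make_binary_df(matrix(rbinom(400 * 4, 1, 0.3), ncol = 4))
  names(d) <- paste0("m", 1:4)
  y <- rbinom(400, 1, 0.5)
  tab <- combination_table(d, names(d), y = y)
  expect_equal(nrow(tab), 15L)
  got <- apply(tab[, paste0("m", 1:4)], 1, paste, collapse = "")
  expect_equal(got, c(
    "1000", "0100", "0010", "0001",
    "1001", "1010", "1100", "0101", "0110", "0011",
    "1011", "1101", "1110", "0111", "1111"
  ))
  expect_equal(tab$combination, sprintf("CoRF%d", 1:15))

  # exposure profiles partition the cohort: counts over all 2^k masks sum n
  exposed_total <- sum(tab$a + tab$b)
  none <- combination_exposure(d, names(d), c(1, 1, 1, 1))  # placeholder
  all_zero <- rowSums(sapply(d, function(col) col == "yes")) == 0
  expect_equal(exposed_total + sum(all_zero), 400)

  expect_equal(nrow(combination_table(d, "m1", y = y)), 1L)
  expect_error(combination_table(d, character(0), y = y), "between")
})

test_that("a planted cause carries a positive singleton odds ratio", {
  net <- generate_discrete_network(synthetic_spec(n_planted = 1, seed = 43),
                                   n = 2000)
  tab <- combination_table(net$x, net$causes, y = net$y)
  expect_gt(tab$odds_ratio[1], 1)
})
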