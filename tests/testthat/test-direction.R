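test_that("conversion enumerates joint states with the last component fastest", {
  d <- data.frame(
    x5 = factor("a", levels = letters[1:2]),
    x6 = factor("a", levels = letters[1:3]),
    x9 = factor("a", levels = letters[1:2])
  )
  cf <- convert_features(d, c("x5", "x6", "x9"))
  expect_equal(cf$m_bar, 12L)
  m <- cf$m
  expect_equal(convert_index(c(1L, 1L, 1L), m), 1L)
  expect_equal(convert_index(c(1L, 1L, 2L), m), 2L)      # advance last component
  expect_equal(convert_index(c(1L, 2L, 1L), m), 3L)      # = m9 + 1
  expect_equal(convert_index(c(2L, 3L, 2L), m), 12L)     # all-last tuple = prod
  # single component: identity map
  expect_equal(convert_index(matrix(1:4), 4L), 1:4)
  expect_error(convert_features(d, character(0)), "empty")
})

test_that("conversion is a bijection on a handful of random alphabets", {
  set.seed(31)
  for (i in 1:10) {
    m <- sample(2:6, sample(1:4, 1), replace = TRUE)
    idx <- seq_len(prod(m))
    tup <- convert_decode(idx, m)
    expect_equal(convert_index(tup, m), idx)
    expect_equal(nrow(unique(tup)), prod(m))
  }
  expect_error(convert_decode(0L, c(2L, 2L)), "range")
})

test_that("a deterministic mechanism gives zero residuals and p = 1", {
  x <- rep(1:4, each = 25)
  y <- c(0L, 1L, 1L, 0L)[x]
  fit <- fit_anm(x, y, m_x = 4L, m_y = 2L)
  expect_true(all(fit$residuals == 0L))
  expect_equal(fit$independence_p, 1)
})

test_that("the additive-noise asymmetry identifies the planted direction", {
  hits <- vapply(1:8, function(s) {
    net <- generate_discrete_network(
      synthetic_spec(n_planted = 3, seed = 300 + s), n = 2000
    )
    cf <- convert_features(net$x, net$causes)
    fwd <- fit_anm(cf, net$y, m_y = 2L)
    bwd <- fit_anm(net$y + 1L, cf$index, m_x = 2L, m_y = cf$m_bar)
    fwd$independence_p > 0.05 && bwd$independence_p <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.75)
})

test_that("independent variables claim no direction", {
  set.seed(33)
  x <- sample.int(6, 1500, replace = TRUE)
  y <- rbinom(1500, 1, 0.4)
  fwd <- fit_anm(x, y, m_x = 6L, m_y = 2L)
  bwd <- fit_anm(y + 1L, x, m_x = 2L, m_y = 6L)
  expect_false(fwd$independence_p > 0.05 && bwd$independence_p <= 0.05)
})

test_that("discover_causes finds the planted cause set on a clean blanket", {
  spec <- synthetic_spec(n_cases = 200, n_controls = 200, n_features = 40,
                         n_planted = 3, seed = 35)
  net <- generate_discrete_network(spec, n = 400)
  res <- discover_causes(net$x, net$causes, y = net$y)
  expect_true(res$accepted)
  expect_setequal(res$causes, net$causes)
  expect_gt(res$forward_p, res$alpha %||% 0.05)
})

test_that("a lone outcome child is not accepted as a cause", {
  spec <- synthetic_spec(n_features = 30, n_planted = 1, n_children = 1,
                         seed = 36)
  net <- generate_discrete_network(spec, n = 2000)
  child <- setdiff(net$mb, net$causes)
  res <- discover_causes(net$x, child, y = net$y)
  expect_false(res$accepted)
  expect_length(res$causes, 0L)
})

test_that("empty blankets and member order do not change the result", {
  spec <- synthetic_spec(n_features = 30, n_planted = 2, seed = 37)
  net <- generate_discrete_network(spec, n = 1000)
  expect_false(discover_causes(net$x, character(0), y = net$y)$accepted)

  r1 <- discover_causes(net$x, net$causes, y = net$y)
  r2 <- discover_causes(net$x, rev(net$causes), y = net$y)
  expect_identical(r1$causes, r2$causes)
  expect_identical(r1$accepted, r2$accepted)
})

test_that("oversized joint alphabets are skipped by the reliability cap", {
  d <- data.frame(
    a = factor(sample(1:6, 60, TRUE), levels = 1:6),
    b = factor(sample(1:6, 60, TRUE), levels = 1:6)
  )
  y <- rbinom(60, 1, 0.5)
  res <- discover_causes(d, c("a", "b"), y = y)
  expect_true(all(res$search$status[res$search$size == 2] == "skipped_mbar"))
})
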