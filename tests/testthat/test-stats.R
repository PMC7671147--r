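test_that("identical groups give p = 1 and zero observed difference", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  res <- perm_t_test(x, x, n_perm = 499, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_diff, 0)
  expect_error(perm_t_test(1, c(1, 2)), "insufficient")
})

test_that("exhaustive enumeration reproduces the hand-counted p for separated groups", {
  # choose(6, 3) = 20 assignments; only the observed split and its mirror
  # reach |mean difference| = 100, so the exact two-sided p is 2/20
  res <- perm_t_test(c(1, 2, 3), c(101, 102, 103), method = "exhaustive")
  expect_equal(res$p_value, 2 / 20)
  expect_equal(res$n_permutations, 20L)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration within binomial error", {
  set.seed(21)
  a <- rnorm(4); b <- rnorm(4) + 1.2
  exact <- perm_t_test(a, b, method = "exhaustive")$p_value
  mc <- perm_t_test(a, b, n_perm = 4999, seed = 8)$p_value
  se <- sqrt(exact * (1 - exact) / 4999)
  expect_lt(abs(mc - exact), 3 * se + 2 / 4999)
})

test_that("permutation p-values are invariant to label swap, shift, and scale", {
  set.seed(13)
  a <- rnorm(6, 1); b <- rnorm(5)
  # exact invariances hold under complete enumeration
  p0 <- perm_t_test(a, b, method = "exhaustive")$p_value
  expect_equal(perm_t_test(b, a, method = "exhaustive")$p_value, p0)
  expect_equal(perm_t_test(a + 7, b + 7, method = "exhaustive")$p_value, p0)
  expect_equal(perm_t_test(a * 3, b * 3, method = "exhaustive")$p_value, p0)
  # Monte-Carlo estimates of the swapped design agree within sampling error
  pm <- perm_t_test(a, b, n_perm = 1999, seed = 3)$p_value
  ps <- perm_t_test(b, a, n_perm = 1999, seed = 4)$p_value
  se <- sqrt(p0 * (1 - p0) / 1999)
  expect_lt(abs(pm - ps), 6 * se + 2 / 2000)
  # shift and scale leave the Monte-Carlo draw stream itself unchanged
  expect_equal(perm_t_test(a + 7, b + 7, n_perm = 999, seed = 3)$p_value,
               perm_t_test(a, b, n_perm = 999, seed = 3)$p_value)
  expect_equal(perm_t_test(a * 3, b * 3, n_perm = 999, seed = 3)$p_value,
               perm_t_test(a, b, n_perm = 999, seed = 3)$p_value)
})

test_that("p-values respect the add-one floor and determinism in the seed", {
  a <- 1:5; b <- 6:10
  r1 <- perm_t_test(a, b, n_perm = 199, seed = 5)
  r2 <- perm_t_test(a, b, n_perm = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  # studentized statistic is permutationally equivalent here
  rt <- perm_t_test(a, b, n_perm = 199, seed = 5, statistic = "t")
  expect_equal(rt$p_value, r1$p_value)
})

test_that("null p-values are close to uniform", {
  set.seed(31)
  ps <- replicate(400, perm_t_test(rnorm(5), rnorm(5), n_perm = 99,
                                   seed = sample.int(1e6, 1))$p_value)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("log-log regression recovers exact and noisy power laws", {
  x <- seq(1, 10, length.out = 12)
  fit <- power_law_fit(x, x^2)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  fit2 <- power_law_fit(x, 3 * x^-1.5)
  expect_equal(fit2$slope, -1.5, tolerance = 1e-12)
  expect_equal(fit2$intercept, log(3), tolerance = 1e-12)
  set.seed(17)
  x3 <- seq(0.5, 8, length.out = 15)
  fit3 <- power_law_fit(x3, x3^-3 * exp(rnorm(15, sd = 0.1)))
  expect_lt(abs(fit3$slope + 3), 0.1)
  expect_error(power_law_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("summary tables report group means, SEs, and permutation tests", {
  cfg <- run_config(n_permutations = 199)
  ident <- matrix(rep(c(3, 5), each = 10), 10, 2,
                  dimnames = list(NULL, c("m1", "m2")))
  g <- rep(c("A", "B"), each = 5)
  tab <- build_summary(ident, g, cfg)
  expect_equal(tab$p_value, c(1, 1))
  expect_equal(tab$se_A, c(0, 0))
  expect_false(any(tab$significant))

  set.seed(2)
  sep <- cbind(strong = c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)))
  tab2 <- build_summary(sep, g, cfg)
  expect_true(tab2$significant)
  expect_equal(tab2$p_value, 1 / 200)

  # single individual in a group: SE undefined, test skipped
  single <- cbind(m = c(1, 2, 3, 4))
  tab3 <- build_summary(single, c("A", "A", "A", "B"), cfg)
  expect_true(is.na(tab3$se_B))
  expect_true(is.na(tab3$p_value))
  expect_warning(
    build_summary(cbind(ok = c(1, 2, 3, 4), gone = NA_real_),
                  c("A", "A", "B", "B"), cfg),
    "omitted")
})
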