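test_that("group summaries compute n, mean and extrema", {
  s <- group_summary(c(1, 2, 3), "g", "m")
  expect_equal(s[, c("n", "mean", "min", "max")],
               data.frame(n = 3L, mean = 2, min = 1, max = 3))
  s1 <- group_summary(4.2, "g", "m")
  expect_true(s1$mean == 4.2 && s1$min == 4.2 && s1$max == 4.2)
  expect_error(group_summary(numeric(0), "g", "m"), "empty")
})

test_that("U and the exact p-value match hand-checked cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 0.1)   # 2 of choose(6,3) = 20 arrangements
  expect_identical(res$method, "exact_enumeration")

  sym <- suppressWarnings(mann_whitney_u(c(1, 2), c(1, 2)))
  expect_equal(sym$U, 2)               # n1 n2 / 2
  expect_equal(sym$p_two_sided, 1)
})

test_that("exact p equals brute-force enumeration for all small partitions", {
  set.seed(404)
  pools <- list(
    function(n) sample(1:4, n, replace = TRUE),    # heavy ties
    function(n) rnorm(n),                          # tie-free
    function(n) round(rnorm(n), 1)                 # occasional ties
  )
  for (n in 4:10) {
    for (n1 in 1:(n - 1)) {
      for (gen in pools) {
        vals <- gen(n)
        if (length(unique(vals)) == 1L) next
        x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
        res <- mann_whitney_u(x, y, mode = "exact")
        expect_equal(res$p_two_sided, brute_mwu_p(x, y),
                     info = sprintf("n1=%d n2=%d", n1, n - n1))
      }
    }
  }
})

test_that("normal approximation tracks the exact p for tie-free 8 vs 8", {
  set.seed(77)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, 0, 1.5))
    pe <- mann_whitney_u(x, y, mode = "exact")$p_two_sided
    pa <- mann_whitney_u(x, y, mode = "approx")$p_two_sided
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("U statistics of the two orderings sum to n1 * n2 without ties", {
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(7); y <- rnorm(11)
    expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 7 * 11)
  }
})

test_that("p is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rexp(9); y <- rexp(13, rate = 0.5)
  p1 <- mann_whitney_u(x, y)$p_two_sided
  p2 <- mann_whitney_u(exp(x), exp(y))$p_two_sided
  p3 <- mann_whitney_u(log(x), log(y))$p_two_sided
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("the approximation agrees with the reference implementation", {
  set.seed(9)
  x <- round(rnorm(25, 5), 1); y <- round(rnorm(18, 5.6), 1)   # with ties
  mine <- mann_whitney_u(x, y, mode = "approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
  expect_true(mine$tie_corrected)
})

test_that("degenerate identical data yield p = 1 with a warning", {
  expect_warning(res <- mann_whitney_u(rep(2, 5), rep(2, 7)), "degenerate")
  expect_equal(res$p_two_sided, 1)
})

test_that("the below-threshold re-test restricts, errors and degrades correctly", {
  g1 <- data.frame(diameter_ratio = c(6, 8, 12, 3, 4))
  g2 <- data.frame(diameter_ratio = c(2, 3.5, 4.2, 9))

  # threshold above every observation: identical to the unrestricted test
  full <- mann_whitney_u(g1$diameter_ratio, g2$diameter_ratio)
  re <- below_threshold_retest(g1, g2, threshold = 100)
  expect_equal(re$U, full$U)
  expect_equal(re$p_two_sided, full$p_two_sided)

  # threshold below every observation: domain error naming the group
  expect_error(below_threshold_retest(g1, g2, threshold = 1), "group 1")
  expect_error(below_threshold_retest(g1, data.frame(diameter_ratio = 9),
                                      threshold = 5), "group 2")

  # when both restricted samples come from one distribution, the test is
  # usually non-significant
  set.seed(15)
  nonsig <- 0L
  for (s in 1:20) {
    d1 <- runif(40, 2, 9)
    d2 <- c(runif(20, 2, 6), runif(10, 6, 12))
    r <- below_threshold_retest(d1, d2, threshold = 6)
    nonsig <- nonsig + (r$p_two_sided > 0.05)
  }
  expect_gt(nonsig, 10L)
})
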