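test_that("the Shapiro-Wilk gate separates normal from skewed samples", {
  set.seed(101)
  gate_norm <- vapply(1:50, function(i) normalityGate(rnorm(200)), logical(1))
  expect_gte(mean(gate_norm), 0.9)
  gate_exp <- vapply(1:50, function(i) normalityGate(rexp(200)), logical(1))
  expect_lte(mean(gate_exp), 0.1)

  expect_warning(res <- normalityGate(rep(2, 20)), "constant")
  expect_false(res)
  expect_error(normalityGate(c(1, 2)), "at least 3")
})

test_that("identical samples give p = 1 and Bonferroni arithmetic is exact", {
  r <- compareGroups(1:30, 1:30, method = "wilcoxon")
  expect_equal(r$raw_p, 1)
  expect_equal(r$test_used, "wilcoxon_rank_sum")

  set.seed(102)
  a <- rnorm(40); b <- rnorm(40, 0.9)
  r <- compareGroups(a, b, m = 10L, method = "student")
  expect_equal(r$adjusted_p, min(1, r$raw_p * 10))
  # the printed example: raw 0.01 with m = 10 adjusts to 0.1, not significant
  expect_equal(min(1, 0.01 * 10), 0.1)
  r2 <- compareGroups(a, b + 100, m = 10L)   # raw p astronomically small
  expect_true(r2$significant)
  # monotone in m, capped at 1
  adj <- vapply(c(1, 5, 50, 5000), function(m)
    compareGroups(a, b, m = m, method = "student")$adjusted_p, numeric(1))
  expect_true(all(diff(adj) >= 0))
  expect_lte(max(adj), 1)
})

test_that("a clear location shift is detected with the right direction", {
  set.seed(103)
  a <- rnorm(100); b <- rnorm(100, mean = 2)   # 2 pooled-sd shift
  r <- compareGroups(a, b, m = 1L)
  expect_true(r$significant)
  expect_equal(r$effect_direction, 1)
  rswap <- compareGroups(b, a, m = 1L)
  expect_equal(rswap$raw_p, r$raw_p)           # symmetric in p
  expect_equal(rswap$effect_direction, -1)     # direction flips
})

test_that("the t branch agrees with a permutation oracle at moderate effect", {
  set.seed(104)
  a <- rnorm(100); b <- rnorm(100, mean = 0.45)
  r <- compareGroups(a, b, m = 1L, method = "student")
  pooled <- c(a, b)
  obs <- abs(mean(b) - mean(a))
  nperm <- 20000L
  exceed <- 0L
  for (i in seq_len(nperm)) {
    idx <- sample.int(200, 100)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs)
      exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1) / (nperm + 1)
  expect_lt(abs(r$raw_p - p_perm) / p_perm, 0.35)
})

test_that("summaries follow the median/MAD and n-1 variance conventions", {
  s <- summarizeFeature(c(1, 2, 3, 4, 100))
  expect_equal(unname(s["median"]), 3)
  expect_equal(unname(s["mad"]), 1)            # plain MAD, no constant
  s1 <- summarizeFeature(5)
  expect_equal(unname(s1["mean"]), 5)
  expect_true(is.na(s1["std"]))

  set.seed(105)
  x <- rnorm(1000, 10, 3)
  s <- summarizeFeature(x)
  m <- sum(x) / length(x)                      # two-pass explicit variance
  v <- sum((x - m)^2) / (length(x) - 1)
  expect_equal(unname(s["variance"]), v)
  expect_equal(unname(s["std"])^2, unname(s["variance"]))
  expect_error(summarizeFeature(NA_real_), "empty")
})

test_that("the variance table recovers per-condition dispersion", {
  df <- data.frame(condition = rep(c("UC", "T"), each = 4),
                   f = c(1, 2, 3, 4, 10, 30, 50, 70))
  vt <- varianceTable(df, "f")
  expect_equal(dim(vt), c(2L, 3L))
  expect_equal(vt$var_f[vt$condition == "UC"], var(c(1, 2, 3, 4)))
  expect_equal(vt$n, c(4L, 4L))

  # generated 10:1 variance ratio recovered within 2x over seeds
  set.seed(106)
  ratios <- vapply(1:20, function(i) {
    d <- data.frame(condition = rep(c("UC", "T"), each = 200),
                    f = c(rnorm(200, 0, sqrt(10)), rnorm(200, 0, 1)))
    v <- varianceTable(d, "f")
    v$var_f[v$condition == "UC"] / v$var_f[v$condition == "T"]
  }, numeric(1))
  expect_true(all(ratios > 5 & ratios < 20))

  # empty feature column yields a missing cell
  df$g <- NA_real_
  expect_true(all(is.na(varianceTable(df, "g")$var_g)))
})
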