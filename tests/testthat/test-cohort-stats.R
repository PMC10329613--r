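fixture <- system.file("extdata", "cohort_table1.csv", package = "cbctvol")

test_that("the packaged cohort table parses into 40 site records", {
  rec <- parse_cohort_table(fixture)
  expect_equal(nrow(rec), 40)
  expect_equal(length(unique(rec$participant)), 23)
})

test_that("cohort summary reproduces the demographic tallies", {
  s <- cohort_summary(parse_cohort_table(fixture))
  expect_equal(unname(s$sex_counts["M"]), 14)
  expect_equal(unname(s$sex_counts["F"]), 9)
  expect_equal(unname(s$gap_size_counts["1_tooth"]), 13)
  expect_equal(s$n_sites, 40)
  expect_equal(unname(s$hvc_counts[c("HL", "CL", "CM", "HM")]), c(27, 6, 6, 1))
  expect_equal(round(s$age$mean, 2), 45.48)
  expect_equal(round(s$age$sd, 2), 12.52)
})

test_that("parser validates rows and handles the empty table", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant,sex,age,tooth,hvc", tmp)
  expect_equal(nrow(parse_cohort_table(tmp)), 0)
  writeLines(c("participant,sex,age,tooth,hvc", "1,M,40,11,XX"), tmp)
  expect_error(parse_cohort_table(tmp), "row 1")
  writeLines(c("participant,sex,age,tooth,hvc", "1,M,40,99,HL"), tmp)
  expect_error(parse_cohort_table(tmp), "FDI")
  writeLines(c("participant,sex,age,tooth,hvc", "1,M,15,11,HL"), tmp)
  expect_error(parse_cohort_table(tmp), "18")
})

test_that("descriptive statistics follow the n-1 conventions", {
  d <- descriptive(c(1, 2, 3))
  expect_equal(d$mean, 2); expect_equal(d$sd, 1); expect_equal(d$median, 2)
  d1 <- descriptive(5)
  expect_equal(d1$mean, 5); expect_true(is.na(d1$sd))
  expect_equal(descriptive(c(1, 2, 3, 4))$median, 2.5)
  expect_error(descriptive(numeric(0)))
})

test_that("wilcoxon worked example: six positive differences", {
  r <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p_value, 2 / 64)
  expect_equal(r$statistic, 21)
  expect_true(r$exact)
})

test_that("identical pairs give the degenerate p = 1", {
  expect_warning(r <- wilcoxon_signed_rank(1:8, 1:8), "zero")
  expect_equal(r$p_value, 1)
  expect_equal(r$n, 0L)
})

test_that("exact wilcoxon p equals full-enumeration oracle for n <= 10", {
  ## independent oracle: enumerate all 2^m sign assignments explicitly
  oracle <- function(x, y) {
    d <- x - y; d <- d[d != 0]
    m <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    ws <- as.vector(signs %*% r)
    min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
  }
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    x <- round(stats::rnorm(n, 0, 2), 1)
    y <- round(stats::rnorm(n, 0.5, 2), 1)
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact wilcoxon agrees with stats::wilcox.test when tie-free", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n, 0.4)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, ref$p.value,
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon p is invariant to swapping arms and common shifts", {
  set.seed(23)
  x <- stats::rnorm(12); y <- stats::rnorm(12, 0.5)
  p1 <- wilcoxon_signed_rank(x, y)$p_value
  expect_equal(wilcoxon_signed_rank(y, x)$p_value, p1)
  expect_equal(wilcoxon_signed_rank(x + 3, y + 3)$p_value, p1)
})

test_that("large-sample wilcoxon approximation tracks the exact branch", {
  set.seed(24)
  x <- stats::rnorm(14); y <- stats::rnorm(14, 0.8)
  exact <- wilcoxon_signed_rank(x, y, exact_max = 15)$p_value
  approx <- wilcoxon_signed_rank(x, y, exact_max = 5)$p_value
  expect_equal(approx, exact, tolerance = 0.05)
})

test_that("spearman rho matches the rank-definition oracle to 1e-12", {
  set.seed(25)
  for (rep in 1:10) {
    x <- stats::rnorm(10); y <- stats::rnorm(10)
    rho_oracle <- stats::cor(rank(x), rank(y))   # definition: Pearson on ranks
    expect_equal(spearman_rho(x, y)$statistic, rho_oracle, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y)$statistic,
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("spearman endpoints and invariances", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$statistic, 1)
  expect_equal(spearman_rho(1:5, 5:1)$statistic, -1)
  set.seed(26)
  x <- stats::rnorm(9); y <- stats::rnorm(9)
  r0 <- spearman_rho(x, y)
  r1 <- spearman_rho(exp(x), y)          # strictly monotone transform
  expect_equal(r1$statistic, r0$statistic)
  expect_equal(r1$p_value, r0$p_value)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("exact spearman permutation p agrees with cor.test", {
  set.seed(27)
  x <- stats::rnorm(7); y <- stats::rnorm(7)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(spearman_rho(x, y)$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("paired sample size follows the noncentral-t power function", {
  expect_equal(paired_sample_size(2.0, 0.05, 0.8), 5)
  expect_equal(paired_sample_size(0.5, 0.05, 1e-6), 2)   # power -> 0+
  ## cross-check against the base power calculator at several effects
  for (dz in c(0.3, 0.55, 0.8, 1.2)) {
    ref <- ceiling(stats::power.t.test(delta = dz, sd = 1, power = 0.8,
                                       sig.level = 0.05,
                                       type = "paired")$n)
    expect_equal(paired_sample_size(dz, 0.05, 0.8), ref)
  }
  expect_error(paired_sample_size(-1), "invalid")
})
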