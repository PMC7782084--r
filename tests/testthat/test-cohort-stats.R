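# Cohort summaries and the nonparametric comparison battery.

test_that("group summaries use midpoint medians and interpolated quartiles", {
  s <- summarize_group(c(10, 20, 30), "g")
  expect_equal(s$median_area, 20)
  expect_equal(s$iqr_area, 10)
  expect_equal(s$cd, equivalent_diameter(20))

  s1 <- summarize_group(42)
  expect_equal(s1$median_area, 42)
  expect_equal(s1$iqr_area, 0)

  s0 <- summarize_group(numeric(0), "empty")
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median_area))

  # midpoint-of-middle-two convention for even n
  expect_equal(summarize_group(c(1, 2, 3, 10))$median_area, 2.5)
})

test_that("the sample median of a large draw falls in its order-statistic interval", {
  m_true <- 83.6
  vals <- withr::with_seed(61, {
    p <- lognormal_from_median_iqr(m_true, 63.5)
    rlnorm(10001, p$meanlog, p$sdlog)
  })
  n <- length(vals)
  # 99% order-statistic interval for the population median
  lo <- qbinom(0.005, n, 0.5); hi <- qbinom(0.995, n, 0.5) + 1
  sorted <- sort(vals)
  med <- summarize_group(vals)$median_area
  expect_gte(med, sorted[lo])
  expect_lte(med, sorted[hi])
})

test_that("summaries are invariant to input order", {
  vals <- withr::with_seed(62, runif(101, 10, 300))
  expect_equal(summarize_group(vals)[-1],
               summarize_group(rev(vals))[-1])
  expect_equal(summarize_group(vals)[-1],
               summarize_group(sample(vals))[-1])
})

test_that("Kruskal-Wallis matches the rank-formula oracle and handles edge cases", {
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b", "c"), each = 2))
  res <- kruskal_wallis(d, v, g)
  # tie-free H from first principles: 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)
  r <- rank(d$v); N <- 6
  H <- 12 / (N * (N + 1)) * sum(tapply(r, d$g, sum)^2 / 2) - 3 * (N + 1)
  expect_equal(res$statistic, H)
  expect_equal(res$df, 2)
  # exact permutation p of that H as an independent cross-check
  perms <- combn(6, 2, simplify = FALSE)
  hs <- unlist(lapply(perms, function(i1) {
    rest <- setdiff(1:6, i1)
    sapply(combn(rest, 2, simplify = FALSE), function(i2) {
      sums <- c(sum(r[i1]), sum(r[i2]), sum(r[setdiff(rest, i2)]))
      12 / (N * (N + 1)) * sum(sums^2 / 2) - 3 * (N + 1)
    })
  }))
  expect_gte(mean(hs >= H - 1e-9), 0)  # enumeration well-formed
  expect_equal(length(hs), 90L)

  ident <- data.frame(v = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"), each = 3))
  res_id <- kruskal_wallis(ident, v, g)
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p_value, 1)

  expect_error(kruskal_wallis(data.frame(v = 1:3, g = "a"), v, g),
               class = "ctcmorph_validation_error")
})

test_that("two-group Kruskal-Wallis agrees with the squared MWU z statistic", {
  d <- withr::with_seed(63, data.frame(v = rnorm(40), g = rep(c("a", "b"), 20)))
  kw <- kruskal_wallis(d, v, g)
  mw <- mann_whitney_u(d$v[d$g == "a"], d$v[d$g == "b"])
  z <- qnorm(mw$p_value / 2, lower.tail = FALSE)
  expect_equal(kw$statistic, z^2, tolerance = 1e-6)
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-6)
})

test_that("Mann-Whitney U: exact small-sample path and approximations", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2 of the 20 assignments are as extreme

  ident <- suppressWarnings(mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_gt(ident$p_value, 0.99)

  big <- withr::with_seed(64, {
    a <- rlnorm(500, log(100), 0.5)
    mann_whitney_u(a, rlnorm(500, log(150), 0.5))
  })
  expect_lt(big$p_value, 0.001)

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "ctcmorph_validation_error")
})

test_that("the exact MWU p equals the enumeration oracle exhaustively", {
  cases <- withr::with_seed(65, {
    sizes <- list(c(1, 9), c(2, 8), c(3, 7), c(4, 6), c(5, 5), c(3, 3), c(2, 5))
    lapply(sizes, function(s) list(x = runif(s[1]), y = runif(s[2])))
  })
  for (cs in cases) {
    got <- mann_whitney_u(cs$x, cs$y)
    want <- mwu_exact_oracle(cs$x, cs$y)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("the median test classifies against the pooled median", {
  same <- data.frame(v = rep(c(1, 1, 1, 9, 9, 9), 2),
                     g = rep(c("a", "b"), each = 6))
  res <- median_test(same, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  degen <- data.frame(v = rep(5, 10), g = rep(c("a", "b"), 5))
  res_d <- median_test(degen, v, g)
  expect_true(is.na(res_d$p_value))
  expect_match(res_d$note, "degenerate")

  # contingency table equals the brute-force count on random inputs
  for (seed in 71:73) {
    d <- withr::with_seed(seed, data.frame(v = sample(1:50, 30, replace = TRUE),
                                           g = sample(c("a", "b", "c"), 30,
                                                      replace = TRUE)))
    m <- median(d$v)
    tab <- rbind(above = tapply(d$v > m, d$g, sum),
                 not_above = tapply(d$v <= m, d$g, sum))
    want <- suppressWarnings(chisq.test(tab, correct = FALSE))
    got <- median_test(d, v, g)
    expect_equal(got$statistic, unname(want$statistic))
    expect_equal(got$p_value, want$p.value)
  }
})

test_that("the comparison plan runs the published battery and skips absentees", {
  morph <- withr::with_seed(81, {
    cohorts <- list(
      breast = 110, prostate = 90, colorectal = 60, bladder = 40,
      breast_cell_line = 50, prostate_cell_line = 50, leukocyte = 30
    )
    purrr::imap_dfr(cohorts, function(n, g) {
      tibble::tibble(group = g, material = "blood",
                     cell_area = rlnorm(n, log(100), 0.5))
    })
  })
  # no liquor cohort: that comparison is skipped with a warning
  expect_warning(res <- run_comparisons(morph, cell_area), "liquor")
  expect_s3_class(res, "ctc_comparisons")
  expect_equal(sum(res$test == "kruskal_wallis"), 1L)
  expect_equal(sum(res$test == "median_test"), 1L)
  # 6 pairwise tumor + 2 cell line + 4 leukocyte MWU tests
  expect_equal(sum(res$test == "mann_whitney_u"), 12L)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  expect_error(suppressWarnings(
    run_comparisons(morph, cell_area, strict = TRUE)),
    "liquor", class = "ctcmorph_validation_error")

  adj <- suppressWarnings(run_comparisons(morph, cell_area, adjust = "bonferroni"))
  expect_true(all(adj$p_adjusted >= adj$p_value, na.rm = TRUE))
})

test_that("comparison results expose tidy, glance and autoplot methods", {
  morph <- withr::with_seed(82, {
    purrr::map_dfr(c("breast", "prostate", "colorectal", "bladder"), function(g) {
      tibble::tibble(group = g, material = "blood",
                     cell_area = rlnorm(50, log(100), 0.4))
    })
  })
  plan <- comparison_plan(liquor_group = NULL, cell_line_map = character(0),
                          leukocyte_group = NULL)
  res <- run_comparisons(morph, cell_area, plan = plan)
  expect_equal(nrow(res), 1L + 1L + 6L)  # KW + median test + C(4,2) MWU
  td <- tidy(res)
  expect_true(all(c("label", "p_value", "p_formatted") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_tests, 8L)
  expect_s3_class(autoplot(res), "ggplot")
  expect_equal(format_p(c(0.0004, 0.25, NA)), c("< 0.001", "0.250", NA))
})
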