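test_that("median and IQR follow the fixed interpolation convention", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(c(s$q1, s$q3), c(2, 4))
  s1 <- median_iqr(7)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(7, 7, 7))
  expect_error(median_iqr(numeric(0)), class = "cristamorph_argument_error")
  # snapshot of the quartile convention: changing it must break this
  s2 <- median_iqr(c(1, 2, 3, 4))
  expect_identical(s2$quartile_method, "linear interpolation (type 7)")
  expect_equal(c(s2$q1, s2$q3), c(1.75, 3.25))
})

test_that("complete separation at n = 3 vs 3 gives exact two-sided p = 0.1", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, exact_mw_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("Mann-Whitney p agrees with full enumeration for all small
          group sizes", {
  set.seed(314)
  for (n1 in 3:8) {
    for (n2 in 3:8) {
      a <- round(rlnorm(n1, 0, 0.6), 6)
      b <- round(rlnorm(n2, 0.4, 0.6), 6)
      if (anyDuplicated(c(a, b))) next
      r <- compare_groups(a, b)
      expect_true(r$exact)
      expect_equal(r$p_value, exact_mw_p(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("identical or degenerate samples are not called significant", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- compare_groups(x, x)
  expect_false(r$significant)
  d <- compare_groups(rep(2, 5), rep(2, 6))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("null simulations reject at close to the nominal level", {
  set.seed(2024)
  rejections <- 0L
  nrep <- 400
  for (i in seq_len(nrep)) {
    a <- rlnorm(14, 0, 0.4)
    b <- rlnorm(14, 0, 0.4)
    if (compare_groups(a, b)$significant) rejections <- rejections + 1L
  }
  expect_gt(rejections / nrep, 0.02)
  expect_lt(rejections / nrep, 0.08)
})

test_that("normality gate selects Pearson or Spearman appropriately", {
  set.seed(77)
  x <- rnorm(60)
  y <- 2 * x + 1
  r <- correlate(x, y)
  expect_identical(r$test, "pearson")
  expect_equal(r$statistic, 1.0)
  # strictly decreasing transform of a skewed variable: Spearman -1
  xs <- rlnorm(60, 0, 1.5)
  r2 <- correlate(xs, exp(-xs))
  expect_identical(r2$test, "spearman")
  expect_equal(r2$statistic, -1.0)
  expect_error(correlate(rep(1, 5), 1:5),
               class = "cristamorph_degenerate_error")
})

test_that("correlation estimates recover a known bivariate dependence", {
  set.seed(99)
  rs <- vapply(1:40, function(i) {
    x <- rnorm(50)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(50)
    correlate(x, y)$statistic
  }, numeric(1))
  expect_equal(mean(rs), 0.8, tolerance = 0.05)
})

test_that("percent difference matches the published worked examples", {
  expect_equal(percent_difference(0.0408, 0.0227), 79.7, tolerance = 0.05)
  expect_equal(percent_difference(565.7, 461.1), 22.7, tolerance = 0.05)
  expect_equal(percent_difference(0.233, 0.191), 22, tolerance = 0.5)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), class = "cristamorph_argument_error")
  # ratio identity: a/b = 1 + pct/100
  for (pair in list(c(0.0408, 0.0227), c(598.5, 370.8), c(3, 7))) {
    expect_equal(pair[1] / pair[2],
                 1 + percent_difference(pair[1], pair[2]) / 100)
  }
})

test_that("animal pooling check flags between-animal differences", {
  set.seed(8)
  same <- pool_animals(c(rnorm(10), rnorm(10)), rep(c("m1", "m2"), each = 10))
  expect_true(same$pooled)
  expect_warning(
    diff <- pool_animals(c(rnorm(10), rnorm(10, 8)),
                         rep(c("m1", "m2"), each = 10)),
    class = "cristamorph_pooling_warning")
  expect_false(diff$pooled)
})

test_that("cohort reports summarize metrics per group with comparisons", {
  ps <- population_spec(ca1_reference_targets(), seed = 5)
  cohort <- generate_population(ps)
  rep_ <- build_report(cohort, comparison = "PV")
  expect_s3_class(rep_, "cohort_report")
  expect_true(all(c("cm_density", "csf", "slp_density") %in%
                  rep_$panels$metric))
  expect_identical(unique(rep_$panels$group_a), "PV")
  expect_true(all(rep_$panels$p_value >= 0 & rep_$panels$p_value <= 1))
  # empty cohort: empty report with a warning recorded
  empty <- build_report(data.frame())
  expect_identical(nrow(empty$panels), 0L)
  expect_gt(length(empty$warnings), 0)
  # report writing round-trips through JSON
  jp <- tempfile(fileext = ".json")
  tp <- tempfile(fileext = ".txt")
  write_report(rep_, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$panels$percent_difference,
               rep_$panels$percent_difference, tolerance = 1e-9)
  expect_true(file.size(tp) > 0)
  unlink(c(jp, tp))
})
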