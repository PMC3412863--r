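test_that("per-sample counts deduplicate within samples", {
  iv <- make_intervals(c("S1", "S1", "S1", "S2"), "8",
                       c(100, 100, 300, 100), c(200, 200, 400, 200),
                       c("gain", "gain", "loss", "gain"))
  counts <- per_sample_counts(iv)
  expect_equal(counts, c(S1 = 2L, S2 = 1L))
  expect_equal(per_sample_counts(iv, c("S1", "S2", "S3")),
               c(S1 = 2L, S2 = 1L, S3 = 0L))

  coh <- generate_cohort(cohort_config(seed = 23))
  expect_equal(per_sample_counts(coh$intervals, coh$metadata$sample_id),
               coh$truth$per_sample_counts)
})

test_that("cohort totals split by sex and MSI with truncated display", {
  counts <- c(a = 10, b = 20, c = 31)
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     sex = factor(c("M", "M", "F"), levels = c("M", "F")),
                     msi = factor(c("MSS", "MSI-H", "MSS"),
                                  levels = c("MSS", "MSI-L", "MSI-H")))
  tot <- cohort_totals(counts, meta)
  expect_equal(tot$total, 61)
  expect_equal(tot$mean, trunc_dec(61 / 3, 2))
  # male + female totals add to the grand total
  expect_equal(sum(tot$by_sex$total), tot$total)
  expect_equal(sum(tot$by_msi_h$total), tot$total)
  expect_error(cohort_totals(counts[1:2], meta), "mismatch")
})

test_that("per-chromosome table satisfies its row invariants", {
  coh <- generate_cohort(cohort_config(seed = 25))
  tab <- per_chromosome_table(coh$intervals, coh$metadata)
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$total, tab$amplifications + tab$deletions)
  expect_equal(tab$amp_male + tab$amp_female, tab$amplifications)
  expect_equal(tab$del_male + tab$del_female, tab$deletions)
  expect_equal(sum(tab$total), sum(coh$truth$per_sample_counts))

  # single gain on chromosome 8 in a male
  iv <- make_intervals("a", "8", 100, 200, "gain")
  meta <- data.frame(sample_id = "a", sex = factor("M", c("M", "F")))
  tab1 <- per_chromosome_table(iv, meta)
  r8 <- tab1[tab1$chromosome == "8", ]
  expect_equal(unlist(r8[, -1], use.names = FALSE),
               c(1L, 1L, 0L, 1L, 0L, 0L, 0L))
  expect_true(all(tab1$total[tab1$chromosome != "8"] == 0))
  # empty interval table -> all-zero rows
  tab0 <- per_chromosome_table(iv[0, ], meta)
  expect_true(all(tab0$total == 0))
})

test_that("planted male-only X gains land in the male amplification cell", {
  cfg <- cohort_config(mean_aberrations_cin = 0, mean_aberrations_msih = 0,
                       n_signature_aberrations_msih = 0,
                       msi_h_fraction = 0, msi_l_fraction = 0,
                       male_x_gain_prob = 1, female_x_gain_prob = 0,
                       seed = 26)
  coh <- generate_cohort(cfg)
  tab <- per_chromosome_table(coh$intervals, coh$metadata)
  xrow <- tab[tab$chromosome == "X", ]
  expect_equal(xrow$amp_male, sum(coh$metadata$sex == "M"))
  expect_equal(xrow$amp_female, 0L)
})

test_that("median_iqr follows the (n+1)p weighted-average convention", {
  q <- median_iqr(c(51, 69, 53, 60))
  expect_equal(q$median, 56.5)
  expect_equal(q$q25, 51.5)
  expect_equal(trunc_dec(q$q75, 1), 66.7)
  q <- median_iqr(c(66, 54, 83, 68, 64))
  expect_equal(q$median, 66)
  expect_equal(q$q25, 59)
  expect_equal(q$q75, 75.5)
  expect_equal(median_iqr(7), list(median = 7, q25 = 7, q75 = 7))
  expect_error(median_iqr(numeric(0)), "non-empty")
})

test_that("quantiles agree with the order-statistic oracle and permutation", {
  set.seed(41)
  for (rep in 1:20) {
    x <- stats::runif(sample(1:40, 1), 0, 100)
    q <- median_iqr(x)
    expect_equal(q$median, oracle_quantile6(x, 0.5))
    expect_equal(q$q25, oracle_quantile6(x, 0.25))
    expect_equal(q$q75, oracle_quantile6(x, 0.75))
    expect_equal(median_iqr(sample(x)), q)
  }
})

test_that("association tests dispatch to the three classical tests", {
  # two groups with identical values -> degenerate p = 1
  x <- c(5, 5, 5, 5)
  g <- factor(c("a", "a", "b", "b"))
  cmp <- association_tests(x, g)
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)

  # 2x2 table (10,0; 0,10): chi-square statistic 20, p < 0.001
  xf <- factor(rep(c("yes", "no"), each = 10))
  gf <- factor(rep(c("a", "b"), each = 10))
  cmp <- association_tests(xf, gf)
  expect_equal(unname(cmp$statistic), 20)
  expect_lt(cmp$p_value, 0.001)
  # matches the textbook sum over cells of (O-E)^2/E
  O <- table(xf, gf)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(unname(cmp$statistic), sum((O - E)^2 / E))

  # >2 groups -> one-way ANOVA, equal to the stats::aov p-value
  set.seed(43)
  x <- stats::rnorm(30)
  g <- factor(rep(letters[1:3], each = 10))
  cmp <- association_tests(x, g)
  expect_match(cmp$test, "ANOVA")
  expect_equal(cmp$p_value,
               summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1])

  # 2 groups numeric -> Student t with equal variances
  g2 <- factor(rep(c("a", "b"), 15))
  cmp2 <- association_tests(x, g2)
  expect_equal(cmp2$p_value,
               stats::t.test(x ~ g2, var.equal = TRUE)$p.value)
  expect_gt(association_tests(x, g2, welch = TRUE)$p_value, 0)

  expect_error(association_tests(x, factor(rep("a", 30),
                                           levels = c("a", "b"))),
               "size 0")
})

test_that("the cohort association table runs the reference comparisons", {
  meta <- fixture_metadata()
  counts <- stats::setNames(meta$n_aberrations, meta$sample_id)
  tabs <- cohort_association_table(counts, meta)
  expect_setequal(names(tabs), c("sex", "location", "stage", "msi"))
  # aberration burden is not significantly associated with any variable
  for (cmp in tabs) expect_gt(cmp$p_value, 0.05)
  # MSI-H group mean prints as 19.0
  msi_groups <- tabs$msi$groups
  expect_equal(trunc_dec(msi_groups$mean[msi_groups$group == "MSI-H"], 1),
               19.0)
})
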