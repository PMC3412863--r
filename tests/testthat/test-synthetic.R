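test_that("cohort configuration validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(msi_h_fraction = 1.2), "proportions")
  expect_error(cohort_config(mean_aberrations_cin = 5,
                             mean_aberrations_msih = 10), "fewer")
  expect_error(cohort_config(gain_fold_range = c(1.1, 2)), "1.2")
  expect_error(cohort_config(loss_fold_range = c(0.3, 0.9)), "0.8")
})

test_that("generation is deterministic for a fixed config", {
  cfg <- cohort_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a$intervals, c$intervals))
})

test_that("the defaults produce the intended cohort structure", {
  coh <- generate_cohort(cohort_config(seed = 2))
  meta <- coh$metadata
  expect_equal(nrow(meta), 30L)
  expect_equal(sum(meta$msi == "MSI-H"), 5L)
  expect_equal(sum(meta$msi == "MSI-L"), 4L)
  # MSI-H tumors are right-sided by construction
  expect_true(all(meta$location[meta$msi == "MSI-H"] == "R"))
  # metadata n_aberrations mirrors the planted truth
  expect_equal(meta$n_aberrations,
               unname(coh$truth$per_sample_counts))
  # every MSI-H sample carries every signature aberration, nobody else does
  sig <- coh$truth$signature_keys
  expect_equal(nrow(sig), 5L)
  tag <- function(df) paste(df$chromosome, df$start, df$end, df$direction)
  for (i in seq_len(nrow(sig))) {
    carriers <- unique(coh$intervals$sample_id[
      tag(coh$intervals) == tag(sig[i, ])])
    expect_setequal(carriers, coh$truth$msi_h_sample_ids)
  }
})

test_that("all planted fold changes respect the threshold ranges", {
  coh <- generate_cohort(cohort_config(seed = 14))
  iv <- coh$intervals
  expect_true(all(iv$fold_change[iv$direction == "gain"] > 1.2))
  expect_true(all(iv$fold_change[iv$direction == "loss"] < 0.8))
  expect_true(all(iv$start < iv$end))
  expect_true(all(iv$chromosome %in% c(as.character(1:22), "X", "Y")))
})

test_that("realized group means converge to the configured Poisson means", {
  cfg <- cohort_config(n_samples = 500, mean_aberrations_cin = 27,
                       mean_aberrations_msih = 10,
                       n_signature_aberrations_msih = 0,
                       male_x_gain_prob = 0, female_x_gain_prob = 0,
                       seed = 77)
  coh <- generate_cohort(cfg)
  counts <- coh$truth$per_sample_counts
  h <- coh$metadata$msi == "MSI-H"
  for (grp in list(list(sel = h, mean = 10), list(sel = !h, mean = 27))) {
    m <- mean(counts[grp$sel])
    se <- sqrt(grp$mean / sum(grp$sel))
    expect_lt(abs(m - grp$mean), 3 * se)
  }
})

test_that("male X-gain frequency converges to its configured probability", {
  cfg <- cohort_config(n_samples = 500, mean_aberrations_cin = 0,
                       mean_aberrations_msih = 0,
                       n_signature_aberrations_msih = 0,
                       male_x_gain_prob = 0.6, female_x_gain_prob = 0.1,
                       seed = 78)
  coh <- generate_cohort(cfg)
  males <- coh$metadata$sample_id[coh$metadata$sex == "M"]
  x_gain <- unique(coh$intervals$sample_id[
    coh$intervals$chromosome == "X" & coh$intervals$direction == "gain"])
  frac <- mean(males %in% x_gain)
  se <- sqrt(0.6 * 0.4 / length(males))
  expect_lt(abs(frac - 0.6), 3 * se)
  expect_setequal(coh$truth$x_gain_carriers, x_gain)
})

test_that("a zero-rate configuration yields an empty interval list", {
  cfg <- cohort_config(n_samples = 2, mean_aberrations_cin = 0,
                       mean_aberrations_msih = 0,
                       n_signature_aberrations_msih = 0,
                       msi_h_fraction = 0, msi_l_fraction = 0,
                       male_x_gain_prob = 0, female_x_gain_prob = 0,
                       seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$intervals), 0L)
  expect_equal(nrow(coh$metadata), 2L)
})

test_that("written cohorts read back losslessly", {
  coh <- generate_cohort(cohort_config(seed = 33))
  dir <- file.path(tempdir(), "cohort-rt")
  write_cohort(coh, dir)
  expect_setequal(list.files(dir),
                  c("metadata.csv", "intervals.tsv", "genes.bed"))

  meta <- read_sample_metadata(file.path(dir, "metadata.csv"))
  expect_equal(meta, coh$metadata)
  genes <- read_gene_bed(file.path(dir, "genes.bed"))
  expect_equal(genes, coh$genes)
  iv <- read_interval_report(file.path(dir, "intervals.tsv"),
                             convention = "one_based_inclusive")
  expect_equal(iv$start, coh$intervals$start)
  expect_equal(iv$end, coh$intervals$end)
  expect_equal(iv$sample_id, coh$intervals$sample_id)
  expect_equal(iv$fold_change, coh$intervals$fold_change)
  # reclassification reproduces the planted directions
  expect_equal(classify_intervals(iv)$direction, coh$intervals$direction)

  # an empty cohort writes header-only files that still read back
  empty <- generate_cohort(cohort_config(
    n_samples = 2, mean_aberrations_cin = 0, mean_aberrations_msih = 0,
    n_signature_aberrations_msih = 0, msi_h_fraction = 0,
    msi_l_fraction = 0, male_x_gain_prob = 0, female_x_gain_prob = 0,
    seed = 6))
  dir2 <- file.path(tempdir(), "cohort-empty")
  write_cohort(empty, dir2)
  expect_equal(nrow(read_interval_report(file.path(dir2, "intervals.tsv"))),
               0L)
})
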