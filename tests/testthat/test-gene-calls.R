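test_that("fold-change classification uses strict thresholds", {
  expect_equal(classify_interval(c(1.45, 1.0, 1.2, 1.21, 0.8, 0.79)),
               c("gain", "none", "none", "gain", "none", "loss"))
  expect_error(classify_interval(0), "positive")
  expect_error(classify_interval(-1), "positive")
})

test_that("classification is monotone in the fold change", {
  set.seed(11)
  fc <- sort(stats::runif(200, 0.01, 4))
  ord <- factor(classify_interval(fc), levels = c("loss", "none", "gain"))
  expect_true(all(diff(as.integer(ord)) >= 0))
})

test_that("classify_intervals drops the dead zone and honors log2 input", {
  iv <- data.frame(sample_id = "S1", chromosome = "1",
                   start = c(0, 100, 200), end = c(50, 150, 250),
                   fold_change = c(1.5, 1.0, 0.5))
  out <- classify_intervals(iv)
  expect_equal(out$direction, c("gain", "loss"))
  expect_equal(out$start, c(0L, 200L))

  iv$fold_change <- log2(c(1.5, 1.0, 0.5))
  out2 <- classify_intervals(iv, log2_input = TRUE)
  expect_equal(out2$direction, c("gain", "loss"))
})

test_that("gene calls follow half-open overlap semantics", {
  genes <- data.frame(symbol = "G1", chromosome = "8",
                      start = 100L, end = 200L)
  # overlap of 50 bp -> amplified
  iv <- make_intervals("S1", "8", 150, 300, "gain")
  calls <- call_gene_aberrations(iv, genes)
  expect_equal(calls$status, "amplified")
  expect_equal(calls$supporting_interval_count, 1L)
  # half-open abutment is zero overlap -> no call
  iv <- make_intervals("S1", "8", 200, 300, "loss")
  expect_equal(nrow(call_gene_aberrations(iv, genes)), 0L)
  # same coordinates on another chromosome -> no call
  iv <- make_intervals("S1", "9", 150, 300, "gain")
  expect_equal(nrow(call_gene_aberrations(iv, genes)), 0L)
  # unclassified input is a state error
  iv$direction <- NULL
  expect_error(call_gene_aberrations(iv, genes), "classif")
  expect_error(call_gene_aberrations(make_intervals("S1", "8", 1, 2, "gain"),
                                     genes[0, ]), "non-empty")
})

test_that("minimum-overlap and keep_none options behave", {
  genes <- data.frame(symbol = c("G1", "G2"), chromosome = c("8", "9"),
                      start = c(100L, 0L), end = c(200L, 10L))
  iv <- make_intervals("S1", "8", 150, 300, "gain")   # 50 bp overlap
  expect_equal(nrow(call_gene_aberrations(iv, genes, min_overlap_bp = 50)),
               1L)
  expect_equal(nrow(call_gene_aberrations(iv, genes, min_overlap_bp = 51)),
               0L)
  full <- call_gene_aberrations(iv, genes, keep_none = TRUE)
  expect_equal(nrow(full), 2L)
  expect_equal(full$status[full$symbol == "G2"], "none")
  expect_true(all((full$status == "none") ==
                    (full$supporting_interval_count == 0)))
})

test_that("a gain/loss conflict on one gene yields both calls and a warning", {
  genes <- data.frame(symbol = "G1", chromosome = "8",
                      start = 100L, end = 200L)
  iv <- make_intervals(c("S1", "S1"), "8", c(50, 120), c(150, 260),
                       c("gain", "loss"))
  expect_warning(calls <- call_gene_aberrations(iv, genes), "same gene")
  expect_setequal(calls$status, c("amplified", "deleted"))
  freq <- gene_frequency_table(calls, n_samples = 30)
  expect_equal(freq$amplified_count, 1L)
  expect_equal(freq$deleted_count, 1L)
})

test_that("frequency percentages follow the truncation rule", {
  expect_equal(percent_floor(c(16, 14, 11, 8, 20, 19, 12, 10), 30),
               c(53L, 46L, 36L, 26L, 66L, 63L, 40L, 33L))
  calls <- data.frame(
    sample_id = paste0("S", 1:16), symbol = "SMAD4",
    status = "deleted", supporting_interval_count = 1L)
  freq <- gene_frequency_table(calls, n_samples = 30)
  expect_equal(freq$deleted_percent, 53L)
  expect_equal(freq$amplified_count, 0L)
  expect_equal(gene_frequency_table(calls[0, ], 30)$symbol, character(0))
  expect_error(gene_frequency_table(calls, 0), "positive")
})

test_that("planted gene-spanning deletions are recovered from the generator", {
  coh <- generate_cohort(cohort_config(seed = 9))
  truth <- coh$truth
  expect_false(is.na(truth$signature_gene))
  calls <- suppressWarnings(
    call_gene_aberrations(coh$intervals, coh$genes))
  hit <- calls[calls$symbol == truth$signature_gene &
                 calls$status == "deleted", ]
  # every MSI-H sample carries the planted deletion over the planted gene
  expect_true(all(truth$msi_h_sample_ids %in% hit$sample_id))

  # background-free cohort: the deleted count equals the MSI-H count exactly
  cfg <- cohort_config(mean_aberrations_cin = 0, mean_aberrations_msih = 0,
                       male_x_gain_prob = 0, female_x_gain_prob = 0,
                       seed = 10)
  coh0 <- generate_cohort(cfg)
  calls0 <- call_gene_aberrations(coh0$intervals, coh0$genes)
  freq <- gene_frequency_table(calls0, n_samples = 30, genes = coh0$genes)
  expect_equal(freq$deleted_count[freq$symbol == coh0$truth$signature_gene],
               length(coh0$truth$msi_h_sample_ids))
  # no calls on chromosomes that carry no intervals
  touched <- unique(coh0$intervals$chromosome)
  called <- unique(calls0$symbol)
  gene_chrom <- coh0$genes$chromosome[match(called, coh0$genes$symbol)]
  expect_true(all(gene_chrom %in% touched))
})
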