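# Cohort summary statistics: per-sample and per-chromosome aberration
# counts, and group comparisons by the clinical variables.

#' Count distinct aberrations per sample
#'
#' One aberration = one deduplicated classified interval: identical
#' (chromosome, start, end, direction) calls within a sample count once.
#'
#' @param intervals classified intervals (see [classify_intervals()]).
#' @param sample_ids optional character vector fixing the output names and
#'   order; samples without intervals get 0.
#' @return named integer vector of per-sample counts.
#' @export
per_sample_counts <- function(intervals, sample_ids = NULL) {
  .check_classified(intervals)
  dedup <- unique(intervals[, c("sample_id", "chromosome", "start", "end",
                                "direction")])
  if (is.null(sample_ids)) sample_ids <- sort(unique(dedup$sample_id))
  counts <- table(factor(dedup$sample_id, levels = sample_ids))
  stats::setNames(as.integer(counts), sample_ids)
}

#' Cohort aberration totals and group splits
#'
#' Sums and averages the per-sample aberration counts for the whole cohort
#' and split by sex and by MSI-H versus non-MSI-H. Display means follow the
#' truncation convention ([trunc_dec()]): the overall mean keeps 2 decimals,
#' group means 1 (a cohort totalling 764 aberrations over 30 samples prints
#' a mean of 25.46); exact values are returned alongside.
#'
#' @param counts named numeric vector of per-sample aberration counts (e.g.
#'   from [per_sample_counts()] or a metadata `n_aberrations` column).
#' @param metadata clinical metadata whose `sample_id` set must equal
#'   `names(counts)`.
#' @return object of class `cohort_totals`: list with `n`, `total`, `mean`
#'   (truncated, 2 dp), `mean_exact`, `min`, `max`, `by_sex` and `by_msi_h`
#'   data.frames (columns `group`, `n`, `total`, `mean` truncated to 1 dp,
#'   `mean_exact`, `sd`).
#' @export
cohort_totals <- function(counts, metadata) {
  if (!setequal(names(counts), metadata$sample_id))
    stop("metadata/count key mismatch: counts must cover exactly the ",
         "metadata samples")
  x <- as.numeric(counts[match(metadata$sample_id, names(counts))])

  split_stats <- function(groups) {
    do.call(rbind, lapply(split(x, groups), function(v)
      data.frame(n = length(v), total = sum(v),
                 mean = trunc_dec(mean(v), 1), mean_exact = mean(v),
                 sd = stats::sd(v))))
  }
  by_sex <- split_stats(metadata$sex)
  by_sex <- data.frame(group = rownames(by_sex), by_sex, row.names = NULL)
  msi_h <- factor(ifelse(metadata$msi == "MSI-H", "MSI-H", "non-MSI-H"),
                  levels = c("non-MSI-H", "MSI-H"))
  by_msi <- split_stats(msi_h)
  by_msi <- data.frame(group = rownames(by_msi), by_msi, row.names = NULL)

  structure(list(n = length(x), total = sum(x),
                 mean = trunc_dec(mean(x), 2), mean_exact = mean(x),
                 min = min(x), max = max(x),
                 by_sex = by_sex, by_msi_h = by_msi),
            class = "cohort_totals")
}

#' @export
print.cohort_totals <- function(x, ...) {
  cat(sprintf("Cohort of %d samples: %d aberrations (mean %.2f, range %d-%d)\n",
              x$n, as.integer(x$total), x$mean, as.integer(x$min),
              as.integer(x$max)))
  cat("By sex:\n"); print(x$by_sex, row.names = FALSE)
  cat("By MSI-H status:\n"); print(x$by_msi_h, row.names = FALSE)
  invisible(x)
}

#' Per-chromosome aberration counts split by direction and sex
#'
#' One row per chromosome (1-22, X, Y) with the total number of
#' (within-sample deduplicated) aberrations, the split into amplifications
#' and deletions, and the further split of each by patient sex. Row
#' invariants hold by construction: total = amplifications + deletions, and
#' the male/female cells of each direction sum to its total.
#'
#' @param intervals classified intervals.
#' @param metadata clinical metadata providing `sex` for every sample that
#'   appears in `intervals`.
#' @return data.frame with columns `chromosome`, `total`, `amplifications`,
#'   `deletions`, `amp_male`, `amp_female`, `del_male`, `del_female`.
#' @export
per_chromosome_table <- function(intervals, metadata) {
  .check_classified(intervals)
  dedup <- unique(intervals[, c("sample_id", "chromosome", "start", "end",
                                "direction")])
  miss <- setdiff(unique(dedup$sample_id), metadata$sample_id)
  if (length(miss) > 0)
    stop("no metadata (sex) for sample(s): ", paste(miss, collapse = ", "))
  if (nrow(dedup) > 0 && !all(dedup$chromosome %in% CHROM_LABELS))
    stop("unknown chromosome label(s): ",
         paste(setdiff(unique(dedup$chromosome), CHROM_LABELS),
               collapse = ", "))
  sex <- metadata$sex[match(dedup$sample_id, metadata$sample_id)]
  chrom <- factor(dedup$chromosome, levels = CHROM_LABELS)
  cnt <- function(cond) as.integer(table(chrom[cond]))
  gain <- dedup$direction == "gain"
  loss <- dedup$direction == "loss"
  male <- sex == "M"
  data.frame(chromosome = CHROM_LABELS,
             total = as.integer(table(chrom)),
             amplifications = cnt(gain),
             deletions = cnt(loss),
             amp_male = cnt(gain & male),
             amp_female = cnt(gain & !male),
             del_male = cnt(loss & male),
             del_female = cnt(loss & !male),
             stringsAsFactors = FALSE)
}

#' Median and interquartile range, weighted-average convention
#'
#' Quantiles at the weighted average of order statistics around position
#' (n+1)p (`stats::quantile` type 6) — the convention under which ages
#' {51, 69, 53, 60} give a median of 56.5 with quartiles 51.5 and 66.75.
#' The common linear-interpolation default (type 7) would give 52.5 for the
#' lower quartile and is not used here.
#'
#' @param values non-empty numeric vector.
#' @return list with `median`, `q25`, `q75`.
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop("values must be non-empty and free of NA")
  q <- unname(stats::quantile(values, c(0.5, 0.25, 0.75), type = 6))
  list(median = q[1], q25 = q[2], q75 = q[3])
}

#' Compare an outcome between clinical groups
#'
#' The three classical tests used for cohort tables: a numeric outcome
#' against 2 groups uses the equal-variance two-sample Student t-test
#' (`welch = TRUE` switches to Welch); against more than 2 groups, one-way
#' ANOVA; a categorical outcome uses the Pearson chi-square test without
#' continuity correction. No multiple-testing correction is applied.
#' Zero within-group variance everywhere is reported as a degenerate case
#' (p = 1 when the group means are also identical).
#'
#' @param x numeric outcome (e.g. aberration counts) or a factor
#'   (categorical outcome).
#' @param group grouping factor; every level must be non-empty.
#' @param welch use the Welch t-test instead of the equal-variance Student
#'   t-test for 2-group numeric comparisons.
#' @return object of class `group_comparison`: list with `groups` (per-group
#'   n/mean/sd/median/q25/q75 for numeric outcomes, or the contingency
#'   table), `test`, `statistic`, `p_value` (full precision), `p_display`
#'   (truncated to 1 decimal), `degenerate`.
#' @export
association_tests <- function(x, group, welch = FALSE) {
  if (!is.factor(group)) group <- factor(group)
  tab <- table(group)
  if (any(tab == 0))
    stop("group(s) of size 0: ",
         paste(names(tab)[tab == 0], collapse = ", "))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  degenerate <- FALSE

  if (is.numeric(x)) {
    groups <- do.call(rbind, lapply(levels(group), function(g) {
      v <- x[group == g]
      q <- median_iqr(v)
      data.frame(group = g, n = length(v), mean = mean(v),
                 sd = stats::sd(v), median = q$median, q25 = q$q25,
                 q75 = q$q75, stringsAsFactors = FALSE)
    }))
    vars <- tapply(x, group, stats::var)
    if (all(vars == 0 | is.na(vars))) {
      degenerate <- TRUE
      means <- tapply(x, group, mean)
      p <- if (length(unique(means)) == 1) 1 else 0
      statistic <- NA_real_
      test <- if (nlevels(group) == 2) "t-test (degenerate)"
              else "one-way ANOVA (degenerate)"
    } else if (nlevels(group) == 2) {
      ht <- stats::t.test(x ~ group, var.equal = !welch)
      p <- ht$p.value
      statistic <- unname(ht$statistic)
      test <- if (welch) "Welch t-test" else "Student t-test (equal variance)"
    } else {
      fit <- stats::aov(x ~ group)
      s <- summary(fit)[[1]]
      p <- s[["Pr(>F)"]][1]
      statistic <- s[["F value"]][1]
      test <- "one-way ANOVA"
    }
  } else {
    ct <- table(x, group)
    ht <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
    groups <- ct
    p <- ht$p.value
    statistic <- unname(ht$statistic)
    test <- "Pearson chi-square (no continuity correction)"
    if (is.na(statistic) || any(dim(ct) < 2)) degenerate <- TRUE
  }

  structure(list(groups = groups, test = test, statistic = statistic,
                 p_value = p, p_display = trunc_dec(p, 1),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, "\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("p = %.4g (displayed %.1f)%s\n", x$p_value, x$p_display,
              if (x$degenerate) " [degenerate case]" else ""))
  invisible(x)
}

#' Cohort-wide association table for aberration counts
#'
#' Convenience wrapper building the standard "number of aberrations versus
#' clinical variables" table: one comparison per variable (sex, location,
#' stage, MSI-H versus non-MSI-H), each via [association_tests()].
#'
#' @param counts named per-sample aberration counts.
#' @param metadata clinical metadata covering the same samples.
#' @return named list of `group_comparison` objects
#'   (`sex`, `location`, `stage`, `msi`).
#' @export
cohort_association_table <- function(counts, metadata) {
  x <- as.numeric(counts[match(metadata$sample_id, names(counts))])
  if (anyNA(x)) stop("metadata/count key mismatch")
  msi_h <- factor(ifelse(metadata$msi == "MSI-H", "MSI-H", "non-MSI-H"))
  list(sex = association_tests(x, metadata$sex),
       location = association_tests(x, metadata$location),
       stage = association_tests(x, droplevels(metadata$stage)),
       msi = association_tests(x, msi_h))
}
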