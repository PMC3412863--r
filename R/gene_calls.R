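# Fold-change classification of segmented intervals and gene-level
# aberration calling by genomic overlap.

#' Classify a fold change as gain, loss or none
#'
#' Applies the standard aCGH magnitude filter: a segment is a copy-number
#' gain when its linear tumor/reference ratio is strictly above the gain
#' threshold (default 1.2) and a loss when strictly below the loss threshold
#' (default 0.8). Values at or between the thresholds are `"none"` — the
#' comparisons are strict, so 1.2 and 0.8 themselves are filtered out.
#'
#' @param fold_change positive numeric vector of linear ratios.
#' @param gain_threshold gains require `fold_change > gain_threshold`.
#' @param loss_threshold losses require `fold_change < loss_threshold`.
#' @return character vector in `c("gain", "loss", "none")`.
#' @examples
#' classify_interval(c(1.45, 1.0, 0.8, 0.79))
#' @export
classify_interval <- function(fold_change, gain_threshold = 1.2,
                              loss_threshold = 0.8) {
  fold_change <- as.numeric(fold_change)
  if (any(is.na(fold_change) | fold_change <= 0))
    stop("fold_change must be positive")
  ifelse(fold_change > gain_threshold, "gain",
         ifelse(fold_change < loss_threshold, "loss", "none"))
}

#' Classify an interval table and drop sub-threshold segments
#'
#' Adds a `direction` column (`"gain"`/`"loss"`) to an interval data.frame
#' via [classify_interval()] and drops rows whose fold change lies in the
#' dead zone between the loss and gain thresholds. Downstream stages (gene
#' calling, the polarity matrix, cohort statistics) operate on classified
#' intervals only.
#'
#' @param intervals data.frame from [read_interval_report()].
#' @param log2_input if `TRUE` the `fold_change` column holds log2 ratios and
#'   is converted via `2^x` before classification.
#' @inheritParams classify_interval
#' @return the classified, filtered data.frame with a `direction` column.
#' @export
classify_intervals <- function(intervals, log2_input = FALSE,
                               gain_threshold = 1.2, loss_threshold = 0.8) {
  if (log2_input) intervals$fold_change <- 2^intervals$fold_change
  if (nrow(intervals) == 0) {
    intervals$direction <- character(0)
    return(intervals)
  }
  status <- classify_interval(intervals$fold_change, gain_threshold,
                              loss_threshold)
  out <- intervals[status != "none", , drop = FALSE]
  out$direction <- status[status != "none"]
  rownames(out) <- NULL
  out
}

.check_classified <- function(intervals) {
  if (!"direction" %in% names(intervals))
    stop("intervals are not classified; run classify_intervals() first")
  if (nrow(intervals) > 0 && !all(intervals$direction %in% c("gain", "loss")))
    stop("intervals contain directions other than gain/loss")
  invisible(TRUE)
}

#' Call per-gene, per-sample aberration status by genomic overlap
#'
#' A gene is called `amplified` (`deleted`) in a sample when at least one of
#' that sample's gain (loss) intervals on the same chromosome overlaps the
#' gene span by at least `min_overlap_bp` bases. Any overlap counts by
#' default (`min_overlap_bp = 1`); half-open abutment is zero overlap. When
#' both a gain and a loss overlap the same gene in one sample (possible with
#' overlapping segments), both calls are recorded and a warning is issued;
#' frequency tables then count the gene in both columns.
#'
#' @param intervals classified intervals (see [classify_intervals()]).
#' @param genes gene annotation data.frame (see [read_gene_bed()]); must be
#'   non-empty.
#' @param min_overlap_bp minimum overlap in base pairs (default 1 = any).
#' @param keep_none also emit explicit rows with status `"none"` and
#'   `supporting_interval_count` 0 for every (sample, gene) pair without a
#'   call.
#' @return data.frame with columns `sample_id`, `symbol`, `status`
#'   (`amplified`/`deleted`/`none`), `supporting_interval_count`.
#' @export
call_gene_aberrations <- function(intervals, genes, min_overlap_bp = 1L,
                                  keep_none = FALSE) {
  .check_classified(intervals)
  if (is.null(genes) || nrow(genes) == 0) stop("genes must be non-empty")
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")

  empty <- data.frame(sample_id = character(0), symbol = character(0),
                      status = character(0),
                      supporting_interval_count = integer(0),
                      stringsAsFactors = FALSE)
  calls <- empty
  if (nrow(intervals) > 0) {
    # internal 0-based half-open -> 1-based closed for GRanges
    gi <- GenomicRanges::GRanges(
      intervals$chromosome,
      IRanges::IRanges(intervals$start + 1L, intervals$end))
    gg <- GenomicRanges::GRanges(
      genes$chromosome, IRanges::IRanges(genes$start + 1L, genes$end))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gi, gg,
                                  minoverlap = as.integer(min_overlap_bp)))
    if (length(hits) > 0) {
      h <- data.frame(sample_id = intervals$sample_id[S4Vectors::from(hits)],
                      symbol = genes$symbol[S4Vectors::to(hits)],
                      direction = intervals$direction[S4Vectors::from(hits)],
                      stringsAsFactors = FALSE)
      agg <- stats::aggregate(
        rep(1L, nrow(h)),
        by = h[, c("sample_id", "symbol", "direction")], FUN = sum)
      calls <- data.frame(
        sample_id = agg$sample_id,
        symbol = agg$symbol,
        status = c(gain = "amplified", loss = "deleted")[agg$direction],
        supporting_interval_count = as.integer(agg$x),
        stringsAsFactors = FALSE)
      both <- unique(calls[, c("sample_id", "symbol")])
      conflict <- calls[duplicated(calls[, c("sample_id", "symbol")]), ,
                        drop = FALSE]
      if (nrow(conflict) > 0)
        warning("gain and loss overlap the same gene in the same sample: ",
                paste(unique(paste0(conflict$sample_id, "/",
                                    conflict$symbol)), collapse = ", "))
    }
  }

  if (keep_none) {
    samples <- sort(unique(intervals$sample_id))
    full <- expand.grid(sample_id = samples, symbol = genes$symbol,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key_full <- paste(full$sample_id, full$symbol, sep = "\r")
    key_call <- paste(calls$sample_id, calls$symbol, sep = "\r")
    none <- full[!(key_full %in% key_call), , drop = FALSE]
    if (nrow(none) > 0) {
      none$status <- "none"
      none$supporting_interval_count <- 0L
      calls <- rbind(calls, none)
    }
  }
  calls <- calls[order(calls$sample_id, calls$symbol, calls$status), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Integer percent by truncation
#'
#' `floor(100 * count / n)`, computed in integer arithmetic. This is the
#' display convention for cohort gene-frequency tables: 16/30 prints as 53,
#' 14/30 as 46 and 20/30 as 66 (rounding would give 47 and 67 and disagree
#' with the printed tables).
#'
#' @param count non-negative integer vector of sample counts.
#' @param n cohort size (positive integer).
#' @return integer percent vector.
#' @export
percent_floor <- function(count, n) {
  count <- as.integer(count)
  n <- as.integer(n)
  if (any(is.na(n)) || any(n <= 0)) stop("n must be a positive integer")
  if (any(!is.na(count) & count < 0)) stop("count must be non-negative")
  as.integer((count * 100L) %/% n)
}

#' Gene aberration frequency table for a cohort
#'
#' Tabulates, per gene, the number and truncated percent of cohort samples
#' in which it is amplified or deleted, in the format of published cohort
#' gene-frequency tables ("14 (46)" means amplified in 14 of n samples,
#' 46%). Percentages use [percent_floor()].
#'
#' @param calls gene calls from [call_gene_aberrations()].
#' @param n_samples cohort size used for the percent denominators.
#' @param genes optional annotation data.frame; when given, every annotated
#'   gene appears (zero counts included) and its `cytoband` (if present) or
#'   chromosome labels the `region` column.
#' @return data.frame ordered by symbol with columns `symbol`, `region`,
#'   `amplified_count`, `amplified_percent`, `deleted_count`,
#'   `deleted_percent`, `n_samples`.
#' @export
gene_frequency_table <- function(calls, n_samples, genes = NULL) {
  if (length(n_samples) != 1 || is.na(n_samples) || n_samples <= 0)
    stop("n_samples must be a positive integer")
  n_samples <- as.integer(n_samples)
  real <- calls[calls$status %in% c("amplified", "deleted"), , drop = FALSE]

  symbols <- if (!is.null(genes)) genes$symbol else sort(unique(real$symbol))
  amp <- table(factor(real$symbol[real$status == "amplified"],
                      levels = symbols))
  del <- table(factor(real$symbol[real$status == "deleted"],
                      levels = symbols))
  bad <- pmax(amp, del) > n_samples
  if (any(bad))
    stop("per-gene count exceeds n_samples for: ",
         paste(symbols[bad], collapse = ", "))

  region <- if (!is.null(genes)) {
    if ("cytoband" %in% names(genes)) genes$cytoband else genes$chromosome
  } else {
    rep(NA_character_, length(symbols))
  }
  out <- data.frame(symbol = symbols,
                    region = region,
                    amplified_count = as.integer(amp),
                    amplified_percent = percent_floor(as.integer(amp),
                                                      n_samples),
                    deleted_count = as.integer(del),
                    deleted_percent = percent_floor(as.integer(del),
                                                    n_samples),
                    n_samples = rep(n_samples, length(symbols)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truncate to a fixed number of decimals
#'
#' Truncation (toward zero), not rounding: `trunc_dec(25.466, 2)` is 25.46
#' and `trunc_dec(23.866, 1)` is 23.8. This is the display convention used
#' throughout the cohort summaries, chosen because it reproduces every
#' printed mean and quartile in the reference tables the package mirrors.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return truncated numeric vector.
#' @export
trunc_dec <- function(x, digits = 1) {
  p <- 10^digits
  trunc(x * p) / p
}
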