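# Synthetic aCGH cohort generator with planted ground truth. Emulates the
# statistical structure the downstream analysis assumes: a low-aberration
# MSI-H subgroup sharing exclusive signature aberrations, chromosomal-
# instability (CIN) samples with many aberrations, recurrence concentrated
# on chromosomes 3/5/7/8/20/X, and male-biased chromosome X gains.

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the generator configuration. Defaults describe a
#' 30-sample colorectal-cancer-like cohort: 5/30 MSI-H and 4/30 MSI-L
#' samples; background aberration counts Poisson with mean 27 for non-MSI-H
#' (CIN) and 10 for MSI-H samples; 5 signature aberrations shared by (and
#' exclusive to) every MSI-H sample; a catalog of recurrent regions confined
#' to chromosomes 3/5/7/8/20/X from which half of all background aberrations
#' are drawn; chromosome X gains planted with probability 10/15 in males and
#' 4/15 in females. Intervals live on a miniature genome (24 chromosomes of
#' 10 Mb) with log-uniform lengths between 50 kb and 5 Mb; gain fold changes
#' are uniform on (1.3, 3.0) and losses on (0.3, 0.7), so every planted
#' event survives the 1.2/0.8 threshold filter by construction.
#'
#' @param n_samples cohort size.
#' @param msi_h_fraction,msi_l_fraction fractions of MSI-H and MSI-L samples.
#' @param mean_aberrations_cin,mean_aberrations_msih Poisson means of the
#'   background aberration count per non-MSI-H and MSI-H sample; the MSI-H
#'   mean must be the smaller one.
#' @param n_signature_aberrations_msih number of shared aberrations planted
#'   in every MSI-H sample and no other.
#' @param recurrent_chromosomes,recurrent_weights chromosomes hosting the
#'   recurrent-region catalog and their sampling weights.
#' @param recurrent_fraction probability that a background aberration is
#'   drawn from the catalog rather than placed uniformly.
#' @param n_recurrent_catalog number of catalog intervals.
#' @param male_x_gain_prob,female_x_gain_prob per-sex probability of the
#'   planted chromosome X gain.
#' @param gain_fold_range,loss_fold_range fold-change ranges; the gain low
#'   end must exceed 1.2 and the loss high end must be below 0.8.
#' @param chromosome_length length of each miniature chromosome in bp.
#' @param interval_length_range aberration length range (log-uniform draw).
#' @param signature_spans_gene make the first signature aberration a loss
#'   spanning an annotated gene on a recurrent chromosome.
#' @param jitter_bp when positive, each planted shared interval is jittered
#'   by up to this many bp per sample (stress-tests tolerance matching in
#'   [build_union()]); 0 keeps shared intervals base-identical.
#' @param seed integer seed; cohorts are byte-identical for equal configs.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 30L,
                          msi_h_fraction = 5 / 30,
                          msi_l_fraction = 4 / 30,
                          mean_aberrations_cin = 27,
                          mean_aberrations_msih = 10,
                          n_signature_aberrations_msih = 5L,
                          recurrent_chromosomes = c("3", "5", "7", "8",
                                                    "20", "X"),
                          recurrent_weights = NULL,
                          recurrent_fraction = 0.5,
                          n_recurrent_catalog = 40L,
                          male_x_gain_prob = 10 / 15,
                          female_x_gain_prob = 4 / 15,
                          gain_fold_range = c(1.3, 3.0),
                          loss_fold_range = c(0.3, 0.7),
                          chromosome_length = 1e7,
                          interval_length_range = c(5e4, 5e6),
                          signature_spans_gene = TRUE,
                          jitter_bp = 0L,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              msi_h_fraction = msi_h_fraction,
              msi_l_fraction = msi_l_fraction,
              mean_aberrations_cin = mean_aberrations_cin,
              mean_aberrations_msih = mean_aberrations_msih,
              n_signature_aberrations_msih =
                as.integer(n_signature_aberrations_msih),
              recurrent_chromosomes = as.character(recurrent_chromosomes),
              recurrent_weights = recurrent_weights %||%
                rep(1, length(recurrent_chromosomes)),
              recurrent_fraction = recurrent_fraction,
              n_recurrent_catalog = as.integer(n_recurrent_catalog),
              male_x_gain_prob = male_x_gain_prob,
              female_x_gain_prob = female_x_gain_prob,
              gain_fold_range = gain_fold_range,
              loss_fold_range = loss_fold_range,
              chromosome_length = chromosome_length,
              interval_length_range = interval_length_range,
              signature_spans_gene = isTRUE(signature_spans_gene),
              jitter_bp = as.integer(jitter_bp),
              seed = as.integer(seed))
  props <- c(cfg$msi_h_fraction, cfg$msi_l_fraction, cfg$recurrent_fraction,
             cfg$male_x_gain_prob, cfg$female_x_gain_prob)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]")
  if (cfg$n_samples < 1) stop("n_samples must be positive")
  if (cfg$mean_aberrations_msih > cfg$mean_aberrations_cin)
    stop("mean_aberrations_msih must not exceed mean_aberrations_cin ",
         "(MSI-H tumors carry fewer aberrations)")
  if (cfg$mean_aberrations_cin < 0 || cfg$mean_aberrations_msih < 0)
    stop("aberration means must be non-negative")
  if (cfg$gain_fold_range[1] <= 1.2)
    stop("gain_fold_range low end must exceed 1.2")
  if (cfg$loss_fold_range[2] >= 0.8)
    stop("loss_fold_range high end must be below 0.8")
  if (!all(cfg$recurrent_chromosomes %in% CHROM_LABELS))
    stop("unrecognized recurrent chromosome label")
  if (length(cfg$recurrent_weights) != length(cfg$recurrent_chromosomes))
    stop("recurrent_weights must match recurrent_chromosomes")
  structure(cfg, class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one random interval on the miniature genome
.rand_interval <- function(cfg, chromosome = NULL) {
  if (is.null(chromosome)) chromosome <- sample(CHROM_LABELS, 1L)
  len <- round(exp(stats::runif(1, log(cfg$interval_length_range[1]),
                                log(cfg$interval_length_range[2]))))
  len <- min(len, cfg$chromosome_length - 1)
  start <- sample.int(cfg$chromosome_length - len, 1L) - 1L
  list(chromosome = chromosome, start = as.integer(start),
       end = as.integer(start + len))
}

.rand_fold <- function(cfg, direction, k = 1L) {
  r <- if (direction == "gain") cfg$gain_fold_range else cfg$loss_fold_range
  stats::runif(k, r[1], r[2])
}

#' Generate a synthetic aCGH cohort with planted truth
#'
#' Draws clinical metadata, per-sample aberration intervals and a gene
#' annotation, together with the planted ground truth needed for recovery
#' tests. Per-sample background counts are Poisson with the group-specific
#' mean; background aberrations come from the recurrent-region catalog
#' (shared, base-identical coordinates across samples) with probability
#' `recurrent_fraction` and from a uniform background otherwise; every
#' MSI-H sample additionally carries the same signature aberrations, which
#' no other sample carries; chromosome X gains are planted per sex with the
#' configured probabilities. Deterministic for a fixed config (including
#' its seed).
#'
#' @param config a [cohort_config()].
#' @return object of class `cgh_cohort`: list with `metadata` (one row per
#'   sample, `n_aberrations` filled with the realized counts), `intervals`
#'   (classified, with `direction` and in-range `fold_change`), `genes` (the
#'   packaged synthetic gene annotation), `truth` (list:
#'   `msi_h_sample_ids`, `signature_keys`, `signature_gene`,
#'   `per_sample_counts`, `x_gain_carriers`) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  genes <- can_gene_annotation()
  .with_seed(cfg$seed, {
    n <- cfg$n_samples
    ids <- sprintf("S%02d", seq_len(n))
    n_h <- round(n * cfg$msi_h_fraction)
    n_l <- min(round(n * cfg$msi_l_fraction), n - n_h)
    msi <- rep("MSS", n)
    pick <- sample.int(n, n_h + n_l)
    msi[pick[seq_len(n_h)]] <- "MSI-H"
    if (n_l > 0) msi[pick[n_h + seq_len(n_l)]] <- "MSI-L"
    sex <- sample(c("M", "F"), n, replace = TRUE)
    age <- pmin(pmax(round(stats::rnorm(n, 63.5, 11.6)), 30L), 95L)
    stage <- sample(1:4, n, replace = TRUE, prob = c(3, 9, 15, 3) / 30)
    # MSI-H colorectal tumors are proximal (right-sided)
    location <- ifelse(msi == "MSI-H", "R",
                       sample(c("R", "L"), n, replace = TRUE,
                              prob = c(16, 9) / 25))
    differentiation <- sample(c("well", "moderate", "poor"), n,
                              replace = TRUE, prob = c(2, 27, 1) / 30)

    # signature aberrations: shared by every MSI-H sample, exclusive to them
    sig <- list()
    sig_gene <- NA_character_
    if (n_h > 0 && cfg$n_signature_aberrations_msih > 0) {
      for (j in seq_len(cfg$n_signature_aberrations_msih)) {
        chrom <- sample(cfg$recurrent_chromosomes, 1L,
                        prob = cfg$recurrent_weights)
        direction <- if (j %% 2 == 1) "loss" else "gain"
        if (j == 1 && cfg$signature_spans_gene) {
          cand <- genes[genes$chromosome %in% cfg$recurrent_chromosomes, ,
                        drop = FALSE]
          g <- cand[sample.int(nrow(cand), 1L), ]
          sig_gene <- g$symbol
          pad <- 25000L
          sig[[j]] <- list(chromosome = g$chromosome,
                           start = max(0L, g$start - pad),
                           end = min(as.integer(cfg$chromosome_length),
                                     g$end + pad),
                           direction = "loss")
        } else {
          iv <- .rand_interval(cfg, chrom)
          iv$direction <- direction
          sig[[j]] <- iv
        }
      }
    }

    # recurrent-region catalog (fixed direction per entry so that repeated
    # draws across samples deduplicate into shared characters)
    catalog <- lapply(seq_len(cfg$n_recurrent_catalog), function(i) {
      chrom <- sample(cfg$recurrent_chromosomes, 1L,
                      prob = cfg$recurrent_weights)
      iv <- .rand_interval(cfg, chrom)
      iv$direction <- sample(c("gain", "loss"), 1L)
      iv
    })
    # the planted X gain: one shared interval
    x_gain <- .rand_interval(cfg, "X")
    x_gain$direction <- "gain"

    rows <- list()
    truth_counts <- integer(n)
    x_carriers <- character(0)
    for (i in seq_len(n)) {
      mean_i <- if (msi[i] == "MSI-H") cfg$mean_aberrations_msih
                else cfg$mean_aberrations_cin
      n_bg <- stats::rpois(1L, mean_i)
      ivs <- list()
      if (n_bg > 0) {
        from_cat <- stats::runif(n_bg) < cfg$recurrent_fraction
        n_cat <- min(sum(from_cat), cfg$n_recurrent_catalog)
        if (n_cat > 0)
          ivs <- c(ivs, catalog[sample.int(cfg$n_recurrent_catalog, n_cat)])
        for (j in seq_len(n_bg - n_cat)) {
          iv <- .rand_interval(cfg)
          iv$direction <- sample(c("gain", "loss"), 1L)
          ivs <- c(ivs, list(iv))
        }
      }
      if (msi[i] == "MSI-H") ivs <- c(ivs, sig)
      p_x <- if (sex[i] == "M") cfg$male_x_gain_prob else cfg$female_x_gain_prob
      if (stats::runif(1) < p_x) {
        ivs <- c(ivs, list(x_gain))
        x_carriers <- c(x_carriers, ids[i])
      }
      if (length(ivs) == 0) next
      df <- data.frame(
        sample_id = ids[i],
        chromosome = vapply(ivs, `[[`, "", "chromosome"),
        start = vapply(ivs, function(v) as.integer(v$start), integer(1)),
        end = vapply(ivs, function(v) as.integer(v$end), integer(1)),
        direction = vapply(ivs, `[[`, "", "direction"),
        stringsAsFactors = FALSE)
      if (cfg$jitter_bp > 0) {
        jit <- function(k) as.integer(round(stats::runif(k, -cfg$jitter_bp,
                                                         cfg$jitter_bp)))
        df$start <- pmax(0L, df$start + jit(nrow(df)))
        df$end <- pmin(as.integer(cfg$chromosome_length),
                       df$end + jit(nrow(df)))
      }
      df <- df[!duplicated(df[, c("chromosome", "start", "end",
                                  "direction")]), , drop = FALSE]
      df$fold_change <- NA_real_
      for (d in c("gain", "loss")) {
        idx <- df$direction == d
        if (any(idx)) df$fold_change[idx] <- .rand_fold(cfg, d, sum(idx))
      }
      truth_counts[i] <- nrow(df)
      rows[[length(rows) + 1L]] <- df
    }

    intervals <- if (length(rows) > 0) {
      out <- do.call(rbind, rows)
      out$n_probes <- pmax(3L, as.integer((out$end - out$start) / 10000L))
      rownames(out) <- NULL
      out[, c("sample_id", "chromosome", "start", "end", "fold_change",
              "n_probes", "direction")]
    } else {
      cbind(.empty_intervals(), data.frame(direction = character(0)))
    }

    metadata <- data.frame(
      sample_id = ids, age = as.integer(age),
      sex = factor(sex, levels = c("M", "F")),
      stage = factor(stage, levels = 1:4),
      location = factor(location, levels = c("L", "R")),
      differentiation = factor(differentiation,
                               levels = c("well", "moderate", "poor")),
      msi = factor(msi, levels = c("MSS", "MSI-L", "MSI-H")),
      n_aberrations = truth_counts,
      stringsAsFactors = FALSE)

    signature_keys <- if (length(sig) > 0) {
      data.frame(chromosome = vapply(sig, `[[`, "", "chromosome"),
                 start = vapply(sig, function(v) as.integer(v$start),
                                integer(1)),
                 end = vapply(sig, function(v) as.integer(v$end),
                              integer(1)),
                 direction = vapply(sig, `[[`, "", "direction"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chromosome = character(0), start = integer(0),
                 end = integer(0), direction = character(0))
    }

    structure(list(
      metadata = metadata,
      intervals = intervals,
      genes = genes,
      truth = list(msi_h_sample_ids = ids[msi == "MSI-H"],
                   signature_keys = signature_keys,
                   signature_gene = sig_gene,
                   per_sample_counts = stats::setNames(truth_counts, ids),
                   x_gain_carriers = x_carriers),
      config = cfg), class = "cgh_cohort")
  })
}

#' @export
print.cgh_cohort <- function(x, ...) {
  cat(sprintf("Synthetic aCGH cohort: %d samples (%d MSI-H), %d intervals, seed %d\n",
              nrow(x$metadata), length(x$truth$msi_h_sample_ids),
              nrow(x$intervals), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the three external files in the exact formats of the package
#' readers: `metadata.csv` ([read_sample_metadata()]), `intervals.tsv` in
#' one-based inclusive coordinates ([read_interval_report()]) and
#' `genes.bed` ([read_gene_bed()]). Reading them back reproduces the
#' in-memory cohort records.
#'
#' @param cohort a `cgh_cohort` from [generate_cohort()].
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cgh_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  write_sample_metadata(cohort$metadata, file.path(directory, "metadata.csv"))
  write_interval_report(cohort$intervals, file.path(directory,
                                                    "intervals.tsv"),
                        convention = "one_based_inclusive")
  write_gene_bed(cohort$genes, file.path(directory, "genes.bed"))
  invisible(directory)
}
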