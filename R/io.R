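# Readers and writers for the external formats, and the single home for
# coordinate-convention handling. All coordinates are zero-based half-open
# internally; the readers/writers convert at the boundary.

#' Recognized chromosome labels
#'
#' The analysis covers the 24 human nuclear chromosomes (autosomes 1-22 plus
#' X and Y). Mitochondrial and alternate contigs are rejected.
#' @keywords internal
CHROM_LABELS <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome labels
#'
#' Strips any `chr` prefix, trims whitespace and upper-cases X/Y. Labels not
#' among the 24 recognized nuclear chromosomes (1-22, X, Y) become `NA`.
#'
#' @param x character vector of chromosome labels (e.g. `"chr8"`, `"x"`).
#' @return character vector of normalized labels, `NA` where unrecognized.
#' @examples
#' normalize_chromosome(c("chr8", "x", "17", "chrM"))
#' @export
normalize_chromosome <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x <- toupper(x)
  x[!(x %in% CHROM_LABELS)] <- NA_character_
  x
}

.empty_intervals <- function() {
  data.frame(sample_id = character(0), chromosome = character(0),
             start = integer(0), end = integer(0),
             fold_change = numeric(0), n_probes = integer(0),
             stringsAsFactors = FALSE)
}

#' Read a per-sample aberration interval report
#'
#' Reads a tab-separated interval report (one segmented gain/loss call per
#' row, emulating the interval-based output of aCGH segmentation software)
#' with columns `sample_id`, `chromosome`, `start`, `end`, `fold_change` and
#' optionally `n_probes`. `fold_change` is the linear tumor/reference ratio.
#'
#' Coordinates are converted to the package-internal zero-based half-open
#' convention. Rows whose chromosome label is not among 1-22/X/Y are dropped
#' with a warning; a non-positive fold change is an error (it cannot be a
#' ratio of intensities).
#'
#' @param path path to the TSV file.
#' @param convention coordinate convention of the file: `"one_based_inclusive"`
#'   (the common convention of interval reports and the default) or
#'   `"zero_based_half_open"` (BED-style).
#' @return a data.frame of aberration intervals with columns `sample_id`,
#'   `chromosome`, `start`, `end` (zero-based half-open), `fold_change`,
#'   `n_probes` (`NA` when absent from the file).
#' @seealso [write_interval_report()], [classify_intervals()]
#' @export
read_interval_report <- function(path,
                                 convention = c("one_based_inclusive",
                                                "zero_based_half_open")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("sample_id", "chromosome", "start", "end", "fold_change")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("interval report is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(.empty_intervals())

  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  fc <- suppressWarnings(as.numeric(df$fold_change))
  bad_fc <- is.na(fc) | fc <= 0
  if (any(bad_fc))
    stop("non-positive or unparseable fold_change at row(s): ",
         paste(which(bad_fc), collapse = ", "))
  bad_coord <- is.na(start) | is.na(end)
  if (any(bad_coord))
    stop("unparseable coordinates at row(s): ",
         paste(which(bad_coord), collapse = ", "))

  if (convention == "one_based_inclusive") start <- start - 1

  bad_span <- start >= end
  if (any(bad_span))
    stop("start must be strictly less than end (after conversion) at row(s): ",
         paste(which(bad_span), collapse = ", "))

  chrom <- normalize_chromosome(df$chromosome)
  keep <- !is.na(chrom)
  if (any(!keep))
    warning(sum(!keep), " row(s) with unrecognized chromosome label dropped: ",
            paste(unique(df$chromosome[!keep]), collapse = ", "))

  n_probes <- if ("n_probes" %in% names(df)) {
    suppressWarnings(as.integer(df$n_probes))
  } else {
    rep(NA_integer_, nrow(df))
  }

  out <- data.frame(sample_id = as.character(df$sample_id),
                    chromosome = chrom,
                    start = as.integer(start),
                    end = as.integer(end),
                    fold_change = fc,
                    n_probes = n_probes,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an aberration interval report
#'
#' Inverse of [read_interval_report()]: converts internal zero-based
#' half-open coordinates to the requested convention and writes a TSV.
#' The derived `direction` column, if present, is not written (it is
#' recomputed from `fold_change` on read).
#'
#' @param intervals data.frame as returned by [read_interval_report()].
#' @param path output path.
#' @inheritParams read_interval_report
#' @export
write_interval_report <- function(intervals, path,
                                  convention = c("one_based_inclusive",
                                                 "zero_based_half_open")) {
  convention <- match.arg(convention)
  cols <- c("sample_id", "chromosome", "start", "end", "fold_change")
  stopifnot(all(cols %in% names(intervals)))
  out <- intervals[, intersect(c(cols, "n_probes"), names(intervals)),
                   drop = FALSE]
  if (convention == "one_based_inclusive") out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table (BED4)
#'
#' Reads a BED file with at least four tab-separated fields: chromosome,
#' start, end (BED-native zero-based half-open, retained as-is) and gene
#' symbol. Strand and further columns are ignored (copy-number events are
#' strandless). Duplicate symbols are an error; genes on unrecognized
#' chromosomes are dropped with a warning.
#'
#' @param path path to the BED file.
#' @return data.frame with columns `symbol`, `chromosome`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lines <- lines[keep]
  empty <- data.frame(symbol = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4))
    stop("malformed BED line (fewer than 4 tab-separated fields) at line(s): ",
         paste(which(nf < 4), collapse = ", "))
  chrom_raw <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  symbol <- vapply(parts, `[[`, "", 4L)
  bad <- is.na(start) | is.na(end) | start >= end | !nzchar(symbol)
  if (any(bad))
    stop("malformed BED line (bad coordinates or empty symbol) at line(s): ",
         paste(which(bad), collapse = ", "))

  chrom <- normalize_chromosome(chrom_raw)
  drop <- is.na(chrom)
  if (any(drop))
    warning(sum(drop), " gene(s) on unrecognized chromosomes dropped: ",
            paste(symbol[drop], collapse = ", "))
  symbol <- symbol[!drop]
  dup <- duplicated(symbol)
  if (any(dup))
    stop("duplicate gene symbol(s) in annotation: ",
         paste(unique(symbol[dup]), collapse = ", "))
  data.frame(symbol = symbol, chromosome = chrom[!drop],
             start = as.integer(start[!drop]), end = as.integer(end[!drop]),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation table (BED4)
#'
#' @param genes data.frame as returned by [read_gene_bed()].
#' @param path output path.
#' @export
write_gene_bed <- function(genes, path) {
  stopifnot(all(c("symbol", "chromosome", "start", "end") %in% names(genes)))
  out <- genes[, c("chromosome", "start", "end", "symbol")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Enum normalization tables for the clinical metadata. Clinical tables use
# free text ("Moderately", "well diff", MSI coded S/L/H), so the mapping is
# explicit rather than inferred.
.SEX_MAP <- c(M = "M", MALE = "M", F = "F", FEMALE = "F")
.LOC_MAP <- c(R = "R", RIGHT = "R", PROXIMAL = "R",
              L = "L", LEFT = "L", DISTAL = "L")
.DIFF_MAP <- c(WELL = "well", MODERATE = "moderate", MODERATELY = "moderate",
               MOD = "moderate", POOR = "poor", POORLY = "poor")
.MSI_MAP <- c(S = "MSS", MSS = "MSS", STABLE = "MSS",
              L = "MSI-L", "MSI-L" = "MSI-L", LOW = "MSI-L",
              H = "MSI-H", "MSI-H" = "MSI-H", HIGH = "MSI-H")

.norm_enum <- function(x, map, field, first_word = FALSE) {
  key <- toupper(trimws(as.character(x)))
  if (first_word) key <- sub("[ _].*$", "", key)
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad))
    stop(sprintf("unknown %s value '%s' at row %d", field,
                 x[bad][1], which(bad)[1]))
  out
}

#' Read clinical sample metadata
#'
#' Reads a CSV with one row per sample and the columns `sample_id`, `age`,
#' `sex`, `stage`, `location`, `differentiation`, `msi` and optionally
#' `n_aberrations`; any further columns are ignored. Free-text clinical
#' values are normalized to fixed levels: sex `M`/`F`; tumor location `R`
#' (right-sided/proximal) or `L`; differentiation `well`/`moderate`/`poor`
#' (accepting e.g. "Moderately", "well diff"); microsatellite status
#' `MSS`/`MSI-L`/`MSI-H` (accepting the single-letter codes S/L/H). Unknown
#' tokens, ages below 1 or stages outside 1-4 are errors naming the row.
#'
#' @param path path to the CSV file.
#' @return data.frame with `sample_id` (character), `age` (integer), factor
#'   columns `sex`, `stage`, `location`, `differentiation`, `msi`, and
#'   integer `n_aberrations` (`NA` when absent).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("sample_id", "age", "sex", "stage", "location",
                "differentiation", "msi")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))

  age <- suppressWarnings(as.integer(df$age))
  bad <- is.na(age) | age <= 0
  if (any(bad))
    stop("invalid age '", df$age[bad][1], "' at row ", which(bad)[1])
  stage <- suppressWarnings(as.integer(df$stage))
  bad <- is.na(stage) | stage < 1 | stage > 4
  if (any(bad))
    stop("invalid stage '", df$stage[bad][1], "' at row ", which(bad)[1],
         " (must be 1-4)")

  n_ab <- if ("n_aberrations" %in% names(df)) {
    v <- suppressWarnings(as.integer(df$n_aberrations))
    bad <- (!is.na(df$n_aberrations) & nzchar(df$n_aberrations)) &
      (is.na(v) | v < 0)
    if (any(bad))
      stop("invalid n_aberrations '", df$n_aberrations[bad][1],
           "' at row ", which(bad)[1])
    v
  } else {
    rep(NA_integer_, nrow(df))
  }

  data.frame(
    sample_id = as.character(df$sample_id),
    age = age,
    sex = factor(.norm_enum(df$sex, .SEX_MAP, "sex"), levels = c("M", "F")),
    stage = factor(stage, levels = 1:4),
    location = factor(.norm_enum(df$location, .LOC_MAP, "location"),
                      levels = c("L", "R")),
    differentiation = factor(
      .norm_enum(df$differentiation, .DIFF_MAP, "differentiation",
                 first_word = TRUE),
      levels = c("well", "moderate", "poor")),
    msi = factor(.norm_enum(df$msi, .MSI_MAP, "msi"),
                 levels = c("MSS", "MSI-L", "MSI-H")),
    n_aberrations = n_ab,
    stringsAsFactors = FALSE)
}

#' Write clinical sample metadata
#'
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  out <- metadata
  for (col in names(out)) if (is.factor(out[[col]]))
    out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coerce a tree argument to an ape phylo object
#' @keywords internal
as_phylo <- function(tree) {
  if (inherits(tree, "cladogram")) return(tree$phy)
  if (inherits(tree, "phylo")) return(tree)
  stop("expected a 'cladogram' or ape 'phylo' object")
}

#' Write a cladogram as Newick
#'
#' Serializes a rooted cladogram (or any ape `phylo`) as a Newick string.
#' The output round-trips through [read_newick()]. Duplicate leaf labels are
#' an error.
#'
#' @param tree a `cladogram` (see [parsimony_cladogram()]) or `phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  phy <- as_phylo(tree)
  if (anyDuplicated(phy$tip.label) > 0)
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an ape `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
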