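# Cohort-wide deduplicated aberration list and the binary presence/absence
# ("polarity") matrix that feeds the parsimony stage.

.key_tag <- function(keys) {
  paste0(keys$chromosome, ":", keys$start, "-", keys$end, ":", keys$direction)
}

.chrom_rank <- function(x) match(x, CHROM_LABELS)

#' Build the cohort-wide union of unique aberrations
#'
#' Pools the classified aberration intervals of all samples and removes
#' duplicates. Aberration identity is exact equality of
#' (chromosome, start, end, direction) — gains and losses at the same locus
#' are distinct characters. With `merge_tolerance_bp > 0`, keys on the same
#' chromosome with the same direction whose start and end coordinates each
#' differ by at most the tolerance are merged (single linkage along the
#' start-sorted order) into their union span; this accommodates
#' segmentations that do not agree base-exactly and is off by default.
#'
#' @param intervals classified intervals for the whole cohort (a data.frame
#'   with `sample_id` and a `direction` column; see [classify_intervals()]).
#' @param merge_tolerance_bp endpoint tolerance in bp for merging
#'   near-identical keys (default 0 = exact deduplication).
#' @return data.frame of unique keys ordered by (chromosome, start, end,
#'   direction), with the tolerance stored in attribute `"tolerance"`.
#' @export
build_union <- function(intervals, merge_tolerance_bp = 0L) {
  .check_classified(intervals)
  keys <- unique(intervals[, c("chromosome", "start", "end", "direction")])
  if (merge_tolerance_bp > 0 && nrow(keys) > 1) {
    merged <- list()
    for (grp in split(keys, paste(keys$chromosome, keys$direction))) {
      grp <- grp[order(grp$start, grp$end), , drop = FALSE]
      cluster <- grp[1, , drop = FALSE]
      for (i in seq_len(nrow(grp))[-1]) {
        if (abs(grp$start[i] - cluster$start) <= merge_tolerance_bp &&
            abs(grp$end[i] - cluster$end) <= merge_tolerance_bp) {
          cluster$start <- min(cluster$start, grp$start[i])
          cluster$end <- max(cluster$end, grp$end[i])
        } else {
          merged[[length(merged) + 1L]] <- cluster
          cluster <- grp[i, , drop = FALSE]
        }
      }
      merged[[length(merged) + 1L]] <- cluster
    }
    keys <- do.call(rbind, merged)
  }
  keys <- keys[order(.chrom_rank(keys$chromosome), keys$start, keys$end,
                     keys$direction), , drop = FALSE]
  rownames(keys) <- NULL
  attr(keys, "tolerance") <- as.integer(merge_tolerance_bp)
  keys
}

#' Encode the binary sample-by-aberration polarity matrix
#'
#' Scores each unique aberration as present (1) or absent (0) in each
#' sample. Samples with zero aberrations keep an all-zero row so that every
#' cohort sample appears as a cladogram leaf; pass `sample_ids` to include
#' such samples (by default the samples observed in `intervals` are used).
#' An interval that matches no union key is a state error.
#'
#' @param intervals classified intervals for the whole cohort.
#' @param keys unique aberration keys from [build_union()] on the same data.
#' @param sample_ids optional character vector fixing the row set and order.
#' @return an `aberration_matrix`: list with `cells` (binary integer matrix,
#'   samples x keys), `keys` (the key data.frame) and `sample_ids`.
#' @export
encode_matrix <- function(intervals, keys, sample_ids = NULL) {
  .check_classified(intervals)
  tol <- attr(keys, "tolerance")
  if (is.null(tol)) tol <- 0L
  if (is.null(sample_ids)) sample_ids <- sort(unique(intervals$sample_id))
  tags <- .key_tag(keys)
  cells <- matrix(0L, nrow = length(sample_ids), ncol = nrow(keys),
                  dimnames = list(sample_ids, tags))
  if (nrow(intervals) > 0) {
    if (!all(intervals$sample_id %in% sample_ids))
      stop("intervals contain samples not in sample_ids: ",
           paste(setdiff(unique(intervals$sample_id), sample_ids),
                 collapse = ", "))
    itag <- paste0(intervals$chromosome, ":", intervals$start, "-",
                   intervals$end, ":", intervals$direction)
    col <- match(itag, tags)
    if (tol > 0 && anyNA(col)) {
      # tolerance mode: assign to the smallest key span (same chromosome and
      # direction) whose tolerance-padded span contains the interval
      for (i in which(is.na(col))) {
        cand <- which(keys$chromosome == intervals$chromosome[i] &
                        keys$direction == intervals$direction[i] &
                        keys$start - tol <= intervals$start[i] &
                        keys$end + tol >= intervals$end[i])
        if (length(cand) > 0)
          col[i] <- cand[which.min(keys$end[cand] - keys$start[cand])]
      }
    }
    if (anyNA(col))
      stop("interval(s) not matched by any union key (state error): ",
           paste(itag[is.na(col)], collapse = ", "))
    cells[cbind(match(intervals$sample_id, sample_ids), col)] <- 1L
  }
  structure(list(cells = cells, keys = keys, sample_ids = sample_ids),
            class = "aberration_matrix")
}

#' Coerce to an aberration matrix
#'
#' Accepts an `aberration_matrix` or a plain binary 0/1 matrix with sample
#' row names (keys then unknown).
#' @param x object to coerce.
#' @return an `aberration_matrix`.
#' @export
as_aberration_matrix <- function(x) {
  if (inherits(x, "aberration_matrix")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x)))
      rownames(x) <- paste0("S", seq_len(nrow(x)))
    storage.mode(x) <- "integer"
    if (length(x) > 0 && !all(x %in% c(0L, 1L)))
      stop("matrix cells must be binary 0/1")
    return(structure(list(cells = x, keys = NULL,
                          sample_ids = rownames(x)),
                     class = "aberration_matrix"))
  }
  stop("cannot coerce to aberration_matrix")
}

#' @export
print.aberration_matrix <- function(x, ...) {
  cat("Binary aberration (polarity) matrix\n")
  cat("  samples:    ", nrow(x$cells), "\n")
  cat("  aberrations:", ncol(x$cells), "\n")
  cat("  incidences: ", sum(x$cells), "\n")
  invisible(x)
}

#' Write a binary character matrix in PHYLIP discrete format
#'
#' Relaxed dialect by default (name, whitespace, contiguous 0/1 string);
#' `strict = TRUE` pads/truncates names to the classic 10 characters.
#'
#' @param m an `aberration_matrix` (or coercible).
#' @param path output path.
#' @param strict use strict 10-character name fields.
#' @export
write_phylip <- function(m, path, strict = FALSE) {
  m <- as_aberration_matrix(m)
  cells <- m$cells
  names_ <- rownames(cells)
  if (strict) names_ <- formatC(strtrim(names_, 10), width = -10)
  lines <- c(paste(nrow(cells), ncol(cells)),
             paste0(names_, if (strict) "" else " ",
                    apply(cells, 1L, paste0, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP discrete binary character matrix
#'
#' Reads the relaxed dialect written by [write_phylip()] (strict files also
#' parse, provided names contain no spaces).
#'
#' @param path path to the PHYLIP file.
#' @return an `aberration_matrix` (keys unknown).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n <- hdr[1]; k <- hdr[2]
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != n) stop("expected ", n, " sequence lines, found ",
                              length(body))
  parts <- regmatches(body, regexpr("^\\S+", body))
  states <- gsub("\\s", "", substring(body, nchar(parts) + 1L))
  if (any(nchar(states) != k))
    stop("character rows do not match the declared length ", k)
  cells <- do.call(rbind, lapply(strsplit(states, ""), as.integer))
  rownames(cells) <- parts
  as_aberration_matrix(cells)
}

#' Write the polarity matrix as TSV with full key headers
#'
#' Companion to [write_phylip()]: a TSV with one row per sample, a
#' `sample_id` column and one 0/1 column per aberration key
#' (`chrom:start-end:direction`).
#'
#' @param m an `aberration_matrix`.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as_aberration_matrix(m)
  df <- data.frame(sample_id = rownames(m$cells), m$cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
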