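# Shared fixture builders (all programmatic; no files beyond inst/extdata).

fixture_metadata <- function() {
  read_sample_metadata(system.file("extdata", "aa_crc_cohort_metadata.csv",
                                   package = "cghclade"))
}

# a minimal classified interval table
make_intervals <- function(sample_id, chromosome, start, end, direction,
                           fold_change = NULL) {
  if (is.null(fold_change))
    fold_change <- ifelse(direction == "gain", 1.5, 0.5)
  data.frame(sample_id = sample_id, chromosome = as.character(chromosome),
             start = as.integer(start), end = as.integer(end),
             fold_change = fold_change, n_probes = NA_integer_,
             direction = direction, stringsAsFactors = FALSE)
}

# write a small interval report TSV and return its path
write_report_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
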