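# Packaged reference tables: the 30-patient African American colorectal
# cancer cohort the package's reporting conventions mirror, and the two
# gene panels it is compared against.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "cghclade")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

#' Clinical metadata of the reference 30-patient AA CRC cohort
#'
#' The clinico-pathological table of a 30-patient African American
#' colorectal cancer cohort (age, sex, AJCC stage, tumor location,
#' differentiation, microsatellite-instability status and the number of
#' aCGH aberrations per tumor), packaged as the worked-example input for
#' the cohort statistics: 764 aberrations in total (mean 25.46 per tumor,
#' range 2-99), 21 MSS / 4 MSI-L / 5 MSI-H samples, 21 right-sided tumors.
#'
#' @return metadata data.frame (see [read_sample_metadata()]); the
#'   `specimen` column of the source table is dropped by the reader.
#' @export
aa_cohort_metadata <- function() {
  read_sample_metadata(.extdata("aa_crc_cohort_metadata.csv"))
}

#' Published aberration frequencies of the 68 CAN genes in the AA cohort
#'
#' The candidate cancer gene (CAN) panel — 68 genes proposed from
#' systematic exome sequencing of colon and breast tumors — with the
#' published counts and integer-truncated percentages of samples in which
#' each gene was amplified or deleted in the reference 30-patient cohort.
#' `NA` marks cells left blank in the published table (one gene, ACTL9,
#' carried no alteration call). Used to validate the [percent_floor()]
#' display rule and as a formatting reference for [gene_frequency_table()].
#'
#' @return data.frame with columns `symbol`, `cytoband`, `amplified_count`,
#'   `amplified_percent`, `deleted_count`, `deleted_percent`.
#' @export
can_gene_frequencies <- function() {
  utils::read.csv(.extdata("can_gene_frequencies.csv"),
                  stringsAsFactors = FALSE)
}

#' Synthetic genomic spans for the 68 CAN genes
#'
#' A BED4 annotation of the CAN panel on the synthetic-cohort generator's
#' miniature genome (24 chromosomes of 10 Mb): each gene keeps its real
#' chromosome (parsed from its cytoband) but receives a deterministic
#' synthetic 120 kb span. The real genomic coordinates are not bundled;
#' this annotation exists so that gene-level calling is testable end-to-end
#' against generated cohorts.
#'
#' @return gene data.frame (see [read_gene_bed()]) of 68 records.
#' @export
can_gene_annotation <- function() {
  read_gene_bed(.extdata("can_genes_synthetic.bed"))
}

#' Published gene-panel comparison with a Caucasian CRC cohort
#'
#' The published side-by-side aberration percentages for 41 oncogenes and
#' tumor suppressor genes in a Caucasian colorectal cancer cohort versus
#' the reference African American cohort. The rows are preserved verbatim
#' from the printed comparison, including its internal inconsistencies
#' (LPL appears twice with different values) and blank cells (`NA`);
#' packaged purely as a side-by-side report-formatting reference, not as
#' data this package recomputes.
#'
#' @return data.frame with columns `symbol`, `cytoband`,
#'   `caucasian_amplified_percent`, `caucasian_deleted_percent`,
#'   `aa_amplified_percent`, `aa_deleted_percent`.
#' @export
caucasian_comparison_reference <- function() {
  utils::read.csv(.extdata("caucasian_comparison_reference.csv"),
                  stringsAsFactors = FALSE)
}
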