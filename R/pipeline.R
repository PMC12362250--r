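#' trnamod: tRNA modification detection from nanopore caller scores
#'
#' See the package DESCRIPTION and the methods vignette for an overview of
#' the pipeline: reference assembly, local alignment and filtering,
#' MM/ML score extraction, de novo pseudouridine fraction calling,
#' symmetric-KL sample comparison, error-score outlier calling, and
#' move-table signal extraction.
#'
#' @useDynLib trnamod, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

#' Run alignment, filtering and score extraction for one sample
#'
#' Convenience wrapper chaining [align_all()], [filter_alignments()] and
#' [build_site_table()].
#'
#' @param reads reads (named character vector or data.frame `read_id`,
#'   `seq`).
#' @param tracks list of [read_score_track()] keyed by read id.
#' @param refs a [reference_set].
#' @param mod_code modification code of the tracks.
#' @param scheme a [scoring_scheme()].
#' @param min_as minimum alignment score (see [filter_alignments()]).
#' @param max_uncovered full-length tolerance (see [filter_alignments()]).
#' @return list with `site_table`, `alignments` (the filtered set) and
#'   `audit` (the filter audit data.frame).
#' @export
extract_sample <- function(reads, tracks, refs, mod_code = "psi",
                           scheme = scoring_scheme(), min_as = 50L,
                           max_uncovered = 0L) {
  alns <- align_all(reads, refs, scheme)
  kept <- filter_alignments(alns, refs, min_as = min_as,
                            max_uncovered = max_uncovered)
  list(site_table = build_site_table(kept, tracks, refs, mod_code),
       alignments = kept, audit = attr(kept, "audit"))
}

#' Write fraction records, KL records or outlier calls as TSV
#'
#' Plain TSV writers for the pipeline's tabular outputs.
#'
#' @param x a data.frame output of [site_fraction()], [call_sites()],
#'   [compare_samples()], [threshold_curve()], [call_outliers()] or
#'   [integrate_models()].
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
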