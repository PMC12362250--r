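#' Per-site modification fraction statistic
#'
#' For each site the fraction of reads whose prediction score strictly
#' exceeds `high_threshold` (default 204 = floor(255 * 0.80)), over a
#' denominator of either all matched reads (`"matched"`, the default:
#' matched-but-unscored reads count as unmodified, since their withheld
#' scores lie below the 5% emission threshold) or only reads with an emitted
#' score (`"scored"`). Sites with denominator below `min_coverage` are
#' skipped with a message.
#'
#' @param sites a `site_score_table` from [build_site_table()].
#' @param high_threshold high-confidence score threshold; counting is
#'   strictly greater-than.
#' @param denominator `"matched"` or `"scored"`.
#' @param min_coverage minimum denominator for a site to be reported.
#' @return data.frame (`fraction_records`) with columns `ref_id`,
#'   `body_pos`, `mod_code`, `n_high`, `n_total`, `fraction`.
#' @export
site_fraction <- function(sites, high_threshold = 204L,
                          denominator = c("matched", "scored"),
                          min_coverage = 20L) {
  denominator <- match.arg(denominator)
  n_total <- if (denominator == "matched") sites$n_matched else sites$n_scored
  n_high <- vapply(sites$scores, function(s)
    sum(s > high_threshold), integer(1))
  keep <- n_total >= max(1L, min_coverage)
  if (any(!keep))
    message(sum(!keep), " site(s) skipped: coverage below ", min_coverage)
  out <- data.frame(ref_id = sites$ref_id, body_pos = sites$body_pos,
                    mod_code = sites$mod_code, n_high = n_high,
                    n_total = n_total,
                    fraction = ifelse(n_total > 0, n_high / n_total, NA_real_),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "denominator") <- denominator
  attr(out, "high_threshold") <- high_threshold
  out
}

#' Binary de novo modification calls from site fractions
#'
#' A site is called modified when its fraction is greater than or equal to
#' `cutoff` (default 0.2, the operating point chosen from the
#' annotated-vs-non-annotated threshold curve).
#'
#' @param fractions output of [site_fraction()].
#' @param cutoff fraction cutoff; the boundary is inclusive (>=).
#' @return the input with a logical `call` column added.
#' @export
call_sites <- function(fractions, cutoff = 0.2) {
  fractions$call <- fractions$fraction >= cutoff
  fractions
}

#' Threshold-selection curve over annotated vs non-annotated sites
#'
#' For each candidate fraction cutoff, the percentage of annotated sites and
#' of non-annotated sites (for `mod_code`) whose fraction is >= the cutoff.
#' Both percentages are non-increasing in the cutoff; the curve is how the
#' default call cutoff of 0.2 is chosen.
#'
#' @param fractions output of [site_fraction()].
#' @param annotations an `annotation_table`.
#' @param mod_code modification code defining the annotated class.
#' @param grid cutoffs to evaluate.
#' @return data.frame with columns `cutoff`, `pct_annotated`,
#'   `pct_nonannotated` (percentages 0-100; NA when a class is empty).
#' @export
threshold_curve <- function(fractions, annotations, mod_code = "psi",
                            grid = seq(0, 1, by = 0.05)) {
  ann <- annotations[annotations$mod_code == mod_code &
                       !annotations$is_insertion, , drop = FALSE]
  key <- paste(fractions$ref_id, fractions$body_pos)
  is_ann <- key %in% paste(ann$ref_id, ann$position_num)
  n_ann <- sum(is_ann); n_non <- sum(!is_ann)
  data.frame(
    cutoff = grid,
    pct_annotated = vapply(grid, function(ct)
      if (n_ann == 0L) NA_real_ else
        100 * sum(fractions$fraction[is_ann] >= ct) / n_ann, numeric(1)),
    pct_nonannotated = vapply(grid, function(ct)
      if (n_non == 0L) NA_real_ else
        100 * sum(fractions$fraction[!is_ann] >= ct) / n_non, numeric(1))
  )
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie handling, equivalent
#' to the trapezoid rule over the empirical ROC and to the proportion of
#' positive/negative pairs ranked correctly (ties counting 1/2).
#'
#' @param scores numeric site-level scores.
#' @param labels logical (or 0/1) true-class labels; both classes must be
#'   non-empty.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be non-empty")
  r <- rank(scores) # midranks
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Export site fractions as a sites-by-tRNA matrix
#'
#' Plotting-ready wide matrix of fractions (rows = references, columns =
#' body positions), as used for per-tRNA modification-fraction maps.
#'
#' @param fractions output of [site_fraction()] or [call_sites()].
#' @return numeric matrix with NA at uncovered cells.
#' @export
fraction_matrix <- function(fractions) {
  refs <- sort(unique(fractions$ref_id))
  pos <- seq_len(max(fractions$body_pos))
  m <- matrix(NA_real_, length(refs), length(pos),
              dimnames = list(refs, pos))
  m[cbind(match(fractions$ref_id, refs), fractions$body_pos)] <-
    fractions$fraction
  m
}
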