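#' Alignment scoring scheme
#'
#' Affine-gap scoring for local alignment. A gap of length L scores
#' `gap_open + (L - 1) * gap_extend`; the open penalty covers the first
#' gapped base. The minimum-alignment-score filter cutoff (default 50 in
#' [filter_alignments()]) is relative to this scheme, so both are exposed
#' together in configuration.
#'
#' @param match match score (> 0).
#' @param mismatch,gap_open,gap_extend penalties (<= 0 by convention).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -1L, gap_open = -2L,
                           gap_extend = -1L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

OP_LEVELS <- c("match", "mismatch", "insertion", "deletion")

#' Optimal local alignment of one read against one reference
#'
#' Smith-Waterman-Gotoh local alignment with affine gaps and deterministic
#' tie-breaking (smallest reference end, then smallest read end; traceback
#' prefers diagonal). Returns the alignment score ("AS"), the per-base
#' pairing, and the spans on both sequences.
#'
#' @param read,ref non-empty sequences (character scalars, same alphabet;
#'   U is normalized to T).
#' @param scheme a [scoring_scheme()].
#' @param read_id,ref_id identifiers carried into the result.
#' @return A `read_alignment`: list with `read_id`, `ref_id`, `score`,
#'   `pairs` (data.frame `read_pos`, `ref_pos` — 0-based, NA for gaps — and
#'   `op` in match/mismatch/insertion/deletion), `read_span` and `ref_span`
#'   (0-based half-open), `read_len`, and `full_length` (set by
#'   [filter_alignments()]).
#' @export
local_align <- function(read, ref, scheme = scoring_scheme(),
                        read_id = "read", ref_id = "ref") {
  if (!nzchar(read) || !nzchar(ref)) stop("empty sequence")
  read <- normalize_seq(read); ref <- normalize_seq(ref)
  r <- sw_align_cpp(read, ref, scheme$match, scheme$mismatch,
                    scheme$gap_open, scheme$gap_extend)
  pairs <- data.frame(
    read_pos = ifelse(r$read_pos < 0L, NA_integer_, r$read_pos),
    ref_pos = ifelse(r$ref_pos < 0L, NA_integer_, r$ref_pos),
    op = OP_LEVELS[r$op + 1L],
    stringsAsFactors = FALSE
  )
  structure(list(read_id = read_id, ref_id = ref_id, score = r$score,
                 pairs = pairs,
                 read_span = c(r$read_start, r$read_end),
                 ref_span = c(r$ref_start, r$ref_end),
                 read_len = nchar(read),
                 full_length = NA, multi_ref = NA),
            class = "read_alignment")
}

#' Re-score an alignment's pair list under a scoring scheme
#'
#' Used to check the invariant that the reported AS equals the score implied
#' by the pairing.
#'
#' @param aln a `read_alignment`.
#' @param scheme a [scoring_scheme()].
#' @return integer score.
#' @export
rescore_alignment <- function(aln, scheme = scoring_scheme()) {
  ops <- aln$pairs$op
  s <- sum(ops == "match") * scheme$match +
    sum(ops == "mismatch") * scheme$mismatch
  gap <- ops %in% c("insertion", "deletion")
  if (any(gap)) {
    runs <- rle(gap)
    ng <- sum(runs$values)
    s <- s + ng * scheme$gap_open +
      (sum(runs$lengths[runs$values]) - ng) * scheme$gap_extend
  }
  as.integer(s)
}

as_reads <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    data.frame(read_id = as.character(reads$read_id),
               seq = as.character(reads$seq), stringsAsFactors = FALSE)
  } else {
    stopifnot(is.character(reads), !is.null(names(reads)))
    data.frame(read_id = names(reads), seq = unname(reads),
               stringsAsFactors = FALSE)
  }
}

#' All-against-all read-to-reference alignment
#'
#' Aligns every read against every reference. The result content is
#' independent of input order.
#'
#' @param reads named character vector (names = read ids) or data.frame with
#'   columns `read_id`, `seq`.
#' @param refs a [reference_set].
#' @param scheme a [scoring_scheme()].
#' @return An `alignment_set`: list of `read_alignment`, one per
#'   (read, reference) pair.
#' @export
align_all <- function(reads, refs, scheme = scoring_scheme()) {
  reads <- as_reads(reads)
  stopifnot(nrow(reads) >= 1L, nrow(refs) >= 1L)
  out <- vector("list", nrow(reads) * nrow(refs))
  k <- 1L
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(refs))) {
      out[[k]] <- local_align(reads$seq[i], refs$sequence[j], scheme,
                              read_id = reads$read_id[i],
                              ref_id = refs$ref_id[j])
      k <- k + 1L
    }
  }
  structure(out, class = "alignment_set")
}

#' @export
as.data.frame.alignment_set <- function(x, ...) {
  data.frame(
    read_id = vapply(x, `[[`, character(1), "read_id"),
    ref_id = vapply(x, `[[`, character(1), "ref_id"),
    AS = vapply(x, `[[`, integer(1), "score"),
    ref_start = vapply(x, function(a) a$ref_span[1], integer(1)),
    ref_end = vapply(x, function(a) a$ref_span[2], integer(1)),
    full_length = vapply(x, function(a) isTRUE(a$full_length), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Three-rule alignment filter
#'
#' Applies, in order: (i) per read, keep only the alignment(s) tied at that
#' read's maximal alignment score (reads tied on several references are
#' retained on all of them and flagged `multi_ref`); (ii) drop alignments
#' with AS below `min_as`; (iii) keep only full-length alignments, defined
#' as alignments whose reference span covers the entire tRNA body, with at
#' most `max_uncovered` uncovered body bases tolerated at each end
#' (default 0). The filter is idempotent and monotone in `min_as`.
#'
#' @param alns an `alignment_set` from [align_all()].
#' @param refs the [reference_set] the alignments were computed against
#'   (needed for body bounds).
#' @param min_as minimum alignment score; alignments with AS < `min_as` are
#'   excluded.
#' @param max_uncovered tolerated uncovered body bases at each end for the
#'   full-length rule.
#' @return An `alignment_set` containing the retained alignments, each with
#'   `full_length` and `multi_ref` filled in. The attribute `"audit"` holds
#'   a data.frame (read_id, ref_id, AS, rule_failed) recording every input
#'   alignment's fate ("" = retained).
#' @export
filter_alignments <- function(alns, refs, min_as = 50L, max_uncovered = 0L) {
  df <- as.data.frame.alignment_set(alns)
  i <- ref_row(refs, df$ref_id)
  body_start0 <- refs$adapter5_len[i]
  body_end0 <- refs$adapter5_len[i] + refs$body_len[i]
  full <- df$ref_start <= body_start0 + max_uncovered &
    df$ref_end >= body_end0 - max_uncovered
  best <- stats::ave(df$AS, df$read_id, FUN = max)
  rule <- character(nrow(df))
  rule[df$AS < best] <- "not_best_as"
  sel <- rule == "" & df$AS < min_as
  rule[sel] <- "as_below_min"
  sel <- rule == "" & !full
  rule[sel] <- "not_full_length"
  keep <- rule == ""
  kept <- alns[keep]
  nref <- table(df$read_id[keep])
  for (k in seq_along(kept)) {
    kept[[k]]$full_length <- full[keep][k]
    kept[[k]]$multi_ref <- nref[[kept[[k]]$read_id]] > 1L
  }
  audit <- data.frame(read_id = df$read_id, ref_id = df$ref_id, AS = df$AS,
                      rule_failed = rule, stringsAsFactors = FALSE)
  structure(kept, class = "alignment_set", audit = audit)
}
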