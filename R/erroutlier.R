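#' Load a per-position basecalling-error score table
#'
#' Parses the tabular output of an external error-profiling tool (one score
#' per reference position). Column names are configurable via `columns`.
#' Positions may be given on the full (adapter-flanked) sequence or already
#' on the tRNA body; full-sequence positions are converted to body
#' coordinates and adapter-region positions are excluded. Malformed rows
#' (non-numeric or negative scores, unknown references) are dropped with a
#' warning.
#'
#' @param tsv_path path to the TSV (with header).
#' @param refs a [reference_set] (required when `coords = "full"`).
#' @param columns named character vector mapping the roles `ref`, `pos`,
#'   `score` (and optionally `base`) to column names in the file.
#' @param coords `"body"` (positions already 1-based on the body) or
#'   `"full"` (1-based on the adapter-flanked sequence).
#' @return An `error_score_table`: data.frame with columns `ref_id`,
#'   `body_pos`, `canonical_base` (RNA; NA if absent), `score`.
#' @export
load_error_table <- function(tsv_path, refs = NULL,
                             columns = c(ref = "ref_id", pos = "position",
                                         score = "score"),
                             coords = c("body", "full")) {
  coords <- match.arg(coords)
  df <- utils::read.delim(tsv_path)
  need <- columns[c("ref", "pos", "score")]
  if (!all(need %in% names(df)))
    stop("error table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(ref_id = as.character(df[[columns[["ref"]]]]),
                    pos = suppressWarnings(as.integer(df[[columns[["pos"]]]])),
                    score = suppressWarnings(as.numeric(df[[columns[["score"]]]])),
                    stringsAsFactors = FALSE)
  out$canonical_base <- if ("base" %in% names(columns) &&
                            columns[["base"]] %in% names(df))
    as_rna_base(normalize_seq(as.character(df[[columns[["base"]]]])))
  else NA_character_
  bad <- is.na(out$pos) | !is.finite(out$score) | out$score < 0
  if (!is.null(refs)) bad <- bad | !(out$ref_id %in% refs$ref_id)
  if (coords == "full") {
    if (is.null(refs)) stop("full-sequence coordinates require `refs`")
    body <- rep(NA_integer_, nrow(out))
    ok <- !bad
    body[ok] <- full0_to_body(refs, out$ref_id[ok], out$pos[ok] - 1L)
    bad <- bad | is.na(body) # adapter-region positions excluded
    out$pos <- body
  } else if (!is.null(refs)) {
    bl <- refs$body_len[match(out$ref_id, refs$ref_id)]
    bad <- bad | is.na(bl) | out$pos < 1L | out$pos > bl
  }
  if (any(bad))
    warning(sum(bad), " row(s) dropped (malformed, unknown reference, or ",
            "outside the tRNA body)")
  out <- out[!bad, , drop = FALSE]
  if (nrow(out) == 0L) stop("no parseable rows in ", tsv_path)
  if (anyDuplicated(out[c("ref_id", "pos")]))
    stop("duplicate (ref_id, position) rows")
  out <- data.frame(ref_id = out$ref_id, body_pos = out$pos,
                    canonical_base = out$canonical_base, score = out$score,
                    stringsAsFactors = FALSE)
  class(out) <- c("error_score_table", "data.frame")
  out
}

#' Tukey's-fences outlier threshold
#'
#' Upper fence Q3 + k * IQR with k = 1.5 by default; quartiles use
#' linear-interpolation quantiles (stats::quantile type 7).
#'
#' @param scores numeric vector (>= 4 values).
#' @param k fence multiplier.
#' @return the threshold; values strictly greater are outliers.
#' @export
tukey_threshold <- function(scores, k = 1.5) {
  if (length(scores) < 4L) stop("need at least 4 scores")
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + k * (q[2] - q[1])
}

#' Call modification sites as error-score outliers
#'
#' A site is an outlier when its score strictly exceeds the Tukey fence of
#' the chosen score population (`scope = "global"` pools all positions of
#' all tRNAs; `"per_base"` computes one fence per canonical base identity).
#' Reported calls additionally require the score to pass the absolute floor
#' (>= `score_floor`, default 10, calibrated on the distribution of non-U
#' basecalling-error outliers).
#'
#' @param table an `error_score_table`.
#' @param k fence multiplier, see [tukey_threshold()].
#' @param score_floor absolute minimum score for a reported call (inclusive).
#' @param scope fence population: `"global"` or `"per_base"`.
#' @return data.frame (`outlier_calls`) with columns `ref_id`, `body_pos`,
#'   `score`, `threshold`, `is_outlier`, `passed_floor`, `call`. The scope
#'   used is recorded in the `"scope"` attribute.
#' @export
call_outliers <- function(table, k = 1.5, score_floor = 10,
                          scope = c("global", "per_base")) {
  scope <- match.arg(scope)
  stopifnot(nrow(table) > 0L)
  thr <- rep(NA_real_, nrow(table))
  if (scope == "global") {
    thr[] <- tukey_threshold(table$score, k)
  } else {
    if (anyNA(table$canonical_base))
      stop("per-base scope requires a canonical_base column")
    for (b in unique(table$canonical_base)) {
      sel <- table$canonical_base == b
      if (sum(sel) < 4L) stop("fewer than 4 scores for base ", b)
      thr[sel] <- tukey_threshold(table$score[sel], k)
    }
  }
  out <- data.frame(ref_id = table$ref_id, body_pos = table$body_pos,
                    score = table$score, threshold = thr,
                    is_outlier = table$score > thr,
                    passed_floor = table$score >= score_floor,
                    stringsAsFactors = FALSE)
  out$call <- out$is_outlier & out$passed_floor
  attr(out, "scope") <- scope
  out
}

#' Internal per-site basecalling-error score from alignments
#'
#' A self-contained, clearly non-equivalent stand-in for an external
#' error-profiling tool, provided so the outlier caller can be exercised
#' end-to-end on simulated data: for each body position, the absolute
#' difference between samples in the arcsine-square-root-stabilized
#' per-site error rate (mismatches + insertions + deletions over aligned
#' reads), scaled by 100. It does not reproduce any external tool's
#' statistic.
#'
#' @param alns_a,alns_b filtered `alignment_set`s for the two samples.
#' @param refs a [reference_set].
#' @return An `error_score_table`.
#' @export
error_score_from_alignments <- function(alns_a, alns_b, refs) {
  rate <- function(alns) {
    tot <- list(); err <- list()
    for (a in alns) {
      i <- ref_row(refs, a$ref_id)
      p <- a$pairs
      # deletions consume a ref position; insertions are charged to the
      # preceding aligned ref position
      refp <- p$ref_pos
      ins <- which(p$op == "insertion")
      for (j in ins) {
        prev <- p$ref_pos[seq_len(j - 1L)]
        refp[j] <- if (any(!is.na(prev))) max(prev, na.rm = TRUE) else NA
      }
      ok <- !is.na(refp)
      body <- full0_to_body(refs, a$ref_id, refp[ok])
      iserr <- p$op[ok] != "match"
      key <- paste(a$ref_id, body, sep = "\r")[!is.na(body)]
      iserr <- iserr[!is.na(body)]
      for (u in unique(key)) {
        tot[[u]] <- (if (is.null(tot[[u]])) 0L else tot[[u]]) + sum(key == u)
        err[[u]] <- (if (is.null(err[[u]])) 0L else err[[u]]) +
          sum(iserr[key == u])
      }
    }
    keys <- names(tot)
    data.frame(key = keys,
               rate = vapply(keys, function(u) err[[u]] / tot[[u]],
                             numeric(1)),
               stringsAsFactors = FALSE)
  }
  ra <- rate(alns_a); rb <- rate(alns_b)
  common <- intersect(ra$key, rb$key)
  va <- ra$rate[match(common, ra$key)]
  vb <- rb$rate[match(common, rb$key)]
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(
    ref_id = vapply(parts, `[`, character(1), 1),
    body_pos = as.integer(vapply(parts, `[`, character(1), 2)),
    canonical_base = NA_character_,
    score = 100 * abs(asin(sqrt(pmin(1, va))) - asin(sqrt(pmin(1, vb)))),
    stringsAsFactors = FALSE
  )
  out$canonical_base <- as_rna_base(
    ref_base_at_body(refs, out$ref_id, out$body_pos))
  out <- out[order(out$ref_id, out$body_pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("error_score_table", "data.frame")
  out
}
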