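#' Modification codes handled by the score extractor
#'
#' Maps short modification codes to the canonical base the caller scores and
#' to the code used in SAM base-modification (MM) tags: pseudouridine and
#' inosine use their ChEBI ids, N6-methyladenosine and 5-methylcytosine the
#' single-letter codes of the SAM tag specification.
#'
#' @format data.frame with columns `mod_code`, `canonical` (DNA alphabet),
#'   `sam_code`.
#' @export
MOD_CODES <- data.frame(
  mod_code = c("psi", "m6a", "m5c", "inosine"),
  canonical = c("T", "A", "C", "A"),
  sam_code = c("17802", "a", "m", "17596"),
  stringsAsFactors = FALSE
)

mod_info <- function(mod_code) {
  i <- match(mod_code, MOD_CODES$mod_code)
  if (is.na(i)) stop("unknown mod_code: ", mod_code,
                     " (known: ", paste(MOD_CODES$mod_code, collapse = ", "), ")")
  MOD_CODES[i, ]
}

#' Discretize a modification probability to the caller's integer score
#'
#' Modification callers emit per-read probabilities discretized to integers:
#' `floor(255 * p)`. The default emission threshold of 5% corresponds to a
#' score of 12, and the high-confidence threshold of 80% to 204.
#'
#' @param p probability (vectorized), in \[0, 1\].
#' @return integer score(s) in \[0, 255\].
#' @export
discretize_probability <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  as.integer(floor(255 * p))
}

#' Per-read modification score track
#'
#' @param read_id read identifier.
#' @param mod_code one of the codes in [MOD_CODES].
#' @param scores integer vector of emitted scores named by 0-based read
#'   position (sequencing orientation). May be empty.
#' @return A `read_score_track` list.
#' @export
read_score_track <- function(read_id, mod_code, scores = integer()) {
  if (length(scores)) {
    stopifnot(!is.null(names(scores)),
              all(scores >= 0L), all(scores <= 255L))
    scores <- scores[order(as.integer(names(scores)))]
  }
  structure(list(read_id = read_id, mod_code = mod_code,
                 scores = stats::setNames(as.integer(scores), names(scores))),
            class = "read_score_track")
}

#' Decode SAM base-modification (MM/ML) tags into a score track
#'
#' Resolves the MM skip counts against the occurrences of the model's
#' canonical base in the read (sequencing orientation), honoring both the
#' '?' (skipped bases carry no information) and '.'/implicit (skipped bases
#' are unmodified, i.e. no emitted score) semantics, and pairs the ML bytes
#' in order with the MM entries.
#'
#' @param seq read sequence (sequencing orientation).
#' @param mm MM tag value, e.g. `"T+17802?,1,0;"`.
#' @param ml integer vector of ML bytes for all MM entries, in order.
#' @param mod_code one of the codes in [MOD_CODES].
#' @param read_id identifier for the returned track.
#' @return A [read_score_track()]. Records without a matching MM entry give
#'   an empty track.
#' @export
decode_mod_tags <- function(seq, mm, ml, mod_code, read_id = "read") {
  info <- mod_info(mod_code)
  seq <- normalize_seq(seq)
  if (is.null(mm) || !nzchar(mm))
    return(read_score_track(read_id, mod_code))
  items <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1]]
  ml_off <- 0L
  for (item in items) {
    fields <- strsplit(item, ",", fixed = TRUE)[[1]]
    head <- fields[1]
    skips <- as.integer(fields[-1])
    m <- regmatches(head, regexec("^([A-Z])([-+])([A-Za-z0-9]+)([.?]?)$", head))[[1]]
    if (length(m) == 0L) stop("malformed MM item: ", item)
    base <- m[2]; codes <- m[4]
    n_entries <- length(skips)
    # multi-code items (e.g. "mh") carry one ML byte per code per position
    codes_list <- if (grepl("^[0-9]+$", codes)) codes else
      strsplit(codes, "")[[1]]
    n_bytes <- n_entries * length(codes_list)
    if (ml_off + n_bytes > length(ml)) stop("MM/ML length mismatch")
    if (base == normalize_seq(info$canonical) && info$sam_code %in% codes_list) {
      ci <- match(info$sam_code, codes_list)
      bytes <- ml[ml_off + (seq_len(n_entries) - 1L) * length(codes_list) + ci]
      occ <- which(strsplit(seq, "")[[1]] == base) - 1L # 0-based
      idx <- cumsum(skips + 1L)
      if (length(idx) && max(idx) > length(occ))
        stop("MM skip counts overrun canonical-base occurrences")
      pos <- occ[idx]
      return(read_score_track(read_id, mod_code,
                              stats::setNames(as.integer(bytes), pos)))
    }
    ml_off <- ml_off + n_bytes
  }
  if (ml_off != length(ml)) stop("MM/ML length mismatch")
  warning("no MM entry for mod code '", mod_code, "' in read ", read_id)
  read_score_track(read_id, mod_code)
}

#' Encode a score track as MM/ML tag values
#'
#' Inverse of [decode_mod_tags()], using '?' skip semantics (bases without
#' an emitted score carry no information), as modification callers do when
#' sub-threshold scores are withheld.
#'
#' @param seq read sequence (sequencing orientation).
#' @param track a [read_score_track()].
#' @return list with elements `mm` (MM tag string) and `ml` (integer vector).
#' @export
encode_mod_tags <- function(seq, track) {
  info <- mod_info(track$mod_code)
  seq <- normalize_seq(seq)
  base <- normalize_seq(info$canonical)
  occ <- which(strsplit(seq, "")[[1]] == base) - 1L
  pos <- as.integer(names(track$scores))
  if (length(pos) == 0L)
    return(list(mm = sprintf("%s+%s?;", base, info$sam_code), ml = integer()))
  idx <- match(pos, occ)
  if (anyNA(idx)) stop("scored position is not a canonical-base position")
  skips <- diff(c(0L, idx)) - 1L
  list(mm = sprintf("%s+%s?,%s;", base, info$sam_code,
                    paste(skips, collapse = ",")),
       ml = unname(track$scores))
}

#' Write / read modification-tagged reads as SAM text
#'
#' Minimal SAM text I/O for unaligned reads carrying MM/ML base-modification
#' tags, used to exchange simulator output and for round-trip testing.
#' Alignment is performed by this package, so reads are stored unmapped
#' (flag 4).
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param tracks list of [read_score_track()] keyed by read id.
#' @param path output SAM path.
#' @export
write_modsam <- function(reads, tracks, path) {
  reads <- as_reads(reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_len(nrow(reads))) {
    tr <- tracks[[reads$read_id[i]]]
    tags <- ""
    if (!is.null(tr)) {
      enc <- encode_mod_tags(reads$seq[i], tr)
      ml <- if (length(enc$ml))
        paste0("\tML:B:C,", paste(enc$ml, collapse = ",")) else "\tML:B:C"
      tags <- paste0("\tMM:Z:", enc$mm, ml)
    }
    writeLines(paste0(reads$read_id[i], "\t4\t*\t0\t0\t*\t*\t0\t0\t",
                      normalize_seq(reads$seq[i]), "\t*", tags), con)
  }
  invisible(path)
}

#' @rdname write_modsam
#' @param mod_code modification code to decode from the tags.
#' @return `read_modsam`: list with `reads` (data.frame `read_id`, `seq`) and
#'   `tracks` (list of score tracks keyed by read id).
#' @export
read_modsam <- function(path, mod_code) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  reads <- data.frame(read_id = character(), seq = character(),
                      stringsAsFactors = FALSE)
  tracks <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rid <- f[1]; seq <- f[10]
    reads <- rbind(reads, data.frame(read_id = rid, seq = seq,
                                     stringsAsFactors = FALSE))
    mm <- sub("^MM:Z:", "", grep("^MM:Z:", f, value = TRUE))
    mlf <- sub("^ML:B:C,?", "", grep("^ML:B:C", f, value = TRUE))
    if (length(mm)) {
      ml <- if (length(mlf) && nzchar(mlf))
        as.integer(strsplit(mlf, ",", fixed = TRUE)[[1]]) else integer()
      tracks[[rid]] <- decode_mod_tags(seq, mm, ml, mod_code, read_id = rid)
    } else {
      tracks[[rid]] <- read_score_track(rid, mod_code)
    }
  }
  list(reads = reads, tracks = tracks)
}

#' Read a tag-free score sidecar TSV
#'
#' Alternative to MM/ML tags: a TSV with columns `read_id`, `read_pos`
#' (0-based), `mod_code`, `score`.
#'
#' @param path TSV path.
#' @param mod_code modification code to extract.
#' @return list of [read_score_track()] keyed by read id.
#' @export
read_score_sidecar <- function(path, mod_code) {
  df <- utils::read.delim(path)
  df <- df[df$mod_code == mod_code, , drop = FALSE]
  lapply(split(df, df$read_id), function(d)
    read_score_track(d$read_id[1], mod_code,
                     stats::setNames(as.integer(d$score), d$read_pos)))
}

#' Project a read's scores onto reference body coordinates
#'
#' For each aligned pair that is a sequence match at a position whose
#' reference base is the model's canonical base and that lies within the
#' tRNA body, the position is counted as matched; if the read carries an
#' emitted score there, the score is recorded. Mismatches, insertions and
#' deletions contribute nothing (a mismatched position has no prediction
#' score for the reference canonical base).
#'
#' @param aln a filtered `read_alignment`.
#' @param track the same read's [read_score_track()].
#' @param refs a [reference_set].
#' @return data.frame with columns `ref_id`, `body_pos`, `score` (NA when
#'   matched but no emitted score); one row per matched canonical-base body
#'   position.
#' @export
project_scores <- function(aln, track, refs) {
  if (!is.null(track) && track$read_id != aln$read_id)
    stop("track/alignment read id mismatch")
  if (!is.null(track) && length(track$scores) &&
      max(as.integer(names(track$scores))) >= aln$read_len)
    stop("score track addresses positions beyond the read length")
  info <- mod_info(if (is.null(track)) "psi" else track$mod_code)
  i <- ref_row(refs, aln$ref_id)
  refchars <- strsplit(refs$sequence[i], "")[[1]]
  p <- aln$pairs
  sel <- p$op == "match" & !is.na(p$ref_pos) &
    refchars[p$ref_pos + 1L] == info$canonical
  if (!any(sel))
    return(data.frame(ref_id = character(), body_pos = integer(),
                      score = integer(), stringsAsFactors = FALSE))
  ref_pos <- p$ref_pos[sel]
  read_pos <- p$read_pos[sel]
  body <- full0_to_body(refs, aln$ref_id, ref_pos)
  keep <- !is.na(body)
  sc <- rep(NA_integer_, sum(keep))
  if (!is.null(track) && length(track$scores)) {
    m <- match(as.character(read_pos[keep]), names(track$scores))
    sc[!is.na(m)] <- unname(track$scores[m[!is.na(m)]])
  }
  data.frame(ref_id = aln$ref_id, body_pos = body[keep], score = sc,
             stringsAsFactors = FALSE)
}

#' Aggregate per-read score projections into a per-site score table
#'
#' Builds, for one modification model, the per (reference, body position)
#' multiset of emitted per-read scores together with `n_matched` (filtered
#' reads with a sequence match at the position) and `n_scored` (those with
#' an emitted score). Per-site score lists are stored sorted so the table is
#' invariant under read input order. The attribute `"ref_coverage"` records
#' the number of retained read-reference alignments per reference (the
#' per-tRNA coverage used for gating in [compare_samples()]).
#'
#' @param alns a filtered `alignment_set`.
#' @param tracks list of [read_score_track()] keyed by read id (reads
#'   without a track contribute matched-but-unscored positions).
#' @param refs a [reference_set].
#' @param mod_code modification code of the tracks.
#' @return A `site_score_table`: data.frame with columns `ref_id`,
#'   `body_pos`, `mod_code`, `n_matched`, `n_scored` and a list-column
#'   `scores` of sorted integer vectors.
#' @export
build_site_table <- function(alns, tracks, refs, mod_code = "psi") {
  contrib <- lapply(alns, function(a)
    project_scores(a, tracks[[a$read_id]], refs))
  df <- do.call(rbind, contrib)
  cov <- integer(0)
  if (length(alns)) {
    tab <- table(vapply(alns, `[[`, character(1), "ref_id"))
    cov <- stats::setNames(as.integer(tab), names(tab))
  }
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(ref_id = character(), body_pos = integer(),
                      mod_code = character(), n_matched = integer(),
                      n_scored = integer(), stringsAsFactors = FALSE)
    out$scores <- list()
  } else {
    key <- paste(df$ref_id, df$body_pos, sep = "\r")
    sp <- split(df, key)
    out <- do.call(rbind, lapply(sp, function(d) {
      s <- sort(d$score[!is.na(d$score)])
      r <- data.frame(ref_id = d$ref_id[1], body_pos = d$body_pos[1],
                      mod_code = mod_code, n_matched = nrow(d),
                      n_scored = length(s), stringsAsFactors = FALSE)
      r$scores <- list(as.integer(s))
      r
    }))
    out <- out[order(out$ref_id, out$body_pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "ref_coverage") <- cov
  class(out) <- c("site_score_table", "data.frame")
  out
}

new_site_table <- function(df, ref_coverage) {
  df <- df[order(df$ref_id, df$body_pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "ref_coverage") <- ref_coverage
  class(df) <- c("site_score_table", "data.frame")
  df
}

#' Write / read a site score table as TSV
#'
#' Scores are comma-joined; per-reference coverage is stored in `#coverage`
#' header comment lines so the table round-trips.
#'
#' @param x a `site_score_table`.
#' @param path TSV path.
#' @export
write_site_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cov <- attr(x, "ref_coverage")
  for (r in names(cov))
    writeLines(sprintf("#coverage\t%s\t%d", r, cov[[r]]), con)
  writeLines("ref_id\tbody_pos\tmod_code\tn_matched\tn_scored\tscores", con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(x$ref_id[i], x$body_pos[i], x$mod_code[i],
                     x$n_matched[i], x$n_scored[i],
                     paste(x$scores[[i]], collapse = ","), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  lines <- readLines(path)
  covlines <- grep("^#coverage\t", lines, value = TRUE)
  cov <- integer(0)
  if (length(covlines)) {
    parts <- strsplit(covlines, "\t", fixed = TRUE)
    cov <- stats::setNames(vapply(parts, function(p) as.integer(p[3]),
                                  integer(1)),
                           vapply(parts, `[`, character(1), 2))
  }
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1L) {
    df <- data.frame(ref_id = character(), body_pos = integer(),
                     mod_code = character(), n_matched = integer(),
                     n_scored = integer(), stringsAsFactors = FALSE)
    df$scores <- list()
    return(new_site_table(df, cov))
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  df <- data.frame(
    ref_id = vapply(rows, `[`, character(1), 1),
    body_pos = as.integer(vapply(rows, `[`, character(1), 2)),
    mod_code = vapply(rows, `[`, character(1), 3),
    n_matched = as.integer(vapply(rows, `[`, character(1), 4)),
    n_scored = as.integer(vapply(rows, `[`, character(1), 5)),
    stringsAsFactors = FALSE
  )
  df$scores <- lapply(rows, function(r)
    if (length(r) < 6L || !nzchar(r[6])) integer() else
      as.integer(strsplit(r[6], ",", fixed = TRUE)[[1]]))
  new_site_table(df, cov)
}
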