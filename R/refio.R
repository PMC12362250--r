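#' Reference sets of adapter-flanked mature tRNAs
#'
#' A `reference_set` holds mature tRNA body sequences with 5'/3' splint
#' adapter sequences attached, exactly as they are presented to the aligner.
#' Sequences are stored internally in the DNA alphabet (U is normalized to
#' T); single-base columns in exported tables are reported as RNA (U).
#'
#' Coordinate conventions used throughout the package:
#' * body positions are 1-based and inclusive on the mature tRNA body,
#'   i.e. excluding the adapters — this is the coordinate reported in all
#'   outputs;
#' * internal full-sequence coordinates (alignment spans, pair lists) are
#'   0-based, half-open.
#'
#' @param ref_id character vector of unique reference identifiers.
#' @param body character vector of mature tRNA body sequences (A/C/G/T/U).
#' @param adapter5,adapter3 single 5' and 3' splint adapter sequences,
#'   attached to every body. May be empty strings.
#' @return An object of class `reference_set`: a data.frame with columns
#'   `ref_id`, `sequence` (full adapter5+body+adapter3, DNA alphabet),
#'   `adapter5_len`, `adapter3_len`, `body_len`.
#' @export
reference_set <- function(ref_id, body, adapter5 = "", adapter3 = "") {
  stopifnot(length(ref_id) == length(body), length(adapter5) == 1L,
            length(adapter3) == 1L)
  if (anyDuplicated(ref_id))
    stop("duplicate reference ids: ",
         paste(unique(ref_id[duplicated(ref_id)]), collapse = ", "))
  adapter5 <- normalize_seq(adapter5)
  adapter3 <- normalize_seq(adapter3)
  body <- vapply(body, normalize_seq, character(1), USE.NAMES = FALSE)
  bad <- !grepl("^[ACGT]*$", body) | nchar(body) == 0L
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected (empty or non-ACGU characters): ",
            paste(ref_id[bad], collapse = ", "))
    ref_id <- ref_id[!bad]; body <- body[!bad]
  }
  if (length(body) == 0L) stop("no valid reference records")
  if (anyDuplicated(body))
    warning("duplicate sequences under distinct ids: ",
            paste(ref_id[duplicated(body) | duplicated(body, fromLast = TRUE)],
                  collapse = ", "))
  out <- data.frame(
    ref_id = as.character(ref_id),
    sequence = paste0(adapter5, body, adapter3),
    adapter5_len = nchar(adapter5),
    adapter3_len = nchar(adapter3),
    body_len = nchar(body),
    stringsAsFactors = FALSE
  )
  attr(out, "adapter5") <- adapter5
  attr(out, "adapter3") <- adapter3
  class(out) <- c("reference_set", "data.frame")
  out
}

normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Load mature tRNA bodies from FASTA and attach splint adapters
#'
#' Reads body sequences (without adapters) from a FASTA file and returns the
#' adapter-flanked reference set. U and T are both accepted and normalized
#' to the DNA alphabet; records containing other characters are rejected
#' with a warning. The adapter sequences are experiment-specific inputs and
#' are never assumed by the package.
#'
#' @param fasta_path path to a FASTA file of mature tRNA bodies.
#' @inheritParams reference_set
#' @return A [reference_set].
#' @export
load_references <- function(fasta_path, adapter5 = "", adapter3 = "") {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  reference_set(ids, as.character(seqs), adapter5 = adapter5,
                adapter3 = adapter3)
}

#' Write the mature tRNA bodies of a reference set to FASTA
#'
#' Writes the body sequences (adapters stripped), so that reloading with
#' [load_references()] and the same adapters round-trips the set.
#'
#' @param refs a [reference_set].
#' @param path output FASTA path.
#' @export
write_references <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  bodies <- Biostrings::DNAStringSet(body_seq(refs, refs$ref_id))
  names(bodies) <- refs$ref_id
  Biostrings::writeXStringSet(bodies, path)
  invisible(path)
}

ref_row <- function(refs, ref_id) {
  i <- match(ref_id, refs$ref_id)
  if (anyNA(i)) stop("unknown reference id(s): ",
                     paste(ref_id[is.na(i)], collapse = ", "))
  i
}

#' Body sequence and coordinate helpers
#'
#' `body_seq` extracts the mature body sequence (adapters stripped);
#' `body_bounds` returns the 1-based inclusive full-sequence interval the
#' body occupies; `body_to_full0` and `full0_to_body` convert between
#' 1-based body positions and 0-based full-sequence positions.
#'
#' @param refs a [reference_set].
#' @param ref_id reference identifier(s).
#' @param body_pos 1-based body position(s).
#' @param full0 0-based full-sequence position(s).
#' @return `body_seq`: character; `body_bounds`: integer matrix with columns
#'   `start`, `end`; converters: integer positions (`full0_to_body` returns
#'   NA for positions inside the adapters).
#' @export
body_seq <- function(refs, ref_id) {
  i <- ref_row(refs, ref_id)
  substr(refs$sequence[i], refs$adapter5_len[i] + 1L,
         refs$adapter5_len[i] + refs$body_len[i])
}

#' @rdname body_seq
#' @export
body_bounds <- function(refs, ref_id) {
  i <- ref_row(refs, ref_id)
  cbind(start = refs$adapter5_len[i] + 1L,
        end = refs$adapter5_len[i] + refs$body_len[i])
}

#' @rdname body_seq
#' @export
body_to_full0 <- function(refs, ref_id, body_pos) {
  i <- ref_row(refs, ref_id)
  stopifnot(all(body_pos >= 1L), all(body_pos <= refs$body_len[i]))
  refs$adapter5_len[i] + as.integer(body_pos) - 1L
}

#' @rdname body_seq
#' @export
full0_to_body <- function(refs, ref_id, full0) {
  i <- ref_row(refs, ref_id)
  p <- as.integer(full0) - refs$adapter5_len[i] + 1L
  p[p < 1L | p > refs$body_len[i]] <- NA_integer_
  p
}

ref_base_at_body <- function(refs, ref_id, body_pos) {
  i <- ref_row(refs, ref_id)
  full <- refs$adapter5_len[i] + as.integer(body_pos)
  substr(refs$sequence[i], full, full)
}

as_rna_base <- function(b) ifelse(b == "T", "U", b)

#' Load a modification-site annotation table
#'
#' Reads a TSV with header columns `ref_id`, `position`, `mod_code` and an
#' optional `canonical_base`. Positions are 1-based on the tRNA body.
#' Insertion labels such as "20.1" (positions inserted relative to canonical
#' tRNA numbering) are retained as opaque labels and flagged; they are
#' excluded from coordinate arithmetic. Rows whose position falls outside
#' the body, whose reference is unknown, or whose canonical base disagrees
#' with the reference are rejected with a warning.
#'
#' @param tsv_path path to the annotation TSV.
#' @param refs a [reference_set] the rows are validated against.
#' @return An `annotation_table`: data.frame with columns `ref_id`,
#'   `position` (character, as given), `position_num` (integer, NA for
#'   insertion labels), `mod_code`, `canonical_base` (RNA alphabet),
#'   `is_insertion`.
#' @export
load_annotations <- function(tsv_path, refs) {
  df <- utils::read.delim(tsv_path, colClasses = "character")
  need <- c("ref_id", "position", "mod_code")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have header columns: ",
         paste(need, collapse = ", "))
  annotation_table(df, refs)
}

#' @rdname load_annotations
#' @param df data.frame with columns `ref_id`, `position`, `mod_code` and
#'   optionally `canonical_base` (for in-memory construction).
#' @export
annotation_table <- function(df, refs) {
  df$ref_id <- as.character(df$ref_id)
  df$position <- as.character(df$position)
  df$mod_code <- as.character(df$mod_code)
  df$is_insertion <- !grepl("^[0-9]+$", df$position)
  df$position_num <- ifelse(df$is_insertion, NA_integer_,
                            suppressWarnings(as.integer(df$position)))
  keep <- rep(TRUE, nrow(df))
  known <- df$ref_id %in% refs$ref_id
  keep[!known] <- FALSE
  bl <- rep(NA_integer_, nrow(df))
  bl[known] <- refs$body_len[match(df$ref_id[known], refs$ref_id)]
  oob <- !df$is_insertion & known &
    (df$position_num < 1L | df$position_num > bl)
  keep[oob] <- FALSE
  if ("canonical_base" %in% names(df)) {
    df$canonical_base <- normalize_seq(df$canonical_base)
    chk <- keep & !df$is_insertion & nzchar(df$canonical_base)
    if (any(chk)) {
      actual <- ref_base_at_body(refs, df$ref_id[chk], df$position_num[chk])
      bad <- df$canonical_base[chk] != actual
      keep[chk][bad] <- FALSE
    }
  } else {
    df$canonical_base <- NA_character_
  }
  fill <- keep & !df$is_insertion &
    (is.na(df$canonical_base) | !nzchar(df$canonical_base))
  if (any(fill))
    df$canonical_base[fill] <-
      ref_base_at_body(refs, df$ref_id[fill], df$position_num[fill])
  if (any(!keep))
    warning(sum(!keep), " annotation row(s) rejected ",
            "(unknown reference, out-of-body position, or base mismatch)")
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df[c("ref_id", "position", "mod_code")]))
    stop("duplicate (ref_id, position) pairs for the same mod_code")
  df$canonical_base <- as_rna_base(df$canonical_base)
  out <- df[c("ref_id", "position", "position_num", "mod_code",
              "canonical_base", "is_insertion")]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}
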