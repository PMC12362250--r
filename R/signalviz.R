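#' Segment a raw signal by the basecaller move table
#'
#' The move table assigns each basecalled nucleotide a contiguous block of
#' raw signal samples; the basecalling model emits one move entry per
#' `stride` samples, so every per-base segment length is a positive multiple
#' of `stride` (6 for the direct-RNA model used here). Inconsistent totals
#' (signal length not equal to `stride` times the move-table length) are an
#' error.
#'
#' @param moves integer 0/1 vector, one entry per stride block; 1 marks the
#'   first block of a new base. The first entry must be 1.
#' @param signal numeric raw signal.
#' @param stride samples per move entry.
#' @param read_id identifier carried into the result.
#' @return A `move_segmentation`: list with `read_id`, `stride`, and
#'   `segments`, a data.frame (`base_index`, `start`, `end`) of 1-based
#'   inclusive signal index ranges, one row per basecalled position.
#' @export
segment_signal <- function(moves, signal, stride = 6L, read_id = "read") {
  moves <- as.integer(moves)
  if (length(signal) != length(moves) * stride)
    stop("signal length (", length(signal), ") is not stride (", stride,
         ") times the move-table length (", length(moves), ")")
  if (!all(moves %in% c(0L, 1L)) || moves[1] != 1L)
    stop("move table must be 0/1 with a leading 1")
  starts <- (which(moves == 1L) - 1L) * stride + 1L
  ends <- c(starts[-1] - 1L, length(signal))
  structure(list(read_id = read_id, stride = stride,
                 segments = data.frame(base_index = seq_along(starts),
                                       start = starts, end = ends)),
            class = "move_segmentation")
}

#' Moves vector from per-base segment lengths (inverse of segmentation)
#'
#' @param lengths per-base segment lengths (positive multiples of `stride`).
#' @param stride samples per move entry.
#' @return integer 0/1 move vector.
#' @export
moves_from_lengths <- function(lengths, stride = 6L) {
  if (any(lengths <= 0L) || any(lengths %% stride != 0L))
    stop("segment lengths must be positive multiples of ", stride)
  unlist(lapply(lengths / stride, function(k) c(1L, rep(0L, k - 1L))))
}

#' Equally spaced six-point subsample of a per-base signal segment
#'
#' Signals are variable in length (dwell time); each per-base segment of
#' length L (a positive multiple of 6) is reduced to the six values at
#' indices floor(i * L / 6) for i = 0..5 (one value per L/6 block), so a
#' length-6 segment is returned unchanged.
#'
#' @param segment numeric vector, length a positive multiple of 6.
#' @return numeric vector of length 6.
#' @export
subsample_six <- function(segment) {
  L <- length(segment)
  if (L <= 0L || L %% 6L != 0L)
    stop("segment length must be a positive multiple of 6")
  segment[floor((0:5) * L / 6) + 1L]
}

#' Per-position signal track restricted to aligned reference positions
#'
#' Extracts, for every read, the six-point subsampled signal of each
#' basecalled position that is aligned to a reference position (matches and
#' mismatches; insertions are dropped, and reference positions deleted from
#' a read are absent for that read), keyed by tRNA body position. Reads
#' lacking a segmentation or signal are skipped with a message.
#'
#' @param alns a filtered `alignment_set`.
#' @param segmentations list of [segment_signal()] results keyed by read id.
#' @param signals list of numeric signal vectors keyed by read id.
#' @param refs a [reference_set].
#' @return A `signal_track`: data.frame with columns `ref_id`, `body_pos`,
#'   `read_id`, `v1`..`v6`; the attribute `"summary"` holds per-position
#'   `median` and `sd` over all subsampled values.
#' @export
build_signal_track <- function(alns, segmentations, signals, refs) {
  rows <- list()
  for (a in alns) {
    seg <- segmentations[[a$read_id]]
    sig <- signals[[a$read_id]]
    if (is.null(seg) || is.null(sig)) {
      message("read ", a$read_id, " skipped: missing segmentation or signal")
      next
    }
    p <- a$pairs
    sel <- p$op %in% c("match", "mismatch")
    body <- full0_to_body(refs, a$ref_id, p$ref_pos[sel])
    read_pos <- p$read_pos[sel]
    ok <- !is.na(body) & (read_pos + 1L) <= nrow(seg$segments)
    for (j in which(ok)) {
      s <- seg$segments[read_pos[j] + 1L, ]
      six <- subsample_six(sig[s$start:s$end])
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = a$ref_id, body_pos = body[j], read_id = a$read_id,
        v1 = six[1], v2 = six[2], v3 = six[3], v4 = six[4], v5 = six[5],
        v6 = six[6], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_id = character(), body_pos = integer(),
               read_id = character(), v1 = numeric(), v2 = numeric(),
               v3 = numeric(), v4 = numeric(), v5 = numeric(),
               v6 = numeric(), stringsAsFactors = FALSE)
  key <- paste(out$ref_id, out$body_pos, sep = "\r")
  summ <- do.call(rbind, lapply(unique(key), function(u) {
    d <- out[key == u, , drop = FALSE]
    vals <- unlist(d[paste0("v", 1:6)], use.names = FALSE)
    data.frame(ref_id = d$ref_id[1], body_pos = d$body_pos[1],
               n_reads = nrow(d), median = stats::median(vals),
               sd = stats::sd(vals), stringsAsFactors = FALSE)
  }))
  if (is.null(summ))
    summ <- data.frame(ref_id = character(), body_pos = integer(),
                       n_reads = integer(), median = numeric(),
                       sd = numeric(), stringsAsFactors = FALSE)
  summ <- summ[order(summ$ref_id, summ$body_pos), , drop = FALSE]
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  class(out) <- c("signal_track", "data.frame")
  out
}

#' Vertical shift between two samples' signal tracks
#'
#' Offset-corrects intrinsic signal differences between samples: per tRNA,
#' the median over common covered positions of the difference in per-position
#' median signal (sample A minus sample B). The convention is A = wt,
#' B = mutant, and the returned shift is added to the mutant's signals for
#' display; the roles are explicit arguments, never inferred.
#'
#' @param track_a,track_b `signal_track`s (see [build_signal_track()]).
#' @return named numeric vector, one shift per tRNA common to both tracks.
#' @export
vertical_shift <- function(track_a, track_b) {
  sa <- attr(track_a, "summary"); sb <- attr(track_b, "summary")
  key_a <- paste(sa$ref_id, sa$body_pos, sep = "\r")
  key_b <- paste(sb$ref_id, sb$body_pos, sep = "\r")
  common <- intersect(key_a, key_b)
  if (length(common) == 0L) stop("no common covered positions")
  ia <- match(common, key_a); ib <- match(common, key_b)
  diffs <- sa$median[ia] - sb$median[ib]
  refs <- sa$ref_id[ia]
  vapply(split(diffs, refs), stats::median, numeric(1))
}

#' Write / read signal bundles as TSV sidecars
#'
#' Dependency-light exchange format for raw signals plus move tables: one
#' row per read with the comma-joined signal values and move entries.
#'
#' @param bundle list keyed by read id, each element a list with `signal`
#'   (numeric) and `moves` (0/1 integer vector).
#' @param path TSV path.
#' @export
write_signal_sidecar <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("read_id\tsignal\tmoves", con)
  for (rid in names(bundle))
    writeLines(paste(rid,
                     paste(format(bundle[[rid]]$signal, trim = TRUE,
                                  digits = 10), collapse = ","),
                     paste(bundle[[rid]]$moves, collapse = ","),
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signal_sidecar
#' @export
read_signal_sidecar <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i)
    list(signal = as.numeric(strsplit(df$signal[i], ",", fixed = TRUE)[[1]]),
         moves = as.integer(strsplit(df$moves[i], ",", fixed = TRUE)[[1]])))
  names(out) <- df$read_id
  out
}
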