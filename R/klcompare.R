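#' Smoothed per-site score histogram
#'
#' Discretized prediction scores take integer values in \[12, 255\] and are
#' smoothed by binning into `n_bins` equal-width half-open bins spanning
#' \[`lo`, `hi`) (defaults: 10 bins over \[11, 256), width 24.5) and adding a
#' pseudocount to every bin before normalization, so every bin probability
#' is strictly positive and the Kullback-Leibler divergence stays finite.
#'
#' @param scores integer scores, all within \[`lo`, `hi`); must be non-empty
#'   (gate coverage before calling).
#' @param n_bins number of bins (>= 2).
#' @param lo,hi histogram support.
#' @param pseudocount additive smoothing per bin (> 0).
#' @return A `score_histogram`: list with `bin_edges` (length `n_bins` + 1),
#'   `counts` and `probs` (`probs = (counts + pseudocount) /
#'   (sum(counts) + n_bins * pseudocount)`).
#' @export
smooth_histogram <- function(scores, n_bins = 10L, lo = 11, hi = 256,
                             pseudocount = 1) {
  if (length(scores) == 0L) stop("empty score list")
  stopifnot(n_bins >= 2L, pseudocount > 0)
  if (any(scores < lo) || any(scores >= hi))
    stop("scores outside histogram support [", lo, ", ", hi, ")")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(scores, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  probs <- (counts + pseudocount) / (sum(counts) + n_bins * pseudocount)
  structure(list(bin_edges = edges, counts = counts, probs = probs),
            class = "score_histogram")
}

as_probs <- function(x) {
  if (inherits(x, "score_histogram")) x <- x$probs
  x <- as.numeric(x)
  if (any(x <= 0)) stop("probabilities must be strictly positive")
  if (abs(sum(x) - 1) > 1e-8) stop("probabilities must sum to 1")
  x
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' `kl_divergence` computes D(P||Q) = sum P(x) log(P(x)/Q(x)) in natural
#' log units (nats); `symmetric_kl` returns D(P||Q) + D(Q||P), the
#' order-free statistic used to compare per-site score distributions between
#' samples. Inputs must be strictly positive (guaranteed by
#' [smooth_histogram()] smoothing) and of equal length.
#'
#' @param P,Q probability vectors or `score_histogram` objects.
#' @return non-negative divergence in nats; 0 exactly when P = Q.
#' @export
kl_divergence <- function(P, Q) {
  p <- as_probs(P); q <- as_probs(Q)
  if (length(p) != length(q)) stop("length mismatch")
  sum(p * log(p / q))
}

#' @rdname kl_divergence
#' @export
symmetric_kl <- function(P, Q) {
  kl_divergence(P, Q) + kl_divergence(Q, P)
}

cov_of <- function(tab, ref) {
  cov <- attr(tab, "ref_coverage")
  if (is.null(cov) || is.na(match(ref, names(cov)))) 0L else cov[[ref]]
}

#' Compare per-site score distributions between two samples
#'
#' The core sample-comparison statistic: for every site present in both
#' samples on a tRNA where both samples have at least `min_coverage`
#' filtered reads (coverage is gated per tRNA per sample), the symmetric KL
#' divergence between the two smoothed per-site score histograms. Sites on
#' tRNAs failing the coverage gate, or with no emitted scores in one sample,
#' are emitted with `passed_coverage = FALSE` and no divergence.
#'
#' @param table_a,table_b `site_score_table`s for the two samples
#'   (conventionally wt and mutant/IVT), built against the same references
#'   and modification model.
#' @param min_coverage minimum filtered reads per tRNA per sample.
#' @param n_bins,lo,hi,pseudocount histogram parameters, see
#'   [smooth_histogram()].
#' @return data.frame (`kl_records`) with columns `ref_id`, `body_pos`,
#'   `mod_code`, `cov_a`, `cov_b`, `passed_coverage`, `d_pq`, `d_qp`,
#'   `sym_kl` (NA when not passed).
#' @export
compare_samples <- function(table_a, table_b, min_coverage = 100L,
                            n_bins = 10L, lo = 11, hi = 256,
                            pseudocount = 1) {
  if (!identical(unique(table_a$mod_code), unique(table_b$mod_code)))
    stop("tables were built with different modification models")
  key_a <- paste(table_a$ref_id, table_a$body_pos, sep = "\r")
  key_b <- paste(table_b$ref_id, table_b$body_pos, sep = "\r")
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  n <- length(common)
  out <- data.frame(
    ref_id = table_a$ref_id[ia], body_pos = table_a$body_pos[ia],
    mod_code = table_a$mod_code[ia],
    cov_a = vapply(table_a$ref_id[ia], cov_of, integer(1), tab = table_a),
    cov_b = vapply(table_a$ref_id[ia], cov_of, integer(1), tab = table_b),
    stringsAsFactors = FALSE
  )
  out$passed_coverage <- out$cov_a >= min_coverage &
    out$cov_b >= min_coverage &
    table_a$n_scored[ia] >= 1L & table_b$n_scored[ib] >= 1L
  out$d_pq <- NA_real_; out$d_qp <- NA_real_; out$sym_kl <- NA_real_
  for (k in seq_len(n)) {
    if (!out$passed_coverage[k]) next
    P <- smooth_histogram(table_a$scores[[ia[k]]], n_bins, lo, hi, pseudocount)
    Q <- smooth_histogram(table_b$scores[[ib[k]]], n_bins, lo, hi, pseudocount)
    out$d_pq[k] <- kl_divergence(P, Q)
    out$d_qp[k] <- kl_divergence(Q, P)
    out$sym_kl[k] <- out$d_pq[k] + out$d_qp[k]
  }
  out <- out[order(out$ref_id, out$body_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Min-max normalization within groups
#'
#' Rescales values to \[0, 1\] as (x - min)/(max - min) within each group,
#' for cross-panel comparison of divergence scores. Constant groups give all
#' zeros with a warning. NA values are ignored for the range and propagated.
#'
#' @param values numeric vector.
#' @param group optional grouping vector (one group when NULL).
#' @return numeric vector in \[0, 1\].
#' @export
min_max_normalize <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(values))
  out <- rep(NA_real_, length(values))
  for (g in unique(group[!is.na(group)])) {
    sel <- !is.na(group) & group == g & !is.na(values)
    if (!any(sel)) next
    rng <- range(values[sel])
    if (rng[1] == rng[2]) {
      warning("constant group '", g, "': normalized to 0")
      out[sel] <- 0
    } else {
      out[sel] <- (values[sel] - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Integrate per-model divergence records into a modification map
#'
#' Builds the per-tRNA, per-position map by assigning to each body position
#' the symmetric KL divergence of the model matching its canonical base:
#' the pseudouridine model at U positions, the m6A model at A positions,
#' the m5C model at C positions. G positions carry no score (no G-targeting
#' model exists). Divergences are min-max normalized, by default per model
#' across all mapped sites; annotations and fraction calls are joined when
#' provided.
#'
#' @param kl_by_model named list `mod_code -> kl_records` (from
#'   [compare_samples()]), all computed against the same sample pair.
#' @param refs a [reference_set].
#' @param annotations optional `annotation_table`.
#' @param fractions optional output of [call_sites()] for the on-label model.
#' @param normalize `"per_model"` (default) or `"per_trna"` grouping for the
#'   min-max normalization.
#' @return A `modification_map`: data.frame with columns `ref_id`,
#'   `body_pos`, `base` (RNA alphabet), `model`, `sym_kl`, `sym_kl_norm`,
#'   `annotation`, `fraction`, `call`.
#' @export
integrate_models <- function(kl_by_model, refs, annotations = NULL,
                             fractions = NULL,
                             normalize = c("per_model", "per_trna")) {
  normalize <- match.arg(normalize)
  base_model <- c(T = "psi", A = "m6a", C = "m5c")
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    b <- strsplit(body_seq(refs, refs$ref_id[i]), "")[[1]]
    data.frame(ref_id = refs$ref_id[i], body_pos = seq_along(b),
               base_dna = b, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map$model <- unname(base_model[map$base_dna])
  map$sym_kl <- NA_real_
  for (mc in names(kl_by_model)) {
    rec <- kl_by_model[[mc]]
    rec <- rec[rec$passed_coverage & !is.na(rec$sym_kl), , drop = FALSE]
    if (nrow(rec) == 0L) next
    dup <- duplicated(rec[c("ref_id", "body_pos")])
    if (any(dup)) stop("conflicting duplicate records for model ", mc)
    sel <- !is.na(map$model) & map$model == mc
    m <- match(paste(map$ref_id[sel], map$body_pos[sel]),
               paste(rec$ref_id, rec$body_pos))
    map$sym_kl[sel][!is.na(m)] <- rec$sym_kl[m[!is.na(m)]]
  }
  grp <- if (normalize == "per_model") map$model else
    paste(map$model, map$ref_id)
  map$sym_kl_norm <- suppressWarnings(min_max_normalize(map$sym_kl, grp))
  map$annotation <- NA_character_
  if (!is.null(annotations)) {
    ann <- annotations[!annotations$is_insertion, , drop = FALSE]
    m <- match(paste(map$ref_id, map$body_pos),
               paste(ann$ref_id, ann$position_num))
    map$annotation[!is.na(m)] <- ann$mod_code[m[!is.na(m)]]
  }
  map$fraction <- NA_real_; map$call <- NA
  if (!is.null(fractions)) {
    m <- match(paste(map$ref_id, map$body_pos),
               paste(fractions$ref_id, fractions$body_pos))
    map$fraction[!is.na(m)] <- fractions$fraction[m[!is.na(m)]]
    if (!is.null(fractions$call))
      map$call[!is.na(m)] <- fractions$call[m[!is.na(m)]]
  }
  map$base <- as_rna_base(map$base_dna)
  map$base_dna <- NULL
  map <- map[c("ref_id", "body_pos", "base", "model", "sym_kl",
               "sym_kl_norm", "annotation", "fraction", "call")]
  class(map) <- c("modification_map", "data.frame")
  map
}

#' Export a modification map as a plotting-ready wide matrix
#'
#' @param map a `modification_map`.
#' @param value which column to spread (`"sym_kl_norm"` or `"sym_kl"`).
#' @return matrix (references x body positions).
#' @export
map_matrix <- function(map, value = c("sym_kl_norm", "sym_kl")) {
  value <- match.arg(value)
  refs <- sort(unique(map$ref_id))
  pos <- seq_len(max(map$body_pos))
  m <- matrix(NA_real_, length(refs), length(pos),
              dimnames = list(refs, pos))
  m[cbind(match(map$ref_id, refs), map$body_pos)] <- map[[value]]
  m
}

#' Heatmap of a modification map or fraction matrix
#'
#' Simple base-graphics heatmap (references x body positions) for the
#' per-tRNA modification maps.
#'
#' @param m matrix from [map_matrix()] or [fraction_matrix()].
#' @param main plot title.
#' @param col color ramp.
#' @export
plot_site_matrix <- function(m, main = "",
                             col = grDevices::hcl.colors(64, "YlOrRd",
                                                         rev = TRUE)) {
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = col, xlab = "tRNA body position", ylab = "",
                  yaxt = "n", main = main)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(m)
}
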