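#' Score distributions for the simulator
#'
#' Per-read prediction scores are simulated by drawing a probability from a
#' distribution on \[0, 1\] and discretizing it with
#' [discretize_probability()]. Three shapes cover the phenomenology of
#' modification callers on tRNA: unmodified positions draw from a low mode
#' (`dist_unmodified()`, Beta(1, 20)); positions carrying the modification
#' the caller was trained for draw from a high mode (`dist_onlabel()`,
#' Beta(20, 1)); positions carrying a different ("off-label") uridine
#' modification draw from a broad mid-range mixture (`dist_offlabel()`,
#' 0.5 Beta(4, 4) + 0.5 Beta(8, 2)). The shapes are qualitative, chosen to
#' reproduce the reported low/high/abnormal distribution patterns, not
#' fitted values.
#'
#' @param shape1,shape2 Beta parameters.
#' @return A `score_dist` list.
#' @export
dist_beta <- function(shape1, shape2) {
  structure(list(type = "beta", shape1 = shape1, shape2 = shape2),
            class = "score_dist")
}

#' @rdname dist_beta
#' @param components list of `score_dist`.
#' @param weights mixture weights (sum to 1).
#' @export
dist_mixture <- function(components, weights) {
  stopifnot(length(components) == length(weights),
            abs(sum(weights) - 1) < 1e-8)
  structure(list(type = "mixture", components = components,
                 weights = weights), class = "score_dist")
}

#' @rdname dist_beta
#' @param p fixed probability for a point mass.
#' @export
dist_point <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(type = "point", p = p), class = "score_dist")
}

#' @rdname dist_beta
#' @export
dist_unmodified <- function() dist_beta(1, 20)

#' @rdname dist_beta
#' @export
dist_onlabel <- function() dist_beta(20, 1)

#' @rdname dist_beta
#' @export
dist_offlabel <- function()
  dist_mixture(list(dist_beta(4, 4), dist_beta(8, 2)), c(0.5, 0.5))

#' Draw discretized scores from a score distribution
#'
#' @param n number of draws.
#' @param dist a `score_dist`.
#' @return integer scores in \[0, 255\].
#' @export
rscore <- function(n, dist) {
  stopifnot(inherits(dist, "score_dist"))
  p <- switch(dist$type,
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    point = rep(dist$p, n),
    mixture = {
      k <- sample.int(length(dist$components), n, replace = TRUE,
                      prob = dist$weights)
      out <- numeric(n)
      for (i in seq_along(dist$components)) {
        sel <- k == i
        ci <- dist$components[[i]]
        out[sel] <- switch(ci$type,
                           beta = stats::rbeta(sum(sel), ci$shape1, ci$shape2),
                           point = rep(ci$p, sum(sel)))
      }
      out
    })
  discretize_probability(pmin(p, 1))
}

#' Modification site model for the simulator
#'
#' Describes one modified site: its stoichiometry (per-read probability of
#' carrying the modification), the score distributions of modified and
#' unmodified reads, and optional neighbor interference — modifications
#' whose presence perturbs the caller's scores at nearby canonical-base
#' positions of the same read (offsets relative to the site).
#'
#' @param ref_id,body_pos site location (1-based body coordinate).
#' @param stoichiometry per-read modification probability in \[0, 1\].
#' @param modified,unmodified `score_dist`s for modified / unmodified reads.
#' @param interference NULL, or a list with `offsets` (integer, e.g.
#'   `c(-1, 1)`) and `dist` (a `score_dist` drawn at the neighboring
#'   positions of modified reads).
#' @return A `site_model` list.
#' @export
site_model <- function(ref_id, body_pos, stoichiometry = 1,
                       modified = dist_onlabel(),
                       unmodified = dist_unmodified(),
                       interference = NULL) {
  stopifnot(stoichiometry >= 0, stoichiometry <= 1)
  structure(list(ref_id = ref_id, body_pos = as.integer(body_pos),
                 stoichiometry = stoichiometry, modified = modified,
                 unmodified = unmodified, interference = interference),
            class = "site_model")
}

#' Set all site stoichiometries to zero (knockout sample)
#'
#' @param site_models list of [site_model()].
#' @return the models with `stoichiometry = 0` (so no interference fires).
#' @export
knockout_models <- function(site_models) {
  lapply(site_models, function(s) { s$stoichiometry <- 0; s })
}

# Arbitrary fixed splint-adapter sequences for simulation only; real
# adapter sequences are experiment-specific configuration inputs.
SIM_ADAPTER5 <- "GGCTTCTTCTTGCTCTTAGGTAGT"                 # 24 nt
SIM_ADAPTER3 <- "CCTAAGAGCAAGAAGAAGCCTGGAAATCCT"           # 30 nt

#' Simulate a reference set of adapter-flanked tRNAs
#'
#' Random mature tRNA bodies with configurable base composition, flanked by
#' fixed simulation adapters (or user-supplied ones). Reproducible given a
#' seed.
#'
#' @param n number of references.
#' @param body_len_range inclusive range of body lengths.
#' @param adapter5,adapter3 adapter sequences.
#' @param base_probs sampling weights for A/C/G/T.
#' @param seed optional integer seed (sets the session RNG).
#' @return A [reference_set].
#' @export
simulate_references <- function(n, body_len_range = c(65L, 90L),
                                adapter5 = SIM_ADAPTER5,
                                adapter3 = SIM_ADAPTER3,
                                base_probs = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                                seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lens <- body_len_range[1] - 1L +
    sample.int(body_len_range[2] - body_len_range[1] + 1L, n, replace = TRUE)
  bodies <- vapply(lens, function(L)
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = ""), character(1))
  reference_set(sprintf("tRNA-sim-%03d", seq_len(n)), bodies,
                adapter5 = adapter5, adapter3 = adapter3)
}

mutate_one_read <- function(full_chars, start0, sub_rate, indel_rate) {
  L <- length(full_chars)
  idx <- (start0 + 1L):L             # 1-based indices into full_chars
  ref_pos0 <- idx - 1L
  del <- stats::runif(length(idx)) < indel_rate / 2
  kept <- which(!del)
  n_kept <- length(kept)
  if (n_kept == 0L)
    return(list(seq = "", map = data.frame(ref_pos0 = ref_pos0,
                                           read_pos0 = NA_integer_,
                                           substituted = FALSE)))
  sub <- stats::runif(n_kept) < sub_rate
  bases <- c("A", "C", "G", "T")
  kept_chars <- full_chars[idx[kept]]
  if (any(sub))
    kept_chars[sub] <- vapply(kept_chars[sub], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  ins <- stats::runif(n_kept) < indel_rate / 2  # one base after each kept base
  shift <- cumsum(c(0L, as.integer(ins[-n_kept])))
  read_pos_kept <- (seq_len(n_kept) - 1L) + shift
  total <- n_kept + sum(ins)
  chars <- character(total)
  chars[read_pos_kept + 1L] <- kept_chars
  if (any(ins))
    chars[read_pos_kept[ins] + 2L] <- sample(bases, sum(ins), replace = TRUE)
  read_pos0 <- rep(NA_integer_, length(idx))
  read_pos0[kept] <- read_pos_kept
  substituted <- rep(FALSE, length(idx))
  substituted[kept] <- sub
  list(seq = paste(chars, collapse = ""),
       map = data.frame(ref_pos0 = ref_pos0, read_pos0 = read_pos0,
                        substituted = substituted))
}

#' Simulate error-bearing direct-RNA reads from a reference set
#'
#' Each read copies one full reference with independent per-base
#' substitution and indel errors. With probability `truncation_prob` the
#' read is 5'-truncated into the tRNA body (direct-RNA sequencing reads
#' 3' to 5', so incomplete translocation loses the 5' end), which makes it
#' fail the full-length filter. The returned truth maps every retained
#' reference position to its read position.
#'
#' @param refs a [reference_set].
#' @param depth reads per reference.
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (split evenly between
#'   insertion and deletion).
#' @param truncation_prob probability a read is 5'-truncated.
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame `read_id`, `ref_id`, `seq`,
#'   `truncated`) and `truth` (list keyed by read id, each with `ref_id`,
#'   `truncated` and `map`: data.frame `ref_pos0`, `read_pos0`,
#'   `substituted`).
#' @export
simulate_reads <- function(refs, depth = 100L, sub_rate = 0.02,
                           indel_rate = 0.01, truncation_prob = 0.1,
                           seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            truncation_prob >= 0, truncation_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  reads <- list(); truth <- list()
  k <- 1L
  for (i in seq_len(nrow(refs))) {
    full_chars <- strsplit(refs$sequence[i], "")[[1]]
    a5 <- refs$adapter5_len[i]; bl <- refs$body_len[i]
    for (d in seq_len(depth)) {
      rid <- sprintf("%s_read%04d", refs$ref_id[i], d)
      trunc <- stats::runif(1) < truncation_prob
      # cut removes at least one body base but leaves >= 5 body bases
      start0 <- if (trunc && bl > 6L)
        sample((a5 + 1L):(a5 + bl - 5L), 1L) else 0L
      m <- mutate_one_read(full_chars, start0, sub_rate, indel_rate)
      reads[[k]] <- data.frame(read_id = rid, ref_id = refs$ref_id[i],
                               seq = m$seq, truncated = trunc && bl > 6L,
                               stringsAsFactors = FALSE)
      truth[[rid]] <- list(ref_id = refs$ref_id[i],
                           truncated = trunc && bl > 6L, map = m$map)
      k <- k + 1L
    }
  }
  list(reads = do.call(rbind, reads), truth = truth)
}

model_key <- function(site_models)
  vapply(site_models, function(s) paste(s$ref_id, s$body_pos, sep = "\r"),
         character(1))

#' Simulate per-read modification score tracks
#'
#' Emulates a modification caller on simulated reads: at every read position
#' whose basecall is the model's canonical base, a score is drawn — from the
#' matching [site_model()]'s modified/unmodified distribution (per-read
#' modification status drawn by stoichiometry) when the position maps
#' faithfully to a modeled body position, and from `background` otherwise
#' (error-derived canonical basecalls included). Neighbor interference is
#' applied after the draws: for each modified read at an interfering site,
#' scores at the site's offset positions are replaced by draws from the
#' interference distribution. Only scores at or above `emission_threshold`
#' are emitted (sub-threshold scores are withheld, as callers do).
#'
#' @param sim output of [simulate_reads()].
#' @param refs the [reference_set] the reads were simulated from.
#' @param site_models list of [site_model()].
#' @param mod_code modification code for the emitted tracks.
#' @param emission_threshold minimum emitted score (default 12 = 5%).
#' @param background `score_dist` for positions without a site model.
#' @param seed optional integer seed.
#' @return list with `tracks` (list of [read_score_track()] keyed by read
#'   id) and `truth` (data.frame `read_id`, `read_pos`, `ref_id`,
#'   `body_pos`, `modified`, `score_raw`, `emitted`).
#' @export
simulate_scores <- function(sim, refs, site_models, mod_code = "psi",
                            emission_threshold = 12L,
                            background = dist_unmodified(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- mod_info(mod_code)
  mkey <- model_key(site_models)
  tracks <- list(); truth_rows <- list()
  for (r in seq_len(nrow(sim$reads))) {
    rid <- sim$reads$read_id[r]
    tr <- sim$truth[[rid]]
    chars <- strsplit(sim$reads$seq[r], "")[[1]]
    canon_pos0 <- which(chars == info$canonical) - 1L
    # per-read modification status of every modeled site on this reference
    on_ref <- which(vapply(site_models, function(s)
      s$ref_id == tr$ref_id, logical(1)))
    z <- vapply(on_ref, function(j)
      stats::runif(1) < site_models[[j]]$stoichiometry, logical(1))
    if (length(canon_pos0) == 0L) {
      tracks[[rid]] <- read_score_track(rid, mod_code)
      next
    }
    m <- tr$map
    faithful <- m[!is.na(m$read_pos0) & !m$substituted, , drop = FALSE]
    body_of <- full0_to_body(refs, tr$ref_id, faithful$ref_pos0)
    bp <- body_of[match(canon_pos0, faithful$read_pos0)] # NA: adapter/error
    site_idx <- match(paste(tr$ref_id, bp, sep = "\r"), mkey)
    scores <- integer(length(canon_pos0))
    modified <- logical(length(canon_pos0))
    for (j in seq_along(canon_pos0)) {
      if (!is.na(site_idx[j])) {
        s <- site_models[[site_idx[j]]]
        zj <- z[match(site_idx[j], on_ref)]
        modified[j] <- zj
        scores[j] <- rscore(1L, if (zj) s$modified else s$unmodified)
      } else {
        scores[j] <- rscore(1L, background)
      }
    }
    # neighbor interference from modified sites of this read
    for (j in seq_along(on_ref)) {
      s <- site_models[[on_ref[j]]]
      if (!z[j] || is.null(s$interference)) next
      for (off in s$interference$offsets) {
        tgt <- which(!is.na(bp) & bp == s$body_pos + off)
        if (length(tgt))
          scores[tgt] <- rscore(length(tgt), s$interference$dist)
      }
    }
    emitted <- scores >= emission_threshold
    tracks[[rid]] <- read_score_track(
      rid, mod_code,
      stats::setNames(scores[emitted], canon_pos0[emitted]))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      read_id = rid, read_pos = canon_pos0, ref_id = tr$ref_id,
      body_pos = bp, modified = modified, score_raw = scores,
      emitted = emitted, stringsAsFactors = FALSE)
  }
  list(tracks = tracks,
       truth = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL)
}

#' Simulate a per-site score table directly (no read errors)
#'
#' Fast path that skips read simulation and alignment: every reference
#' position of the model's canonical base gets `depth` matched reads whose
#' scores are drawn from the applicable [site_model()] (with per-read
#' stoichiometry and neighbor-interference coupling shared across sites of
#' the same read) or from `background`. Scores below `emission_threshold`
#' are withheld, so `n_scored <= n_matched = depth`.
#'
#' @inheritParams simulate_scores
#' @param depth matched reads per site (also the per-tRNA coverage).
#' @return A `site_score_table` (see [build_site_table()]).
#' @export
simulate_site_table <- function(refs, site_models, depth = 100L,
                                mod_code = "psi", emission_threshold = 12L,
                                background = dist_unmodified(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- mod_info(mod_code)
  rows <- list()
  for (i in seq_len(nrow(refs))) {
    rid <- refs$ref_id[i]
    b <- strsplit(body_seq(refs, rid), "")[[1]]
    canon <- which(b == info$canonical)
    if (length(canon) == 0L) next
    on_ref <- Filter(function(s) s$ref_id == rid, site_models)
    z <- lapply(on_ref, function(s)
      stats::runif(depth) < s$stoichiometry)
    names(z) <- vapply(on_ref, function(s) as.character(s$body_pos),
                       character(1))
    site_at <- match(as.character(canon),
                     vapply(on_ref, function(s) as.character(s$body_pos),
                            character(1)))
    scores <- matrix(0L, nrow = depth, ncol = length(canon))
    for (j in seq_along(canon)) {
      if (!is.na(site_at[j])) {
        s <- on_ref[[site_at[j]]]
        zz <- z[[as.character(s$body_pos)]]
        sc <- integer(depth)
        if (any(zz)) sc[zz] <- rscore(sum(zz), s$modified)
        if (any(!zz)) sc[!zz] <- rscore(sum(!zz), s$unmodified)
        scores[, j] <- sc
      } else {
        scores[, j] <- rscore(depth, background)
      }
    }
    for (s in on_ref) {
      if (is.null(s$interference)) next
      zz <- z[[as.character(s$body_pos)]]
      if (!any(zz)) next
      for (off in s$interference$offsets) {
        j <- match(s$body_pos + off, canon)
        if (!is.na(j))
          scores[zz, j] <- rscore(sum(zz), s$interference$dist)
      }
    }
    for (j in seq_along(canon)) {
      em <- scores[, j][scores[, j] >= emission_threshold]
      rr <- data.frame(ref_id = rid, body_pos = canon[j],
                       mod_code = mod_code, n_matched = as.integer(depth),
                       n_scored = length(em), stringsAsFactors = FALSE)
      rr$scores <- list(sort(as.integer(em)))
      rows[[length(rows) + 1L]] <- rr
    }
  }
  df <- do.call(rbind, rows)
  new_site_table(df, stats::setNames(rep(as.integer(depth), nrow(refs)),
                                     refs$ref_id))
}

#' Simulate raw signals with stride-coded move tables
#'
#' For each read, each base contributes one signal segment of length
#' `stride` times a dwell drawn from `dwell_blocks`, sampled around the
#' base's level from `level_table` with Gaussian noise. Positions listed in
#' `shift_sites` (faithfully mapped body positions) have their level shifted
#' by `delta`, emulating a modification's signal perturbation.
#'
#' @param sim output of [simulate_reads()] (reads plus truth maps).
#' @param refs the [reference_set].
#' @param level_table named numeric levels per base (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param stride samples per move entry.
#' @param dwell_blocks possible dwell lengths, in blocks of `stride`.
#' @param shift_sites NULL or data.frame `ref_id`, `body_pos`, `delta`.
#' @param seed optional integer seed.
#' @return list keyed by read id, each with `signal`, `moves` and
#'   `lengths` (true per-base segment lengths).
#' @export
simulate_signals <- function(sim, refs,
                             level_table = c(A = 90, C = 105, G = 85,
                                             T = 110),
                             noise_sd = 2, stride = 6L, dwell_blocks = 1:3,
                             shift_sites = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (r in seq_len(nrow(sim$reads))) {
    rid <- sim$reads$read_id[r]
    tr <- sim$truth[[rid]]
    chars <- strsplit(sim$reads$seq[r], "")[[1]]
    if (length(chars) == 0L) next
    levels <- unname(level_table[chars])
    if (!is.null(shift_sites)) {
      faithful <- tr$map[!is.na(tr$map$read_pos0) & !tr$map$substituted, ,
                         drop = FALSE]
      bp <- full0_to_body(refs, tr$ref_id, faithful$ref_pos0)
      ss <- shift_sites[shift_sites$ref_id == tr$ref_id, , drop = FALSE]
      hit <- match(bp, ss$body_pos)
      sel <- !is.na(hit)
      if (any(sel))
        levels[faithful$read_pos0[sel] + 1L] <-
          levels[faithful$read_pos0[sel] + 1L] + ss$delta[hit[sel]]
    }
    lens <- stride * sample(dwell_blocks, length(chars), replace = TRUE)
    signal <- stats::rnorm(sum(lens), rep(levels, lens), noise_sd)
    out[[rid]] <- list(signal = signal,
                       moves = moves_from_lengths(lens, stride),
                       lengths = lens)
  }
  out
}
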