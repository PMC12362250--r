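test_that("move-table segmentation recovers per-base segments", {
  # 3 bases with segments of 6, 12, 6 samples
  moves <- c(1L, 1L, 0L, 1L)
  seg <- segment_signal(moves, seq_len(24), stride = 6)
  expect_equal(nrow(seg$segments), 3L)
  expect_equal(seg$segments$end - seg$segments$start + 1L, c(6L, 12L, 6L))

  # totals must be consistent: a 7-sample "segment" cannot exist
  expect_error(segment_signal(c(1L), seq_len(7), stride = 6), "stride")
  expect_error(segment_signal(c(0L, 1L), seq_len(12)), "leading 1")

  # round trip with the simulator's truth lengths
  refs <- simulate_references(1, body_len_range = c(30, 30), seed = 401)
  sim <- simulate_reads(refs, depth = 3, sub_rate = 0, indel_rate = 0,
                        truncation_prob = 0, seed = 402)
  sig <- simulate_signals(sim, refs, noise_sd = 0, seed = 403)
  for (rid in names(sig)) {
    seg <- segment_signal(sig[[rid]]$moves, sig[[rid]]$signal)
    expect_equal(seg$segments$end - seg$segments$start + 1L,
                 sig[[rid]]$lengths)
  }
})

test_that("six-point subsampling uses floor(i*L/6) and is idempotent", {
  expect_equal(subsample_six(1:6), 1:6)
  expect_equal(subsample_six(1:12), c(1L, 3L, 5L, 7L, 9L, 11L))
  expect_equal(subsample_six(rep(7.5, 18)), rep(7.5, 6))
  expect_equal(subsample_six(subsample_six(1:12)), subsample_six(1:12))
  expect_error(subsample_six(1:7), "multiple of 6")
  expect_error(subsample_six(numeric()), "multiple of 6")
})

test_that("signal tracks keep aligned positions and drop per-read deletions", {
  refs <- reference_set("t", "ACGTACGTAC", adapter5 = "GG", adapter3 = "CC")
  full <- refs$sequence[1]
  # read with a deletion of full-seq position 5 (0-based) = body pos 4
  ch <- strsplit(full, "")[[1]]
  reads <- c(whole = full, gap = paste(ch[-6], collapse = ""),
             mm = paste(replace(ch, 6, "C"), collapse = "")) # mismatch at 4
  alns <- filter_alignments(align_all(reads, refs), refs, min_as = 5,
                            max_uncovered = 1)
  sigs <- list(); segs <- list()
  for (rid in names(reads)) {
    n <- nchar(reads[[rid]])
    lens <- rep(6L, n)
    sigs[[rid]] <- rep(seq_len(n), each = 6) # constant within each base
    segs[[rid]] <- segment_signal(moves_from_lengths(lens), sigs[[rid]])
  }
  trk <- build_signal_track(alns, segs, sigs, refs)
  expect_false(any(trk$read_id == "gap" & trk$body_pos == 4))
  expect_true(any(trk$read_id == "mm" & trk$body_pos == 4))  # mismatches kept
  expect_true(any(trk$read_id == "whole" & trk$body_pos == 4))
  # constant segments: the six subsampled values equal the base index
  w4 <- trk[trk$read_id == "whole" & trk$body_pos == 4, paste0("v", 1:6)]
  expect_true(all(w4 == 6)) # body pos 4 = read pos 5 (0-based) = base 6

  # reads missing a segmentation are skipped with a message
  expect_message(build_signal_track(alns, segs[-1], sigs, refs), "skipped")
})

test_that("vertical shift is the median of per-position median differences", {
  mk_track <- function(offset) {
    d <- data.frame(ref_id = "t", body_pos = rep(1:2, each = 1),
                    read_id = "r",
                    v1 = 1, v2 = 1, v3 = 1, v4 = 1, v5 = 1, v6 = 1)
    s <- data.frame(ref_id = "t", body_pos = 1:2, n_reads = 1L,
                    median = c(10, 20) + offset, sd = c(1, 1))
    attr(d, "summary") <- s
    class(d) <- c("signal_track", "data.frame")
    d
  }
  expect_equal(unname(vertical_shift(mk_track(0), mk_track(0))), 0)
  # per-position differences {2, 3} -> median 2.5
  a <- mk_track(0); b <- mk_track(0)
  sb <- attr(b, "summary"); sb$median <- sb$median - c(2, 3)
  attr(b, "summary") <- sb
  expect_equal(unname(vertical_shift(a, b)), 2.5)
  # adding c to track b decreases the shift by c (median equivariance)
  sb2 <- attr(b, "summary"); sb2$median <- sb2$median + 7
  b2 <- b; attr(b2, "summary") <- sb2
  expect_equal(unname(vertical_shift(a, b2)), 2.5 - 7)
  # no common positions errors
  sb3 <- attr(b, "summary"); sb3$body_pos <- 8:9
  b3 <- b; attr(b3, "summary") <- sb3
  expect_error(vertical_shift(a, b3), "common")
})

test_that("after applying the shift the median residual is zero", {
  refs <- simulate_references(1, body_len_range = c(40, 40), seed = 411)
  sim_a <- simulate_reads(refs, depth = 8, sub_rate = 0, indel_rate = 0,
                          truncation_prob = 0, seed = 412)
  sim_b <- simulate_reads(refs, depth = 8, sub_rate = 0, indel_rate = 0,
                          truncation_prob = 0, seed = 413)
  sig_a <- simulate_signals(sim_a, refs, noise_sd = 1, seed = 414)
  sig_b <- simulate_signals(sim_b, refs, noise_sd = 1, seed = 415)
  # sample b has a constant instrumental offset
  for (rid in names(sig_b)) sig_b[[rid]]$signal <- sig_b[[rid]]$signal - 12
  track <- function(sim, sig) {
    alns <- filter_alignments(align_all(sim$reads, refs), refs)
    segs <- lapply(sig, function(s) segment_signal(s$moves, s$signal))
    build_signal_track(alns, segs, lapply(sig, `[[`, "signal"), refs)
  }
  ta <- track(sim_a, sig_a); tb <- track(sim_b, sig_b)
  shift <- vertical_shift(ta, tb)
  expect_lt(abs(unname(shift) - 12), 1.5)
  # self-consistency: shifting b's summary by `shift` zeroes the median diff
  sb <- attr(tb, "summary"); sb$median <- sb$median + shift
  tb2 <- tb; attr(tb2, "summary") <- sb
  expect_equal(unname(vertical_shift(ta, tb2)), 0, tolerance = 1e-9)
})

test_that("signal sidecar TSV round trips signals and moves", {
  refs <- simulate_references(1, body_len_range = c(20, 20), seed = 421)
  sim <- simulate_reads(refs, depth = 2, truncation_prob = 0, seed = 422)
  sig <- simulate_signals(sim, refs, seed = 423)
  f <- tempfile(fileext = ".tsv")
  write_signal_sidecar(sig, f)
  back <- read_signal_sidecar(f)
  expect_equal(names(back), names(sig))
  for (rid in names(sig)) {
    expect_equal(back[[rid]]$moves, sig[[rid]]$moves)
    expect_equal(back[[rid]]$signal, sig[[rid]]$signal, tolerance = 1e-8)
  }
})
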