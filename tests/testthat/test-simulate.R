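test_that("reference simulation is reproducible and seed-sensitive", {
  r1 <- simulate_references(5, seed = 501)
  r2 <- simulate_references(5, seed = 501)
  r3 <- simulate_references(5, seed = 502)
  expect_equal(nrow(r1), 5L)
  expect_equal(length(unique(r1$ref_id)), 5L)
  expect_identical(r1, r2)
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("read simulation respects its error-rate knobs", {
  refs <- simulate_references(2, seed = 511)
  clean <- simulate_reads(refs, depth = 4, sub_rate = 0, indel_rate = 0,
                          truncation_prob = 0, seed = 512)
  expect_equal(unique(clean$reads$seq),
               refs$sequence[match(unique(clean$reads$ref_id), refs$ref_id)])

  # empirical substitution rate within 3 binomial SE of the target
  sub <- simulate_reads(refs, depth = 100, sub_rate = 0.02, indel_rate = 0,
                        truncation_prob = 0, seed = 513)
  maps <- do.call(rbind, lapply(sub$truth, `[[`, "map"))
  rate <- mean(maps$substituted)
  se <- sqrt(0.02 * 0.98 / nrow(maps))
  expect_lt(abs(rate - 0.02), 3 * se)

  # determinism
  again <- simulate_reads(refs, depth = 100, sub_rate = 0.02, indel_rate = 0,
                          truncation_prob = 0, seed = 513)
  expect_identical(sub$reads, again$reads)
})

test_that("score simulation honors stoichiometry and emission threshold", {
  refs <- simulate_references(1, seed = 521)
  upos <- which(strsplit(body_seq(refs, refs$ref_id), "")[[1]] == "T")
  sim <- simulate_reads(refs, depth = 60, sub_rate = 0, indel_rate = 0,
                        truncation_prob = 0, seed = 522)

  # pi = 1 with a point mass at 255 gives fraction 1.0 at the site
  models <- list(site_model(refs$ref_id, upos[1], stoichiometry = 1,
                            modified = dist_point(1)))
  sc <- simulate_scores(sim, refs, models, seed = 523)
  kept <- filter_alignments(align_all(sim$reads, refs), refs)
  tab <- build_site_table(kept, sc$tracks, refs)
  fr <- site_fraction(tab, min_coverage = 20)
  expect_equal(fr$fraction[fr$body_pos == upos[1]], 1.0)

  # pi = 0 everywhere: high-score fraction is the background false-positive
  # rate, which is tiny for the low-mode distribution
  sc0 <- simulate_scores(sim, refs, knockout_models(models), seed = 524)
  tab0 <- build_site_table(kept, sc0$tracks, refs)
  fr0 <- site_fraction(tab0, min_coverage = 20)
  expect_lt(max(fr0$fraction), 0.05)

  # an emission threshold of 256 silences every track
  sc256 <- simulate_scores(sim, refs, models, emission_threshold = 256,
                           seed = 525)
  expect_true(all(vapply(sc256$tracks, function(t) length(t$scores) == 0L,
                         logical(1))))

  # truth table is sufficient to recompute emitted tracks
  tr <- sc$truth[sc$truth$read_id == sim$reads$read_id[1] & sc$truth$emitted, ]
  expect_equal(unname(sc$tracks[[sim$reads$read_id[1]]]$scores),
               tr$score_raw)
})

test_that("decoded simulator tags equal the simulator's truth table", {
  refs <- simulate_references(1, seed = 531)
  sim <- simulate_reads(refs, depth = 8, truncation_prob = 0, seed = 532)
  upos <- which(strsplit(body_seq(refs, refs$ref_id), "")[[1]] == "T")
  sc <- simulate_scores(sim, refs,
                        list(site_model(refs$ref_id, upos[2])), seed = 533)
  f <- tempfile(fileext = ".sam")
  write_modsam(sim$reads, sc$tracks, f)
  back <- read_modsam(f, "psi")
  truth <- sc$truth[sc$truth$emitted, ]
  for (rid in sim$reads$read_id) {
    want <- truth[truth$read_id == rid, ]
    got <- back$tracks[[rid]]$scores
    expect_equal(as.integer(names(got)), want$read_pos)
    expect_equal(unname(got), want$score_raw)
  }
})

test_that("direct site-table simulation matches its analytic expectations", {
  refs <- simulate_references(2, seed = 541)
  upos <- which(strsplit(body_seq(refs, refs$ref_id[1]), "")[[1]] == "T")
  models <- list(site_model(refs$ref_id[1], upos[1], stoichiometry = 1,
                            modified = dist_point(1)))
  tab <- simulate_site_table(refs, models, depth = 50, seed = 542)
  expect_true(all(tab$n_matched == 50L))
  expect_true(all(tab$n_scored <= tab$n_matched))
  site <- tab[tab$ref_id == refs$ref_id[1] & tab$body_pos == upos[1], ]
  expect_equal(site$scores[[1]], rep(255L, 50))
  expect_identical(as.data.frame(simulate_site_table(refs, models, depth = 50,
                                                     seed = 542)),
                   as.data.frame(tab))
})

test_that("full truncation leaves no reads after the full-length filter", {
  refs <- simulate_references(1, seed = 551)
  sim <- simulate_reads(refs, depth = 10, truncation_prob = 1, seed = 552)
  expect_true(all(sim$reads$truncated))
  kept <- filter_alignments(align_all(sim$reads, refs), refs)
  expect_length(kept, 0L)
})

test_that("simulated signals follow the level table exactly at zero noise", {
  refs <- simulate_references(1, body_len_range = c(25, 25), seed = 561)
  sim <- simulate_reads(refs, depth = 2, sub_rate = 0, indel_rate = 0,
                        truncation_prob = 0, seed = 562)
  lv <- c(A = 90, C = 105, G = 85, T = 110)
  sig <- simulate_signals(sim, refs, level_table = lv, noise_sd = 0,
                          dwell_blocks = 1, seed = 563)
  rid <- sim$reads$read_id[1]
  chars <- strsplit(sim$reads$seq[1], "")[[1]]
  expect_equal(length(sig[[rid]]$signal), 6L * length(chars))
  expect_equal(sig[[rid]]$signal, rep(unname(lv[chars]), each = 6))

  # a level shift at one site separates the two samples there only
  upos <- which(strsplit(body_seq(refs, refs$ref_id), "")[[1]] == "T")[1]
  shift <- data.frame(ref_id = refs$ref_id, body_pos = upos, delta = 30)
  sig_mod <- simulate_signals(sim, refs, level_table = lv, noise_sd = 0,
                              dwell_blocks = 1, shift_sites = shift,
                              seed = 564)
  alns <- filter_alignments(align_all(sim$reads, refs), refs)
  segs <- lapply(sig, function(s) segment_signal(s$moves, s$signal))
  segs_m <- lapply(sig_mod, function(s) segment_signal(s$moves, s$signal))
  ta <- build_signal_track(alns, segs_m, lapply(sig_mod, `[[`, "signal"), refs)
  tb <- build_signal_track(alns, segs, lapply(sig, `[[`, "signal"), refs)
  sa <- attr(ta, "summary"); sb <- attr(tb, "summary")
  d <- abs(sa$median - sb$median[match(paste(sa$ref_id, sa$body_pos),
                                       paste(sb$ref_id, sb$body_pos))])
  expect_equal(sa$body_pos[d > 1], upos)
})
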