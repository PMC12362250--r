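test_that("probability discretization matches the caller's conversion", {
  expect_equal(discretize_probability(0.05), 12L)
  expect_equal(discretize_probability(0.80), 204L)
  expect_equal(discretize_probability(c(0, 1)), c(0L, 255L))
  expect_error(discretize_probability(-0.1), "\\[0, 1\\]")
  expect_error(discretize_probability(1.1), "\\[0, 1\\]")
})

test_that("MM/ML decoding resolves skip counts against canonical bases", {
  # read AUUGU: Us at 0-based positions 1, 2, 4; address the 2nd and 3rd
  tr <- decode_mod_tags("AUUGU", "T+17802?,1,0;", c(200L, 50L), "psi")
  expect_equal(tr$scores, c(`2` = 200L, `4` = 50L))

  # record without tags gives an empty track
  tr0 <- decode_mod_tags("AUUGU", "", integer(), "psi")
  expect_length(tr0$scores, 0L)

  # a tag for a different model yields an empty track with a warning
  expect_warning(
    tr2 <- decode_mod_tags("AUUGU", "A+a?,0;", 99L, "psi"), "no MM entry")
  expect_length(tr2$scores, 0L)

  # MM/ML length mismatch errors
  expect_error(decode_mod_tags("AUUGU", "T+17802?,1,0;", 200L, "psi"),
               "mismatch")
})

test_that("MM/ML encode-decode round trip recovers emitted scores exactly", {
  set.seed(5)
  for (i in 1:25) {
    seq <- random_dna(40)
    tpos <- which(strsplit(seq, "")[[1]] == "T") - 1L
    if (length(tpos) < 2) next
    keep <- sort(sample(tpos, sample(seq_along(tpos), 1)))
    scores <- stats::setNames(sample(12:255, length(keep), replace = TRUE),
                              keep)
    tr <- read_score_track("r", "psi", scores)
    enc <- encode_mod_tags(seq, tr)
    dec <- decode_mod_tags(seq, enc$mm, enc$ml, "psi", read_id = "r")
    expect_equal(dec$scores, tr$scores)
  }
})

test_that("SAM text round trip preserves reads and score tracks", {
  refs <- simulate_references(2, seed = 61)
  sim <- simulate_reads(refs, depth = 5, seed = 62)
  sc <- simulate_scores(sim, refs, list(), seed = 63)
  f <- tempfile(fileext = ".sam")
  write_modsam(sim$reads, sc$tracks, f)
  back <- read_modsam(f, "psi")
  expect_equal(back$reads$seq,
               vapply(sim$reads$seq, trnamod:::normalize_seq, character(1),
                      USE.NAMES = FALSE))
  for (rid in sim$reads$read_id)
    expect_equal(back$tracks[[rid]]$scores, sc$tracks[[rid]]$scores)
})

test_that("score projection keeps matched canonical-base positions only", {
  refs <- reference_set("t", "ATTGAT", adapter5 = "CC", adapter3 = "GG")
  # read matches the full reference except a mismatch at body pos 2 (first T)
  read <- "CCAGTGATGG"
  aln <- local_align(read, refs$sequence[1], read_id = "r", ref_id = "t")
  tr <- read_score_track("r", "psi", c(`4` = 250L)) # read pos 4 = body pos 3
  out <- project_scores(aln, tr, refs)
  # body Ts at 2, 3, 6; mismatch at 2 contributes nothing
  expect_setequal(out$body_pos, c(3L, 6L))
  expect_equal(out$score[out$body_pos == 3L], 250L)
  expect_true(is.na(out$score[out$body_pos == 6L])) # matched, unscored
  expect_error(project_scores(aln, read_score_track("other", "psi"), refs),
               "mismatch")
})

test_that("site tables aggregate deterministically and conserve scores", {
  refs <- simulate_references(2, seed = 71)
  sim <- simulate_reads(refs, depth = 25, truncation_prob = 0, seed = 72)
  models <- list()
  sc <- simulate_scores(sim, refs, models, seed = 73)
  kept <- filter_alignments(align_all(sim$reads, refs), refs)
  tab <- build_site_table(kept, sc$tracks, refs, "psi")

  # read input order does not change the table
  rev_kept <- structure(rev(kept), class = "alignment_set")
  tab2 <- build_site_table(rev_kept, sc$tracks, refs, "psi")
  expect_equal(as.data.frame(tab), as.data.frame(tab2))

  # conservation: total emitted scores on matched canonical positions equals
  # the sum of per-site n_scored (computed independently from the truth)
  expect_equal(sum(tab$n_scored),
               sum(vapply(tab$scores, length, integer(1))))
  expect_true(all(tab$n_scored <= tab$n_matched))
  expect_true(all(unlist(tab$scores) >= 12L & unlist(tab$scores) <= 255L))

  # empty input
  tab0 <- build_site_table(structure(list(), class = "alignment_set"),
                           list(), refs, "psi")
  expect_equal(nrow(tab0), 0L)

  # two identical error-free reads contribute two scores per emitted site
  refs1 <- reference_set("z", "TTAGGTTC", adapter5 = "ACGTA",
                         adapter3 = "CGTAC")
  reads <- c(a = refs1$sequence[1], b = refs1$sequence[1])
  trks <- list(a = read_score_track("a", "psi", c(`5` = 240L)),
               b = read_score_track("b", "psi", c(`5` = 100L)))
  kept1 <- filter_alignments(align_all(reads, refs1), refs1, min_as = 5)
  tab1 <- build_site_table(kept1, trks, refs1, "psi")
  s <- tab1[tab1$body_pos == 1L, ] # read pos 5 = full pos 5 = body pos 1
  expect_equal(s$scores[[1]], c(100L, 240L))
  expect_equal(s$n_matched, 2L)
})

test_that("site-table coverage matches simulator truth at zero error", {
  refs <- simulate_references(2, seed = 81)
  sim <- simulate_reads(refs, depth = 10, sub_rate = 0, indel_rate = 0,
                        truncation_prob = 0, seed = 82)
  sc <- simulate_scores(sim, refs, list(), seed = 83)
  kept <- filter_alignments(align_all(sim$reads, refs), refs)
  tab <- build_site_table(kept, sc$tracks, refs, "psi")
  expect_true(all(tab$n_matched == 10L))
  cov <- attr(tab, "ref_coverage")
  expect_equal(unname(cov[refs$ref_id]), rep(10L, 2))
})

test_that("site table TSV round trips including coverage metadata", {
  tab <- simulate_site_table(tiny_refs(), list(), depth = 30, seed = 91)
  f <- tempfile(fileext = ".tsv")
  write_site_table(tab, f)
  back <- read_site_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "ref_coverage"), attr(tab, "ref_coverage"))
})

test_that("score sidecar TSV is an equivalent tag-free input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("read_id\tread_pos\tmod_code\tscore",
               "r1\t3\tpsi\t200", "r1\t7\tpsi\t15", "r2\t0\tpsi\t255",
               "r1\t4\tm6a\t99"), f)
  trks <- read_score_sidecar(f, "psi")
  expect_equal(trks$r1$scores, c(`3` = 200L, `7` = 15L))
  expect_equal(trks$r2$scores, c(`0` = 255L))
})
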