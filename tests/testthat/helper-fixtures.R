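# Tiny in-code fixtures shared across test files.

tiny_refs <- function() {
  reference_set(
    ref_id = c("tRNA-A", "tRNA-B"),
    body = c("GGTTCGATTCCCGGTACGTGCA",   # 22 nt
             "GCCGTAATGGCATACGGTTTAGGC"), # 24 nt
    adapter5 = "AACCG",
    adapter3 = "TTGGCA"
  )
}

# site table built by hand: one reference, explicit score lists
hand_site_table <- function(scores_by_pos, n_matched, ref = "tRNA-A",
                            mod_code = "psi", coverage = 100L) {
  df <- data.frame(ref_id = ref,
                   body_pos = as.integer(names(scores_by_pos)),
                   mod_code = mod_code,
                   n_matched = as.integer(n_matched),
                   n_scored = vapply(scores_by_pos, length, integer(1)),
                   stringsAsFactors = FALSE)
  df$scores <- lapply(scores_by_pos, function(s) sort(as.integer(s)))
  trnamod:::new_site_table(df, stats::setNames(as.integer(coverage), ref))
}
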