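# small builders used across the suite

mk_aln <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  alignment(stats::setNames(seqs, ids))
}

mk_popmap <- function(ids, pops, groups = pops) {
  data.frame(sample_id = ids, population_id = pops, group_id = groups,
             stringsAsFactors = FALSE)
}

# random unambiguous alignment, seeded by the caller
rand_aln <- function(n, L) {
  mk_aln(replicate(n, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = "")))
}

strrep1 <- function(ch, n) paste(rep(ch, n), collapse = "")
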