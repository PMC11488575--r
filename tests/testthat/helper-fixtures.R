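# Fixture builders shared across test files; everything is generated in
# code, seeded, and small.

# n ORFs of length L with identical counts `value` (plus optional tweaks)
uniformProfiles <- function(n, L, value = 2) {
  setNames(lapply(seq_len(n), function(i) rep(value, L)),
           sprintf("g%02d", seq_len(n)))
}

# a TpmPartition placing every ORF in a single bin 0
singleBinPartition <- function(ids) {
  tpm <- setNames(rep(1e6 / length(ids), length(ids)), ids)
  methods::new("TpmPartition", tpm = tpm, binEdges = c(0, 1e6),
               bin = setNames(rep(0L, length(ids)), ids))
}

# deterministic random coding sequences (ATG + body + TAA), codon lengths L
randomCds <- function(L, seed = 1, codons = senseCodons()) {
  set.seed(seed)
  seqs <- vapply(L, function(l) {
    paste0("ATG", paste(sample(codons, l - 1, replace = TRUE), collapse = ""),
           "TAA")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(L)))
}

# build a PauseCallSet over full ORFs with pauses at given (orf, index) rows
makeCallSet <- function(orfLengths, pauses, seed = 1) {
  set.seed(seed)
  ids <- names(orfLengths)
  df <- data.frame(
    orf_id = rep(ids, orfLengths),
    codon_index = unlist(lapply(orfLengths, function(l) seq_len(l) - 1L),
                         use.names = FALSE))
  df$score <- runif(nrow(df), 0, 0.4)
  key <- paste(df$orf_id, df$codon_index)
  pkey <- paste(pauses$orf_id, pauses$codon_index)
  df$is_pause <- key %in% pkey
  df$score[df$is_pause] <- runif(sum(df$is_pause), 0.8, 1)
  df$bin <- 0L
  methods::new("PauseCallSet", calls = df,
               params = list(nTrees = 0L, thresholdQuantile = NA_real_,
                             seed = seed, psi = integer(0)),
               binSummary = data.frame())
}

# replace codons at 0-based positions of one CDS (keeps ATG/TAA framing)
setCodons <- function(cds, orf, positions, codon) {
  s <- as.character(cds[[orf]])
  for (p in positions)
    substr(s, 3 * p + 1, 3 * p + 3) <- codon
  cds[[orf]] <- Biostrings::DNAString(s)
  cds
}
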