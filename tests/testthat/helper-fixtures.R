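# Shared fixtures built in code.

# Reference affinity/frequency table (packaged TSV).
ref_table <- pas_reference_table()

# The 16 unlabeled oligos with a measured Kd.
unlabeled_kd <- function() {
  t <- ref_table[!ref_table$labeled & is.finite(ref_table$kd_nM), ]
  stats::setNames(t$kd_nM, t$hexamer)
}

# Renormalised hexamer frequency distribution over the 18 annotated hexamers.
hexamer_probs <- function() {
  t <- ref_table[!ref_table$labeled, ]
  stats::setNames(t$frequency_percent / sum(t$frequency_percent), t$hexamer)
}

# Independent bisection oracle for the free-receptor concentration, written
# against the mass balance directly (kept separate from the package's
# vectorised solver on purpose).
oracle_free_receptor <- function(rt, lt, it, k1, k2) {
  if (rt == 0) return(0)
  g <- function(r) r * (1 + lt / (k1 + r) + it / (k2 + r)) - rt
  lo <- 0; hi <- rt
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Hand-written three-transcript annotation fixture:
#  T1 (+): one AAUAAA;  T2 (+): AAUAAA then AUUAAA;  T3 (-): one AACAAA.
# Returns paths to a GFF3 and its FASTA written under `dir`.
write_tiny_gff3_fixture <- function(dir) {
  mk <- function(len, plant) {
    s <- strrep("C", len)
    for (p in names(plant)) {
      at <- plant[[p]]
      substr(s, at, at + nchar(p) - 1) <- p
    }
    s
  }
  # T3 carries AACAAA on the minus strand: plus-strand DNA is revcomp = TTTGTT
  seqs <- c(T1 = mk(60, list(AATAAA = 21)),
            T2 = mk(90, list(AATAAA = 21, ATTAAA = 51)),
            T3 = mk(60, list(TTTGTT = 31)))
  fasta <- file.path(dir, "tiny.fasta")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             fasta)
  gff <- file.path(dir, "tiny.gff3")
  writeLines(c(
    "##gff-version 3",
    "T1\ttest\tmRNA\t5\t55\t.\t+\t.\tID=T1",
    "T2\ttest\tmRNA\t5\t85\t.\t+\t.\tID=T2",
    "T3\ttest\tmRNA\t5\t55\t.\t-\t.\tID=T3",
    "T1\ttest\tregulatory_region\t21\t26\t.\t+\t.\tParent=T1;regulatory_class=polyA_signal_sequence",
    "T2\ttest\tregulatory_region\t21\t26\t.\t+\t.\tParent=T2;regulatory_class=polyA_signal_sequence",
    "T2\ttest\tregulatory_region\t51\t56\t.\t+\t.\tParent=T2;regulatory_class=polyA_signal_sequence",
    "T3\ttest\tregulatory_region\t31\t36\t.\t-\t.\tParent=T3;regulatory_class=polyA_signal_sequence"),
    gff)
  list(gff3 = gff, fasta = fasta)
}
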