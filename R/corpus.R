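#' Specification of a synthetic annotation corpus
#'
#' Describes a corpus of transcripts, each carrying one or more annotated
#' polyadenylation signals, used to exercise the census with a known ground
#' truth. Background sequence is uniform over ACGT (the census reads
#' features by coordinate, so background content is immaterial); signals
#' are planted at least 10 nt from the transcript ends.
#'
#' @param n_transcripts Number of transcripts.
#' @param hexamer_probs Named probability vector over RNA hexamers
#'   (names 6-nt ACGU strings; must sum to 1).
#' @param pas_count_probs Named probability vector over per-transcript
#'   signal counts, names `"1"`, `"2"`, ... (must sum to 1).
#' @param strand_fraction_minus Probability a transcript is annotated on
#'   the minus strand.
#' @param intergenic_pad Background nucleotides flanking each transcript on
#'   its contig.
#' @param seed Integer seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_transcripts,
                        hexamer_probs,
                        pas_count_probs = c("1" = 0.6, "2" = 0.25, "3" = 0.15),
                        strand_fraction_minus = 0.5,
                        intergenic_pad = 30,
                        seed = 1) {
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  check_rna(names(hexamer_probs), width = 6)
  if (abs(sum(hexamer_probs) - 1) > 1e-9)
    stop("hexamer_probs must sum to 1")
  if (abs(sum(pas_count_probs) - 1) > 1e-9)
    stop("pas_count_probs must sum to 1")
  counts <- as.integer(names(pas_count_probs))
  if (any(is.na(counts)) || any(counts < 1))
    stop("pas_count_probs names must be positive integers")
  if (strand_fraction_minus < 0 || strand_fraction_minus > 1)
    stop("strand_fraction_minus must lie in [0, 1]")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 hexamer_probs = hexamer_probs,
                 pas_count_probs = pas_count_probs,
                 strand_fraction_minus = strand_fraction_minus,
                 intergenic_pad = as.integer(intergenic_pad),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

rna_to_dna <- function(x) chartr("U", "T", x)
dna_to_rna <- function(x) chartr("T", "U", x)
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic annotated corpus
#'
#' Draws, per transcript, a signal count and that many hexamers i.i.d. from
#' the spec's hexamer distribution, plants each hexamer (as DNA,
#' reverse-complemented for minus-strand transcripts) at recorded
#' coordinates inside random background sequence, and writes the corpus in
#' three synthetic fixture formats: genome FASTA, GFF3 annotation, and a
#' GenBank flat file, plus a ground-truth TSV. Each transcript sits on its
#' own contig. Deterministic given the spec's seed.
#'
#' @param spec A [corpus_spec()].
#' @param dir Output directory (created if missing).
#' @param legacy_dialect If `TRUE`, signals are written with the legacy
#'   `polyA_signal` feature key instead of
#'   `regulatory_region`/`regulatory` + `regulatory_class =
#'   polyA_signal_sequence`.
#' @return List with `fasta`, `gff3`, `genbank`, `truth_tsv` paths and the
#'   ground-truth data frame `truth` (columns `transcript_id`, `hexamer`,
#'   `ordinal`, `n_on_transcript`, `chrom`, `start`, `end`, `strand`).
#' @export
generate_corpus <- function(spec, dir, legacy_dialect = FALSE) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pad <- spec$intergenic_pad
  res <- with_seed(spec$seed, {
    n <- spec$n_transcripts
    tid <- sprintf("T%05d", seq_len(n))
    n_pas <- sample(as.integer(names(spec$pas_count_probs)), n, replace = TRUE,
                    prob = spec$pas_count_probs)
    strand <- ifelse(stats::runif(n) < spec$strand_fraction_minus, "-", "+")
    tlen <- 20L + 30L * n_pas
    clen <- tlen + 2L * pad
    hexes <- sample(names(spec$hexamer_probs), sum(n_pas), replace = TRUE,
                    prob = spec$hexamer_probs)
    jitter <- sample.int(15L, sum(n_pas), replace = TRUE) - 1L
    seqs <- vapply(clen, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    list(tid = tid, n_pas = n_pas, strand = strand, tlen = tlen,
         clen = clen, hexes = hexes, jitter = jitter, seqs = seqs)
  })
  idx <- rep(seq_len(spec$n_transcripts), res$n_pas)
  ord <- sequence(res$n_pas)
  # position of the hexamer start within the transcript (5' -> 3'),
  # slots 30 nt apart with jitter; always >= 11 from either end
  tpos <- 11L + (ord - 1L) * 30L + res$jitter
  tlen_i <- res$tlen[idx]
  plus <- res$strand[idx] == "+"
  gstart <- ifelse(plus, pad + tpos, pad + tlen_i - tpos - 4L)
  gend <- gstart + 5L
  planted <- ifelse(plus, rna_to_dna(res$hexes),
                    revcomp_dna(rna_to_dna(res$hexes)))
  seqs <- res$seqs
  for (j in seq_along(idx)) {
    i <- idx[j]
    substr(seqs[i], gstart[j], gend[j]) <- planted[j]
  }
  truth <- data.frame(transcript_id = res$tid[idx], hexamer = res$hexes,
                      ordinal = ord, n_on_transcript = res$n_pas[idx],
                      chrom = res$tid[idx], start = gstart, end = gend,
                      strand = res$strand[idx], stringsAsFactors = FALSE)

  paths <- list(fasta = file.path(dir, "genome.fasta"),
                gff3 = file.path(dir, "annotation.gff3"),
                genbank = file.path(dir, "annotation.gbff"),
                truth_tsv = file.path(dir, "ground_truth.tsv"))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- res$tid
  Biostrings::writeXStringSet(dna, paths$fasta, width = 70)
  write_corpus_gff3(paths$gff3, spec, res, truth, pad, legacy_dialect)
  write_corpus_genbank(paths$genbank, res, truth, seqs, pad, legacy_dialect)
  con <- file(paths$truth_tsv, "w")
  writeLines(sprintf("# pasbind synthetic corpus ground truth; seed=%d",
                     spec$seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  c(paths, list(truth = truth))
}

write_corpus_gff3 <- function(path, spec, res, truth, pad, legacy_dialect) {
  mrna <- sprintf("%s\tpasbind\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                  res$tid, pad + 1L, pad + res$tlen, res$strand, res$tid)
  if (legacy_dialect) {
    feat <- sprintf("%s\tpasbind\tpolyA_signal\t%d\t%d\t.\t%s\t.\tParent=%s",
                    truth$chrom, truth$start, truth$end, truth$strand,
                    truth$transcript_id)
  } else {
    feat <- sprintf(paste0("%s\tpasbind\tregulatory_region\t%d\t%d\t.\t%s\t.\t",
                           "Parent=%s;regulatory_class=polyA_signal_sequence"),
                    truth$chrom, truth$start, truth$end, truth$strand,
                    truth$transcript_id)
  }
  writeLines(c("##gff-version 3",
               sprintf("# pasbind synthetic corpus; seed=%d", spec$seed),
               mrna, feat), path)
}
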