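#' Extract annotated polyadenylation signals from genome annotation
#'
#' Reads polyadenylation-signal features from GFF3 (with a genome FASTA for
#' sequence) or from a GenBank flat file (sequence embedded) and returns one
#' record per feature-transcript association, with the signal hexamer read
#' from the genome (reverse-complemented on the minus strand and reported in
#' the RNA alphabet) and its 1-based ordinal among the transcript's signals
#' in transcript 5'-to-3' order.
#'
#' Recognised signal encodings: feature type/key `polyA_signal_sequence` or
#' legacy `polyA_signal`, and `regulatory_region`/`region`/`regulatory`
#' features carrying `regulatory_class=polyA_signal_sequence`. Transcript
#' association uses the GFF3 `Parent` attribute or the GenBank
#' `transcript_id` qualifier, falling back to coordinate containment within
#' an mRNA feature on the same contig and strand; features with no
#' resolvable transcript are assigned to a synthetic singleton transcript
#' and counted in the skip report. Qualifying features whose span is not
#' 6 nt, or whose sequence leaves the ACGU alphabet, are excluded and
#' counted.
#'
#' @param annotation Path to a GFF3 or GenBank flat file. The dialect is
#'   inferred from the extension (`.gff`/`.gff3` vs `.gb`/`.gbk`/`.gbff`)
#'   unless `dialect` is given.
#' @param fasta Genome FASTA path (required for GFF3 input).
#' @param dialect `"gff3"`, `"genbank"`, or `NULL` to infer.
#' @param dedupe_genomic If `TRUE`, features sharing one genomic locus
#'   (chrom, start, end, strand) are counted once instead of once per
#'   associated transcript.
#' @return An object of class `pas_features`: list with `features` (data
#'   frame with columns `transcript_id`, `hexamer`, `ordinal`,
#'   `n_on_transcript`, `chrom`, `start`, `end`, `strand`) and `skipped`
#'   (named integer vector; see [skip_report()]).
#' @export
parse_annotation <- function(annotation, fasta = NULL, dialect = NULL,
                             dedupe_genomic = FALSE) {
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(annotation))
    dialect <- if (ext %in% c("gff", "gff3")) "gff3"
    else if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank"
    else stop("cannot infer annotation dialect from extension '", ext,
              "'; pass dialect=")
  }
  dialect <- match.arg(dialect, c("gff3", "genbank"))
  raw <- if (dialect == "gff3") {
    if (is.null(fasta)) stop("GFF3 input requires a genome FASTA")
    read_pas_gff3(annotation, fasta)
  } else {
    read_pas_genbank(annotation)
  }
  assemble_pas_features(raw$pas, raw$tx, raw$getseq, dedupe_genomic)
}

# GFF3 route: rtracklayer for the annotation, Biostrings for the genome.
read_pas_gff3 <- function(annotation, fasta) {
  gr <- rtracklayer::import(annotation, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  regclass <- if ("regulatory_class" %in% names(md))
    as.character(md$regulatory_class) else rep(NA_character_, length(gr))
  is_pas <- type %in% c("polyA_signal_sequence", "polyA_signal") |
    (type %in% c("regulatory_region", "region", "regulatory") &
       !is.na(regclass) & regclass == "polyA_signal_sequence")
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  pas <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_pas],
    start = GenomicRanges::start(gr)[is_pas],
    end = GenomicRanges::end(gr)[is_pas],
    strand = as.character(GenomicRanges::strand(gr))[is_pas],
    transcript_id = parent[is_pas],
    stringsAsFactors = FALSE)
  is_tx <- type %in% c("mRNA", "transcript")
  txid <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  tx <- data.frame(
    transcript_id = txid[is_tx],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx],
    strand = as.character(GenomicRanges::strand(gr))[is_tx],
    stringsAsFactors = FALSE)
  getseq <- function(chrom, start, end) {
    as.character(Biostrings::subseq(genome[chrom], start = start, end = end))
  }
  list(pas = pas, tx = tx, getseq = getseq)
}

read_pas_genbank <- function(annotation) {
  gb <- read_genbank(annotation)
  f <- gb$features
  is_pas <- f$key %in% c("polyA_signal_sequence", "polyA_signal") |
    (f$key %in% c("regulatory", "regulatory_region", "region") &
       !is.na(f$regulatory_class) &
       f$regulatory_class == "polyA_signal_sequence")
  pas <- data.frame(chrom = f$chrom[is_pas], start = f$start[is_pas],
                    end = f$end[is_pas], strand = f$strand[is_pas],
                    transcript_id = f$transcript_id[is_pas],
                    stringsAsFactors = FALSE)
  is_tx <- f$key %in% c("mRNA", "transcript")
  tx <- data.frame(
    transcript_id = ifelse(is.na(f$transcript_id[is_tx]), f$chrom[is_tx],
                           f$transcript_id[is_tx]),
    chrom = f$chrom[is_tx], start = f$start[is_tx], end = f$end[is_tx],
    strand = f$strand[is_tx], stringsAsFactors = FALSE)
  seqs <- gb$sequences
  getseq <- function(chrom, start, end)
    substring(seqs[chrom], start, end)
  list(pas = pas, tx = tx, getseq = getseq)
}

assemble_pas_features <- function(pas, tx, getseq, dedupe_genomic) {
  skipped <- c(length_mismatch = 0L, alphabet = 0L, orphan = 0L)
  if (nrow(pas) == 0) {
    return(structure(list(
      features = data.frame(transcript_id = character(), hexamer = character(),
                            ordinal = integer(), n_on_transcript = integer(),
                            chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            stringsAsFactors = FALSE),
      skipped = skipped), class = "pas_features"))
  }
  # resolve missing transcript associations by containment in an mRNA span
  need <- which(is.na(pas$transcript_id))
  for (i in need) {
    hit <- which(tx$chrom == pas$chrom[i] & tx$strand == pas$strand[i] &
                   tx$start <= pas$start[i] & tx$end >= pas$end[i])
    if (length(hit) >= 1) {
      pas$transcript_id[i] <- tx$transcript_id[hit[1]]
    } else {
      pas$transcript_id[i] <- sprintf("orphan_%04d", i)
      skipped["orphan"] <- skipped["orphan"] + 1L
    }
  }
  if (dedupe_genomic) {
    key <- paste(pas$chrom, pas$start, pas$end, pas$strand)
    pas <- pas[!duplicated(key), , drop = FALSE]
  }
  len_ok <- pas$end - pas$start + 1L == 6L
  skipped["length_mismatch"] <- sum(!len_ok)
  pas <- pas[len_ok, , drop = FALSE]

  dna <- getseq(pas$chrom, pas$start, pas$end)
  minus <- pas$strand == "-"
  if (any(minus)) dna[minus] <- revcomp_dna(dna[minus])
  hex <- dna_to_rna(toupper(dna))
  alpha_ok <- !grepl("[^ACGU]", hex)
  skipped["alphabet"] <- sum(!alpha_ok)
  pas <- pas[alpha_ok, , drop = FALSE]
  hex <- hex[alpha_ok]

  # 5'->3' transcript order: ascending genomic start on +, descending on -
  key <- ifelse(pas$strand == "-", -pas$start, pas$start)
  o <- order(pas$transcript_id, key)
  pas <- pas[o, , drop = FALSE]
  hex <- hex[o]
  runs <- rle(pas$transcript_id)
  n_on <- rep(runs$lengths, runs$lengths)
  ordinal <- sequence(runs$lengths)

  structure(list(
    features = data.frame(transcript_id = pas$transcript_id, hexamer = hex,
                          ordinal = ordinal, n_on_transcript = n_on,
                          chrom = pas$chrom, start = pas$start, end = pas$end,
                          strand = pas$strand, row.names = NULL,
                          stringsAsFactors = FALSE),
    skipped = skipped), class = "pas_features")
}

#' @export
print.pas_features <- function(x, ...) {
  cat(sprintf("%d polyadenylation-signal features on %d transcripts\n",
              nrow(x$features), length(unique(x$features$transcript_id))))
  if (sum(x$skipped)) cat("skipped:", paste(names(x$skipped), x$skipped,
                                            collapse = ", "), "\n")
  invisible(x)
}

#' Excluded-feature report for a parse run
#'
#' @param parsed A `pas_features` object from [parse_annotation()].
#' @return Named integer vector with counts of features excluded for a
#'   non-6-nt span (`length_mismatch`) or a non-ACGU hexamer (`alphabet`),
#'   and features kept but assigned to a synthetic singleton transcript
#'   (`orphan`).
#' @export
skip_report <- function(parsed) {
  stopifnot(inherits(parsed, "pas_features"))
  parsed$skipped
}

#' Stratified hexamer frequency census
#'
#' Counts hexamer usage over all signals and within position strata defined
#' per transcript: `single` (the transcript's only signal), `first` /
#' `last` (ordinal 1 / n on transcripts with n >= 2 signals), and
#' `intermediate` (interior signals on transcripts with n >= 3).
#' Percentages are 100 * count / stratum total.
#'
#' @param parsed A `pas_features` object, or its `features` data frame.
#' @return Named list of data frames (strata `all`, `single`, `first`,
#'   `intermediate`, `last`), each with columns `hexamer`, `count`,
#'   `percent` sorted by decreasing count.
#' @export
census <- function(parsed) {
  feats <- if (inherits(parsed, "pas_features")) parsed$features else parsed
  strata <- list(
    all = rep(TRUE, nrow(feats)),
    single = feats$n_on_transcript == 1,
    first = feats$ordinal == 1 & feats$n_on_transcript >= 2,
    intermediate = feats$ordinal > 1 & feats$ordinal < feats$n_on_transcript,
    last = feats$ordinal == feats$n_on_transcript & feats$n_on_transcript >= 2)
  lapply(strata, function(sel) {
    tab <- table(feats$hexamer[sel])
    tab <- sort(tab, decreasing = TRUE)
    total <- sum(tab)
    data.frame(hexamer = names(tab), count = as.integer(tab),
               percent = if (total > 0) 100 * as.integer(tab) / total
               else numeric(0),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Write a stratified census as a single TSV
#'
#' @param tables Result of [census()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(tables, path) {
  rows <- do.call(rbind, lapply(names(tables), function(s) {
    t <- tables[[s]]
    if (nrow(t) == 0) return(NULL)
    cbind(stratum = s, t)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
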